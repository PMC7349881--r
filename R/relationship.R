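#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / (2 * sum(p_i (1 - p_i))), where Z is the dosage matrix centered
#' by twice the reference allele frequency per SNP (Z_ij = x_ij - 2 p_j).
#' Missing dosages are mean-imputed, i.e. set to 0 after centering. Reference
#' frequencies default to the pooled sample. SNPs with undefined or
#' degenerate frequency contribute nothing to Z but monomorphic SNPs still
#' keep the denominator definition consistent (they add zero).
#'
#' @param g a `genotypes` object (at least 2 individuals).
#' @param freqs optional [allele_freqs()] table of reference frequencies;
#'   default pooled frequencies of `g`.
#' @return An object of class `grm`: list with `G` (n x n symmetric, dimnames
#'   = individual ids), `freqs`, `denominator`, `individuals`.
#' @export
grm_vanraden <- function(g, freqs = NULL) {
  stopifnot(inherits(g, "genotypes"))
  if (n_individuals(g) < 2) stop("need at least 2 individuals")
  if (is.null(freqs)) freqs <- allele_freqs(g)
  if (nrow(freqs) != n_snps(g)) stop("freqs table does not match SNP set")
  p <- freqs$p
  usable <- !is.na(p)
  denom <- 2 * sum(p[usable] * (1 - p[usable]))
  if (denom <= 0) stop("all SNPs monomorphic: zero VanRaden denominator")
  Z <- sweep(g$dosage, 2, 2 * p)
  Z[, !usable] <- 0
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(g$individuals$id, g$individuals$id)
  structure(list(G = G, freqs = freqs, denominator = denom,
                 individuals = g$individuals),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$G)
  cat("VanRaden genomic relationship matrix:", n, "x", n, "\n")
  cat(sprintf("  denominator 2*sum(p(1-p)) = %.2f\n", x$denominator))
  cat(sprintf("  diagonal mean %.3f; off-diagonal mean %.3f\n",
              mean(diag(x$G)), mean(x$G[upper.tri(x$G)])))
  invisible(x)
}

#' Genomic inbreeding from the GRM diagonal
#'
#' F_G for individual j is simply `G_jj - 1`.
#'
#' @param grm a `grm` object (or a bare symmetric matrix).
#' @return Named numeric vector of per-individual inbreeding coefficients.
#' @export
genomic_inbreeding_from_grm <- function(grm) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  diag(G) - 1
}

#' Normalized genomic relationships
#'
#' Divides G_jk by sqrt(G_jj * G_kk), yielding a correlation-like matrix with
#' unit diagonal.
#'
#' @param grm a `grm` object (or matrix) with strictly positive diagonal.
#' @return n x n matrix with unit diagonal.
#' @export
normalize_grm <- function(grm) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  d <- diag(G)
  if (any(d <= 0)) {
    bad <- rownames(G)[d <= 0]
    if (is.null(bad)) bad <- which(d <= 0)
    stop("non-positive GRM diagonal for: ", paste(bad, collapse = ", "))
  }
  s <- sqrt(d)
  R <- G / outer(s, s)
  diag(R) <- 1
  R
}

#' Allele-sharing (IBS) distance matrix
#'
#' For each pair, the mean absolute dosage difference over mutually
#' non-missing SNPs divided by 2, i.e. one minus the identity-by-state
#' similarity; values lie in `[0, 1]` with zero diagonal.
#'
#' @param g a `genotypes` object (at least 2 individuals).
#' @return n x n symmetric matrix (dimnames = individual ids). Pairs with no
#'   shared genotyped SNP are `NA` with a warning.
#' @export
ibs_distance <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  if (n_individuals(g) < 2) stop("need at least 2 individuals")
  X <- g$dosage
  I0 <- (!is.na(X) & X == 0L) + 0
  I1 <- (!is.na(X) & X == 1L) + 0
  I2 <- (!is.na(X) & X == 2L) + 0
  nonmiss <- (!is.na(X)) + 0
  shared <- tcrossprod(nonmiss)
  absdiff <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  D <- absdiff / (2 * shared)
  if (any(shared == 0)) {
    warning("pair(s) with zero shared SNPs: distance undefined (NA)")
    D[shared == 0] <- NA_real_
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(g$individuals$id, g$individuals$id)
  D
}

#' Principal component analysis of the GRM
#'
#' Top-k eigenvectors of G scaled by the square root of their eigenvalues;
#' variance explained is each eigenvalue over the sum of positive eigenvalues.
#'
#' @param grm a `grm` object (or symmetric matrix).
#' @param k number of components (`k < n`).
#' @return List with `coordinates` (n x k, dimnames kept) and
#'   `variance_explained` (length k).
#' @export
pca_from_grm <- function(grm, k = 2) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  n <- nrow(G)
  if (k >= n) stop("k must be smaller than the number of individuals")
  e <- eigen(G, symmetric = TRUE)
  pos <- sum(pmax(e$values, 0))
  lam <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  dimnames(coords) <- list(rownames(G), paste0("PC", seq_len(k)))
  list(coordinates = coords, variance_explained = e$values[seq_len(k)] / pos)
}

#' Family clusters from normalized relationships
#'
#' Within each population, connects pairs whose normalized relationship is at
#' least `threshold` and takes connected components as families; singletons
#' form their own family. The default 0.25 corresponds to half-sib /
#' grandparent-level relatedness, so full-sib groups (about 0.5) stay
#' together while unrelated animals separate.
#'
#' @param R normalized GRM (from [normalize_grm()]).
#' @param populations character vector of population labels, one per row of
#'   `R` (in row order).
#' @param threshold relationship cutoff in (0, 1).
#' @return data.frame `id`, `population`, `family` (labels of the form
#'   `<population>.<k>` numbered by first occurrence), with attribute
#'   `n_families` (named vector per population).
#' @export
family_clusters <- function(R, populations, threshold = 0.25) {
  R <- as.matrix(R)
  n <- nrow(R)
  stopifnot(length(populations) == n, threshold > 0, threshold < 1)
  ids <- rownames(R)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- data.frame(id = ids, population = populations,
                    family = NA_character_, stringsAsFactors = FALSE)
  nfam <- c()
  for (pop in unique(populations)) {
    idx <- which(populations == pop)
    A <- R[idx, idx, drop = FALSE] >= threshold
    diag(A) <- FALSE
    gr <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    comp <- igraph::components(gr)$membership
    # renumber components by first occurrence so labels are order-stable
    lab <- match(comp, unique(comp))
    out$family[idx] <- paste0(pop, ".", lab)
    nfam[pop] <- length(unique(lab))
  }
  attr(out, "n_families") <- nfam
  out
}
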