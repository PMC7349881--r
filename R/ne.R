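#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of dosage vectors (composite, unphased LD
#' estimator) for every same-chromosome SNP pair whose distance lies in
#' `[min_dist_bp, max_dist_bp]`, computed over mutually non-missing
#' individuals. Pairs involving a zero-variance SNP are skipped.
#'
#' @param g a `genotypes` object (SNPs should already be MAF-filtered).
#' @param individuals ids or `NULL`; `population` selects by label.
#' @param population population label(s).
#' @param min_dist_bp,max_dist_bp distance window in base pairs.
#' @return data.frame: `chrom`, `snp1`, `snp2`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(g, individuals = NULL, population = NULL,
                        min_dist_bp = 0, max_dist_bp = Inf) {
  stopifnot(inherits(g, "genotypes"))
  rows <- if (!is.null(individuals)) match(individuals, g$individuals$id)
          else pop_rows(g, population)
  if (anyNA(rows)) stop("unknown individual id(s)")
  res <- vector("list", 0L)
  for (ch in unique(g$snps$chrom)) {
    cols <- which(g$snps$chrom == ch)
    if (length(cols) < 2) next
    pos <- as.numeric(g$snps$pos_bp[cols])
    X <- g$dosage[rows, cols, drop = FALSE]
    suppressWarnings(
      cc <- stats::cor(X, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dist <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- dist >= min_dist_bp & dist <= max_dist_bp & !is.na(cc[pr])
    if (!any(keep)) next
    pr <- pr[keep, , drop = FALSE]
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch,
      snp1 = g$snps$id[cols][pr[, 1]], snp2 = g$snps$id[cols][pr[, 2]],
      dist_bp = dist[keep], r2 = cc[pr]^2, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(chrom = integer(0), snp1 = character(0),
                      snp2 = character(0), dist_bp = numeric(0),
                      r2 = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Physical to genetic distance
#'
#' Uniform map: `c = distance_bp * rate / 1e8` Morgans (1 cM/Mb default).
#'
#' @param distance_bp distance in base pairs.
#' @param rate_cm_per_mb recombination rate in cM per Mb.
#' @return Genetic distance in Morgans.
#' @export
bp_to_morgans <- function(distance_bp, rate_cm_per_mb = 1.0) {
  stopifnot(rate_cm_per_mb > 0)
  distance_bp * rate_cm_per_mb / 1e8
}

#' Finite-sample adjustment of mean r-squared
#'
#' Subtracts the `1/n` sampling inflation of dosage-based r-squared
#' (`correction = "1/n"`), or returns the input unchanged
#' (`correction = "none"`). Adjusted values at or below zero are returned as
#' `NA`, flagging the bin as unusable.
#'
#' @param mean_r2 mean r-squared of a distance bin.
#' @param n number of individuals.
#' @param correction `"1/n"` or `"none"`.
#' @return Adjusted mean r-squared, or `NA` if not positive.
#' @export
adjust_r2 <- function(mean_r2, n, correction = c("1/n", "none")) {
  correction <- match.arg(correction)
  if (correction == "none") return(mean_r2)
  stopifnot(n >= 2)
  adj <- mean_r2 - 1 / n
  ifelse(adj > 0, adj, NA_real_)
}

#' Effective population size from one LD bin
#'
#' Inverts Sved's drift relationship `E(r2) = 1 / (alpha + 4 Ne c)`:
#' `Ne = (1/r2_adj - alpha_model) / (4 c)`. `alpha_model = 1` is the
#' drift-only convention; 2.2 is sometimes used when mutation is modelled.
#' Negative results are floored at zero.
#'
#' @param r2_adj adjusted mean r-squared (0 < r2_adj <= 1).
#' @param c_mid genetic distance of the bin in Morgans (> 0).
#' @param alpha_model structural constant of the model.
#' @return Ne estimate (>= 0).
#' @export
ne_from_bin <- function(r2_adj, c_mid, alpha_model = 1) {
  if (any(is.na(r2_adj)) || any(r2_adj <= 0)) stop("r2_adj must be positive")
  stopifnot(all(c_mid > 0))
  pmax(0, (1 / r2_adj - alpha_model) / (4 * c_mid))
}

#' Generations ago corresponding to a genetic distance
#'
#' `t = 1 / (2c)`: LD at genetic distance `c` Morgans reflects the effective
#' size roughly `t` generations in the past.
#'
#' @param c_mid genetic distance in Morgans (> 0).
#' @return Generations ago.
#' @export
generations_from_c <- function(c_mid) {
  stopifnot(all(c_mid > 0))
  1 / (2 * c_mid)
}

#' Historical Ne trajectory from LD decay
#'
#' Full pipeline: pairwise r-squared, binning by genetic distance,
#' finite-sample adjustment, Sved inversion and mapping of each bin's
#' distance to generations ago. Bins with fewer than `min_pairs` pairs, or
#' whose adjusted r-squared is not positive, are omitted. `c_mid` is the mean
#' pair distance within the bin (always between the bin edges).
#'
#' @param g a `genotypes` object (MAF-filtered).
#' @param individuals,population individual set (see [pairwise_r2()]).
#' @param bins vector of genetic-distance bin edges in Morgans; the default
#'   is 30 logarithmic bins spanning roughly 13 to 1000 generations ago.
#' @param rate_cm_per_mb uniform recombination map rate.
#' @param alpha_model Sved structural constant (see [ne_from_bin()]).
#' @param correction r-squared adjustment mode (see [adjust_r2()]).
#' @param min_pairs minimum SNP pairs per usable bin.
#' @return An object of class `ne_trajectory`: data.frame `t`, `Ne`, `c_mid`,
#'   `mean_r2`, `mean_r2_adj`, `n_pairs`, sorted by `t`.
#' @export
ne_trajectory <- function(g, individuals = NULL, population = NULL,
                          bins = NULL, rate_cm_per_mb = 1.0, alpha_model = 1,
                          correction = c("1/n", "none"), min_pairs = 300) {
  correction <- match.arg(correction)
  if (n_snps(g) == 0) stop("no SNPs")
  if (is.null(bins))
    bins <- exp(seq(log(5e-4), log(1 / 26), length.out = 31))
  rows <- if (!is.null(individuals)) match(individuals, g$individuals$id)
          else pop_rows(g, population)
  n <- length(rows)
  max_bp <- max(bins) * 1e8 / rate_cm_per_mb
  min_bp <- min(bins) * 1e8 / rate_cm_per_mb
  ld <- pairwise_r2(g, individuals = g$individuals$id[rows],
                    min_dist_bp = min_bp, max_dist_bp = max_bp)
  if (!nrow(ld)) stop("no usable SNP pairs in the requested distance range")
  cM <- bp_to_morgans(ld$dist_bp, rate_cm_per_mb)
  bin <- cut(cM, bins, include.lowest = TRUE)
  rows_out <- lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    if (length(sel) < min_pairs) return(NULL)
    m_r2 <- mean(ld$r2[sel])
    adj <- if (correction == "1/n") adjust_r2(m_r2, n, "1/n") else m_r2
    if (is.na(adj) || adj <= 0) return(NULL)
    c_mid <- mean(cM[sel])
    data.frame(t = generations_from_c(c_mid),
               Ne = ne_from_bin(adj, c_mid, alpha_model),
               c_mid = c_mid, mean_r2 = m_r2, mean_r2_adj = adj,
               n_pairs = length(sel))
  })
  out <- do.call(rbind, rows_out)
  if (is.null(out) || !nrow(out)) stop("no usable LD bins")
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_individuals = n, alpha_model = alpha_model,
            correction = correction, rate_cm_per_mb = rate_cm_per_mb,
            class = c("ne_trajectory", "data.frame"))
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("LD-based Ne trajectory:", nrow(x), "usable bins,",
      attr(x, "n_individuals"), "individuals\n")
  cat(sprintf("  most recent horizon: t = %.0f generations, Ne = %.0f\n",
              x$t[1], x$Ne[1]))
  cat(sprintf("  oldest horizon:      t = %.0f generations, Ne = %.0f\n",
              x$t[nrow(x)], x$Ne[nrow(x)]))
  invisible(x)
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$Ne, log = "xy", type = "b", pch = 16,
                 xlab = "generations ago", ylab = "Ne", ...)
  invisible(x)
}
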