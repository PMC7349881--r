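#' Per-SNP allele frequencies
#'
#' Frequency of `allele_b` per SNP over a set of individuals, ignoring missing
#' genotypes: `p = sum(dosage) / (2 * n_obs)`.
#'
#' @param g a `genotypes` object.
#' @param individuals character ids or `NULL` for all; alternatively a
#'   population label via `population`.
#' @param population population label(s) selecting the individual set.
#' @return data.frame with columns `snp`, `chrom`, `pos_bp`, `p`, `n_obs`;
#'   SNPs with no non-missing genotypes get `p = NA`.
#' @export
allele_freqs <- function(g, individuals = NULL, population = NULL) {
  stopifnot(inherits(g, "genotypes"))
  rows <- if (!is.null(individuals)) {
    match(individuals, g$individuals$id)
  } else pop_rows(g, population)
  if (anyNA(rows)) stop("unknown individual id(s)")
  if (!length(rows)) stop("empty individual set")
  x <- g$dosage[rows, , drop = FALSE]
  n_obs <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  data.frame(snp = g$snps$id, chrom = g$snps$chrom, pos_bp = g$snps$pos_bp,
             p = as.numeric(p), n_obs = as.integer(n_obs),
             stringsAsFactors = FALSE)
}

#' Proportion of polymorphic SNPs
#'
#' Fraction of all SNPs whose minor allele frequency exceeds `maf_threshold`
#' in the given individual set (P_N). The denominator is the total SNP count,
#' so SNPs that are monomorphic in the set lower the proportion.
#'
#' @inheritParams allele_freqs
#' @param maf_threshold MAF above which a SNP counts as polymorphic.
#' @return A single fraction in `[0, 1]`.
#' @export
prop_polymorphic <- function(g, individuals = NULL, population = NULL,
                             maf_threshold = 0.01) {
  fr <- allele_freqs(g, individuals, population)
  maf <- pmin(fr$p, 1 - fr$p)
  sum(!is.na(maf) & maf > maf_threshold) / nrow(fr)
}

#' Observed and expected heterozygosity
#'
#' Per-SNP observed heterozygosity (fraction of non-missing genotypes that are
#' heterozygous) and Hardy-Weinberg expected heterozygosity `2p(1-p)`, with
#' across-SNP means and standard deviations.
#'
#' @inheritParams allele_freqs
#' @return List with `per_snp` (data.frame: snp, H_O, H_E), `H_O_mean`,
#'   `H_O_sd`, `H_E_mean`, `H_E_sd`.
#' @export
heterozygosity <- function(g, individuals = NULL, population = NULL) {
  stopifnot(inherits(g, "genotypes"))
  rows <- if (!is.null(individuals)) {
    match(individuals, g$individuals$id)
  } else pop_rows(g, population)
  if (anyNA(rows)) stop("unknown individual id(s)")
  x <- g$dosage[rows, , drop = FALSE]
  n_obs <- colSums(!is.na(x))
  H_O <- colSums(x == 1L, na.rm = TRUE) / n_obs
  H_O[n_obs == 0] <- NA_real_
  p <- colSums(x, na.rm = TRUE) / (2 * n_obs)
  H_E <- 2 * p * (1 - p)
  H_E[n_obs == 0] <- NA_real_
  list(per_snp = data.frame(snp = g$snps$id, H_O = as.numeric(H_O),
                            H_E = as.numeric(H_E), stringsAsFactors = FALSE),
       H_O_mean = mean(H_O, na.rm = TRUE), H_O_sd = stats::sd(H_O, na.rm = TRUE),
       H_E_mean = mean(H_E, na.rm = TRUE), H_E_sd = stats::sd(H_E, na.rm = TRUE))
}

#' Homozygosity-excess inbreeding coefficient (F_HOM)
#'
#' Method-of-moments inbreeding per individual from the excess of observed
#' over expected homozygous genotypes: `F_HOM = (O_HOM - E_HOM) / (L - E_HOM)`
#' where, over the individual's non-missing SNPs,
#' `E_HOM = sum(1 - 2 p (1-p) n/(n-1))` with `n` the number of genotypes the
#' frequency `p` was estimated from. Positive values indicate homozygosity
#' excess (inbreeding). Reference frequencies default to the individual's own
#' population.
#'
#' @param g a `genotypes` object.
#' @param freqs optional [allele_freqs()] table to use as the reference for
#'   every individual (e.g. pooled frequencies); default `NULL` computes
#'   within-population frequencies.
#' @param small_sample_correction apply the `n/(n-1)` factor on `2pq`
#'   (default `TRUE`).
#' @return data.frame: `id`, `population`, `O_HOM`, `E_HOM`, `L`, `F_HOM`.
#'   `F_HOM` is `NA` (flagged) where `L == E_HOM`.
#' @export
f_hom <- function(g, freqs = NULL, small_sample_correction = TRUE) {
  stopifnot(inherits(g, "genotypes"))
  n_ind <- n_individuals(g)
  out <- data.frame(id = g$individuals$id, population = g$individuals$population,
                    O_HOM = NA_real_, E_HOM = NA_real_, L = NA_integer_,
                    F_HOM = NA_real_, stringsAsFactors = FALSE)
  freq_for <- function(pop) {
    if (!is.null(freqs)) freqs else allele_freqs(g, population = pop)
  }
  cache <- list()
  for (i in seq_len(n_ind)) {
    pop <- g$individuals$population[i]
    key <- if (is.null(freqs)) pop else ".pooled"
    if (is.null(cache[[key]])) cache[[key]] <- freq_for(pop)
    fr <- cache[[key]]
    x <- g$dosage[i, ]
    obs <- !is.na(x) & !is.na(fr$p)
    L <- sum(obs)
    O <- sum(x[obs] != 1L)
    p <- fr$p[obs]
    nn <- fr$n_obs[obs]
    corr <- if (small_sample_correction) ifelse(nn > 1, nn / (nn - 1), 1) else 1
    E <- sum(1 - 2 * p * (1 - p) * corr)
    out$O_HOM[i] <- O
    out$E_HOM[i] <- E
    out$L[i] <- L
    out$F_HOM[i] <- if (abs(L - E) < .Machine$double.eps^0.5) NA_real_ else (O - E) / (L - E)
  }
  out
}

#' Per-population diversity summary
#'
#' Convenience wrapper assembling, for each population: sample size, P_N,
#' mean/sd observed and expected heterozygosity, and mean F_HOM.
#'
#' @param g a `genotypes` object.
#' @param maf_threshold polymorphism threshold for P_N.
#' @param pooled also append an "Overall" row computed on the pooled sample.
#' @return data.frame with one row per population (class `diversity_summary`).
#' @export
diversity_summary <- function(g, maf_threshold = 0.01, pooled = TRUE) {
  stopifnot(inherits(g, "genotypes"))
  fh <- f_hom(g)
  one <- function(pop, label) {
    rows <- pop_rows(g, pop)
    het <- heterozygosity(g, population = pop)
    fhm <- if (is.null(pop)) mean(fh$F_HOM, na.rm = TRUE) else
      mean(fh$F_HOM[fh$population %in% pop], na.rm = TRUE)
    data.frame(population = label, n = length(rows),
               P_N = prop_polymorphic(g, population = pop, maf_threshold = maf_threshold),
               H_O_mean = het$H_O_mean, H_O_sd = het$H_O_sd,
               H_E_mean = het$H_E_mean, H_E_sd = het$H_E_sd,
               F_HOM_mean = fhm, stringsAsFactors = FALSE)
  }
  pops <- unique(g$individuals$population)
  res <- do.call(rbind, lapply(pops, function(p) one(p, p)))
  if (pooled && length(pops) > 1) res <- rbind(res, one(NULL, "Overall"))
  rownames(res) <- NULL
  class(res) <- c("diversity_summary", "data.frame")
  res
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$P_N <- sprintf("%.1f%%", 100 * y$P_N)
  y$H_O <- sprintf("%.3f ± %.2f", y$H_O_mean, y$H_O_sd)
  y$H_E <- sprintf("%.3f ± %.2f", y$H_E_mean, y$H_E_sd)
  y$F_HOM <- sprintf("%.3f", y$F_HOM_mean)
  print(y[, c("population", "n", "P_N", "H_O", "H_E", "F_HOM")], row.names = FALSE)
  invisible(x)
}
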