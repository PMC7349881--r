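#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided test for one biallelic SNP from genotype counts, conditional
#' on the observed allele counts: the p-value is the sum of probabilities of
#' all heterozygote counts no more probable than the observed one (the SNP-HWE
#' exact test of Wigginton, Cutler and Abecasis).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero: HWE test undefined")
  n_a <- 2 * n_aa + n_Aa           # count of one allele
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)            # rarer allele count; het counts share its parity
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | n, rare) up to the common normalizer
  logp <- vapply(hets, function(h) {
    haa <- (rare - h) / 2
    hAA <- n - h - haa
    lgamma(n + 1) - lgamma(hAA + 1) - lgamma(h + 1) - lgamma(haa + 1) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

qc_thresholds_default <- function() {
  list(call_rate = 0.95, maf = 0.05, hwe_p = 1e-5, mind = 0.10, n_autosomes = 29L)
}

#' Sequential SNP-array quality control with accounting
#'
#' Applies the standard conservation-assessment filter chain and records every
#' exclusion. Individuals with a missing-genotype fraction above `mind` are
#' removed first; SNPs are then filtered sequentially: (1) unrecognized
#' position (chromosome 0 or outside `1..n_autosomes`, or non-positive
#' position), (2) call rate below `call_rate`, (3) minor allele frequency below
#' `maf` (recomputed on the current data, ignoring missing genotypes),
#' (4) Hardy-Weinberg exact p-value below `hwe_p` (pooled sample by default).
#' The order matters: exclusion counts are defined by this sequence.
#'
#' @param g a `genotypes` object.
#' @param call_rate,maf,hwe_p,mind filter thresholds (all in `[0, 1]`).
#' @param n_autosomes largest recognized autosome label.
#' @param hwe_by_population if `TRUE`, a SNP is removed when it fails the HWE
#'   test within any single population rather than in the pooled sample.
#' @return A list with elements `genotypes` (the filtered object) and `report`
#'   (a `qc_report`): the report holds `initial_snps`, an ordered `steps`
#'   data.frame (name, threshold, excluded, remaining), `final_snps` and
#'   `excluded_individuals`, satisfying
#'   `final_snps == initial_snps - sum(steps$excluded)`.
#' @export
run_qc <- function(g, call_rate = 0.95, maf = 0.05, hwe_p = 1e-5, mind = 0.10,
                   n_autosomes = 29L, hwe_by_population = FALSE) {
  stopifnot(inherits(g, "genotypes"))
  for (v in c(call_rate, maf, hwe_p, mind))
    if (!is.numeric(v) || v < 0 || v > 1) stop("QC thresholds must lie in [0, 1]")
  if (n_snps(g) == 0 || n_individuals(g) == 0) stop("empty genotype matrix")
  initial <- n_snps(g)

  # individual-level missingness first
  imiss <- rowMeans(is.na(g$dosage))
  keep_ind <- imiss <= mind
  excluded_individuals <- sum(!keep_ind)
  if (excluded_individuals > 0)
    g <- subset_genotypes(g, individuals = g$individuals$id[keep_ind])

  steps <- data.frame(name = character(0), threshold = character(0),
                      excluded = integer(0), remaining = integer(0),
                      stringsAsFactors = FALSE)
  drop_step <- function(g, name, threshold, bad) {
    ex <- sum(bad)
    if (ex > 0) g <- subset_genotypes(g, snps = g$snps$id[!bad])
    steps <<- rbind(steps, data.frame(name = name, threshold = threshold,
                                      excluded = ex, remaining = n_snps(g),
                                      stringsAsFactors = FALSE))
    g
  }

  bad_pos <- g$snps$chrom < 1L | g$snps$chrom > n_autosomes | g$snps$pos_bp <= 0L
  g <- drop_step(g, "unrecognized position",
                 sprintf("autosomes 1-%d, pos > 0", n_autosomes), bad_pos)

  cr <- colMeans(!is.na(g$dosage))
  g <- drop_step(g, "call rate", sprintf("< %g", call_rate), cr < call_rate)

  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  mafs[is.nan(mafs)] <- 0
  g <- drop_step(g, "minor allele frequency", sprintf("< %g", maf), mafs < maf)

  hwe_fail <- function(sub) {
    nAA <- colSums(sub == 0L, na.rm = TRUE)
    nAa <- colSums(sub == 1L, na.rm = TRUE)
    naa <- colSums(sub == 2L, na.rm = TRUE)
    pv <- vapply(seq_along(nAA), function(j) {
      if (nAA[j] + nAa[j] + naa[j] == 0) return(1)
      hwe_exact_test(nAA[j], nAa[j], naa[j])
    }, numeric(1))
    pv < hwe_p
  }
  if (hwe_by_population) {
    fail <- rep(FALSE, n_snps(g))
    for (pp in unique(g$individuals$population))
      fail <- fail | hwe_fail(g$dosage[pop_rows(g, pp), , drop = FALSE])
  } else {
    fail <- hwe_fail(g$dosage)
  }
  g <- drop_step(g, "Hardy-Weinberg equilibrium", sprintf("p < %g", hwe_p), fail)

  report <- structure(list(initial_snps = initial, steps = steps,
                           final_snps = n_snps(g),
                           excluded_individuals = excluded_individuals),
                      class = "qc_report")
  stopifnot(report$final_snps == initial - sum(steps$excluded))
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP filtration report\n")
  labels <- paste0(x$steps$name, " (", x$steps$threshold, ")")
  w <- max(nchar(c("Total number of SNPs", labels))) + 2
  row <- function(lab, ex, rem)
    cat(sprintf("  %-*s %9s %10s\n", w, lab, ex, rem))
  row("Parameters", "Excluded", "Remained")
  row("Total number of SNPs", "", x$initial_snps)
  for (i in seq_len(nrow(x$steps)))
    row(labels[i], x$steps$excluded[i], x$steps$remaining[i])
  row("Total SNPs", sum(x$steps$excluded), x$final_snps)
  if (x$excluded_individuals > 0)
    cat("  individuals excluded for missingness:", x$excluded_individuals, "\n")
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) x$steps
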