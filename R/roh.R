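#' Minimum number of SNPs constituting a run of homozygosity
#'
#' The false-positive control rule of Lencz and colleagues:
#' `l = ceiling( ln(alpha / (n_s * n_i)) / ln(1 - het) )`, the smallest run
#' length (in SNPs) expected to occur by chance fewer than `alpha` times in a
#' panel of `n_s` SNPs typed on `n_i` individuals, given a mean observed
#' heterozygosity `het`. The ratio is floored by a 1e-9 guard before the
#' ceiling so exactly-integral values are not rounded up by floating-point
#' noise.
#'
#' @param alpha tolerated number of chance runs (e.g. 0.05).
#' @param n_s number of SNPs per individual.
#' @param n_i number of individuals.
#' @param het mean proportion of heterozygous genotypes, strictly in (0, 1).
#' @return Integer minimum SNP count (at least 1).
#' @export
min_snp_threshold <- function(alpha, n_s, n_i, het) {
  stopifnot(alpha > 0, n_s >= 1, n_i >= 1)
  if (!is.numeric(het) || het <= 0 || het >= 1)
    stop("het must lie strictly between 0 and 1")
  l <- log(alpha / (n_s * n_i)) / log(1 - het)
  max(1L, as.integer(ceiling(l - 1e-9)))
}

#' ROH detection parameters
#'
#' Container for the consecutive-scan parameters. If `min_snps` is `NULL` it
#' is computed from the dataset at detection time via [min_snp_threshold()],
#' using the dataset's SNP count, individual count and mean observed
#' heterozygosity.
#'
#' @param min_length_mb minimum run length in Mb.
#' @param max_gap_mb maximum gap between consecutive SNPs within a run, Mb.
#' @param max_het maximum heterozygous calls absorbed per run.
#' @param max_missing maximum missing calls absorbed per run.
#' @param alpha false-positive allowance for the minimum-SNP rule.
#' @param min_snps fixed minimum SNP count, or `NULL` to compute.
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(min_length_mb = 1, max_gap_mb = 1, max_het = 1,
                       max_missing = 1, alpha = 0.05, min_snps = NULL) {
  stopifnot(min_length_mb > 0, max_gap_mb > 0, max_het >= 0, max_missing >= 0,
            alpha > 0, alpha < 1)
  structure(list(min_length_mb = min_length_mb, max_gap_mb = max_gap_mb,
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 alpha = alpha, min_snps = min_snps),
            class = "roh_params")
}

roh_classes <- function() {
  data.frame(class = c("0-5 Mb", "5-15 Mb", "15-30 Mb", ">30 Mb"),
             low_mb = c(0, 5, 15, 30), high_mb = c(5, 15, 30, Inf),
             stringsAsFactors = FALSE)
}

# half-open [low, high) class assignment, lower bound inclusive
assign_length_class <- function(length_bp) {
  cls <- roh_classes()
  mb <- length_bp / 1e6
  idx <- findInterval(mb, cls$low_mb)
  cls$class[pmax(idx, 1L)]
}

#' Detect runs of homozygosity
#'
#' Greedy left-to-right consecutive-SNP scan per individual and chromosome:
#' a run extends over homozygous calls and may absorb up to `max_het`
#' heterozygous and `max_missing` missing calls; a gap larger than
#' `max_gap_mb` between consecutive SNPs, or an allowance overflow, closes
#' the run at the last homozygous call (absorbed calls at run edges are
#' trimmed, so runs start and end on homozygous evidence). Closed runs are
#' emitted iff they span at least `min_length_mb` and contain at least
#' `min_snps` SNPs; runs never span chromosomes.
#'
#' @param g a `genotypes` object (SNPs position-sorted, as the container
#'   guarantees).
#' @param params an [roh_params()] object.
#' @return An object of class `roh_set`: data.frame with columns `individual`,
#'   `population`, `chrom`, `start_bp`, `end_bp`, `n_snps`, `n_het`,
#'   `n_missing`, `length_bp`, `length_class`, carrying attributes
#'   `individuals` (all ids scanned, incl. those with no segments) and
#'   `params` (with the resolved `min_snps`).
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotypes"), inherits(params, "roh_params"))
  if (is.null(params$min_snps)) {
    het <- mean(g$dosage == 1L, na.rm = TRUE)
    params$min_snps <- min_snp_threshold(params$alpha, n_snps(g),
                                         n_individuals(g), het)
  }
  res <- vector("list", 0L)
  chroms <- unique(g$snps$chrom)
  for (ch in chroms) {
    cols <- which(g$snps$chrom == ch)
    pos <- as.numeric(g$snps$pos_bp[cols])
    for (i in seq_len(n_individuals(g))) {
      seg <- roh_scan_cpp(g$dosage[i, cols], pos,
                          params$max_gap_mb * 1e6, params$max_het,
                          params$max_missing, params$min_length_mb * 1e6,
                          params$min_snps)
      if (nrow(seg)) {
        res[[length(res) + 1L]] <- data.frame(
          individual = g$individuals$id[i],
          population = g$individuals$population[i],
          chrom = ch,
          start_bp = g$snps$pos_bp[cols][seg[, "start_idx"]],
          end_bp = g$snps$pos_bp[cols][seg[, "end_idx"]],
          n_snps = seg[, "n_snps"], n_het = seg[, "n_het"],
          n_missing = seg[, "n_missing"], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(individual = character(0), population = character(0),
               chrom = integer(0), start_bp = integer(0), end_bp = integer(0),
               n_snps = integer(0), n_het = integer(0), n_missing = integer(0),
               stringsAsFactors = FALSE)
  out$length_bp <- as.numeric(out$end_bp) - as.numeric(out$start_bp)
  out$length_class <- assign_length_class(out$length_bp)
  rownames(out) <- NULL
  structure(out, individuals = g$individuals, params = params,
            class = c("roh_set", "data.frame"))
}

#' @export
print.roh_set <- function(x, ...) {
  ind <- attr(x, "individuals")
  cat("ROH set:", nrow(x), "segments in", nrow(ind), "individuals",
      sprintf("(min %d SNPs, >= %g Mb)\n", attr(x, "params")$min_snps,
              attr(x, "params")$min_length_mb))
  if (nrow(x)) {
    cat(sprintf("  mean segment length %.2f Mb; per-class counts:\n",
                mean(x$length_bp) / 1e6))
    print(table(factor(x$length_class, levels = roh_classes()$class)))
  }
  invisible(x)
}

roh_ids <- function(roh, ids) {
  if (!is.null(ids)) return(ids)
  ind <- attr(roh, "individuals")
  if (!is.null(ind)) ind$id else unique(roh$individual)
}

#' Genome-wide F_ROH
#'
#' Per-individual total ROH length divided by the autosomal genome length
#' (default: the 2399.4 Mb goat autosome).
#'
#' @param roh a `roh_set` (or compatible data.frame).
#' @param ids individuals to report (default: everyone scanned, so
#'   segment-free individuals get 0).
#' @param L_auto_bp autosomal genome length in bp.
#' @return Named numeric vector of F_ROH values.
#' @export
f_roh_genome <- function(roh, ids = NULL, L_auto_bp = 2399.4e6) {
  ids <- roh_ids(roh, ids)
  tot <- tapply(roh$length_bp, roh$individual, sum)
  out <- setNames(rep(0, length(ids)), ids)
  out[names(tot)] <- tot
  out / L_auto_bp
}

#' Per-chromosome F_ROH
#'
#' Sum of an individual's ROH lengths on each chromosome divided by the
#' chromosome length covered by the SNPs (last minus first SNP position).
#' Chromosomes with fewer than 2 SNPs have undefined coverage and are
#' excluded with a warning.
#'
#' @param roh a `roh_set`.
#' @param g the `genotypes` object the segments were detected on (supplies
#'   SNP coverage per chromosome).
#' @param ids individuals to report (default: everyone scanned).
#' @return Matrix individuals x chromosomes of chromosomal F_ROH.
#' @export
f_roh_chromosome <- function(roh, g, ids = NULL) {
  stopifnot(inherits(g, "genotypes"))
  ids <- roh_ids(roh, ids)
  cov <- tapply(as.numeric(g$snps$pos_bp), g$snps$chrom,
                function(p) if (length(p) >= 2) max(p) - min(p) else NA_real_)
  if (anyNA(cov)) {
    warning("chromosome(s) with < 2 SNPs excluded: ",
            paste(names(cov)[is.na(cov)], collapse = ", "))
    cov <- cov[!is.na(cov)]
  }
  chroms <- names(cov)
  out <- matrix(0, length(ids), length(chroms),
                dimnames = list(ids, chroms))
  if (nrow(roh)) {
    keep <- as.character(roh$chrom) %in% chroms & roh$individual %in% ids
    r <- roh[keep, , drop = FALSE]
    for (k in seq_len(nrow(r)))
      out[r$individual[k], as.character(r$chrom[k])] <-
        out[r$individual[k], as.character(r$chrom[k])] + r$length_bp[k]
  }
  sweep(out, 2, as.numeric(cov), "/")
}

#' F_ROH by ROH length class
#'
#' Splits each individual's F_ROH across the four length classes
#' (`[1,5)`, `[5,15)`, `[15,30)`, `[30,Inf)` Mb; lower bounds inclusive).
#' All classes share the genome-wide denominator `L_auto_bp`, so the class
#' values of an individual sum exactly to the genome-wide F_ROH.
#'
#' @inheritParams f_roh_genome
#' @return List with `per_individual` (matrix individuals x classes) and
#'   `population_means_pct` (matrix populations x classes, in percent, with a
#'   Total column), the latter only when population labels are available.
#' @export
f_roh_by_class <- function(roh, ids = NULL, L_auto_bp = 2399.4e6) {
  ids <- roh_ids(roh, ids)
  cls <- roh_classes()$class
  per <- matrix(0, length(ids), length(cls), dimnames = list(ids, cls))
  if (nrow(roh)) {
    for (k in seq_len(nrow(roh))) {
      if (!roh$individual[k] %in% ids) next
      per[roh$individual[k], roh$length_class[k]] <-
        per[roh$individual[k], roh$length_class[k]] + roh$length_bp[k]
    }
  }
  per <- per / L_auto_bp
  out <- list(per_individual = per)
  ind <- attr(roh, "individuals")
  if (!is.null(ind)) {
    ind <- ind[ind$id %in% ids, , drop = FALSE]
    pops <- unique(ind$population)
    pm <- t(vapply(pops, function(pp) {
      colMeans(per[ind$id[ind$population == pp], , drop = FALSE]) * 100
    }, numeric(length(cls))))
    pm <- cbind(pm, Total = rowSums(pm))
    out$population_means_pct <- pm
  }
  out
}

#' Mean summed ROH length per class and population
#'
#' Adds up all ROH lengths of each length class per population and divides by
#' the population's individual count (in Mb).
#'
#' @param roh a `roh_set`.
#' @param populations optional named vector id -> population; default from the
#'   `roh_set` attributes.
#' @return Matrix populations x length classes, mean summed ROH length in Mb.
#' @export
mean_sum_roh_by_class <- function(roh, populations = NULL) {
  if (is.null(populations)) {
    ind <- attr(roh, "individuals")
    if (is.null(ind)) stop("population labels required")
    populations <- setNames(ind$population, ind$id)
  }
  pops <- unique(populations)
  cls <- roh_classes()$class
  out <- matrix(0, length(pops), length(cls), dimnames = list(pops, cls))
  for (pp in pops) {
    n_pop <- sum(populations == pp)
    if (n_pop == 0) stop("empty population: ", pp)
    sel <- roh$individual %in% names(populations)[populations == pp]
    if (any(sel)) {
      s <- tapply(roh$length_bp[sel], factor(roh$length_class[sel], levels = cls),
                  sum, default = 0)
      out[pp, ] <- s / n_pop / 1e6
    }
  }
  out
}

#' Correlation between F_ROH and F_HOM
#'
#' Pearson correlation of the two per-individual inbreeding estimates, per
#' population and overall.
#'
#' @param froh named numeric vector of F_ROH (id -> value).
#' @param fhom data.frame from [f_hom()] (or named vector id -> F_HOM).
#' @param populations named vector id -> population, or `NULL` for overall
#'   only.
#' @return data.frame `group`, `n`, `r`; `r` is `NA` (flagged with a warning)
#'   for groups with fewer than 3 individuals or zero variance.
#' @export
corr_froh_fhom <- function(froh, fhom, populations = NULL) {
  if (is.data.frame(fhom)) {
    if (is.null(populations) && "population" %in% names(fhom))
      populations <- setNames(fhom$population, fhom$id)
    fhom <- setNames(fhom$F_HOM, fhom$id)
  }
  ids <- intersect(names(froh), names(fhom))
  one <- function(sel, label) {
    x <- froh[sel]; y <- fhom[sel]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      warning("correlation undefined for group ", label)
      NA_real_
    } else stats::cor(x[ok], y[ok])
    data.frame(group = label, n = sum(ok), r = r, stringsAsFactors = FALSE)
  }
  res <- one(ids, "overall")
  if (!is.null(populations)) {
    for (pp in unique(populations[ids]))
      res <- rbind(res, one(ids[populations[ids] == pp], pp))
  }
  rownames(res) <- NULL
  res
}
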