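#' Assessment configuration
#'
#' All tunable parameters of the one-shot [assess()] pipeline, with the
#' standard conservation-assessment defaults: call rate 0.95, MAF 0.05,
#' HWE 1e-5, individual missingness 0.10; ROH minimum length 1 Mb, maximum
#' gap 1 Mb, one heterozygote and one missing call per run, alpha 0.05;
#' length classes at 5/15/30 Mb; autosome length 2399.4 Mb; a uniform
#' 1 cM/Mb map; and a sustainability flag when recent Ne falls below 100.
#'
#' @param ... overrides of the defaults listed above; unknown names error.
#' @return A named list of parameters (class `assess_config`).
#' @export
assess_config <- function(...) {
  cfg <- list(call_rate = 0.95, maf = 0.05, hwe_p = 1e-5, mind = 0.10,
              n_autosomes = 29L,
              roh_min_length_mb = 1, roh_max_gap_mb = 1, roh_max_het = 1,
              roh_max_missing = 1, roh_alpha = 0.05,
              L_auto_mb = 2399.4,
              maf_polymorphic = 0.01,
              family_threshold = 0.25,
              rate_cm_per_mb = 1.0, alpha_model = 1, r2_correction = "1/n",
              ne_bins = NULL, ne_min_pairs = 300,
              ne_threshold = 100)
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown)) stop("unknown config parameter(s): ",
                              paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = c("assess_config", "list"))
}

#' Read an assessment configuration from a YAML or JSON file
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return An `assess_config` with the file's values overriding defaults.
#' @export
read_assess_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(assess_config, vals)
}

#' One-shot conservation assessment
#'
#' Runs the full analysis chain on a genotype dataset: quality control,
#' per-population diversity, genomic relationships (GRM, inbreeding,
#' normalized relationships, NJ tree, PCA, family clusters), runs of
#' homozygosity with genome/chromosome/length-class inbreeding and the
#' F_ROH-F_HOM correlation, and an LD-based Ne trajectory per population.
#' Populations whose most recent Ne estimate falls below
#' `config$ne_threshold` are flagged.
#'
#' @param g a `genotypes` object (or a PLINK prefix: a character path is
#'   loaded with [read_bed_bim_fam()] if a `.bed` exists, else
#'   [read_ped_map()]).
#' @param config an [assess_config()].
#' @param out_dir optional directory; when given, every intermediate artifact
#'   is written there (CSV/JSON/Newick).
#' @return An object of class `assessment` with elements `qc`, `diversity`,
#'   `grm`, `inbreeding_grm`, `tree`, `pca`, `families`, `roh`, `inbreeding`
#'   (per-individual F_ROH & F_HOM), `roh_class_means`, `froh_fhom_corr`,
#'   `ne` (named list of `ne_trajectory` per population), `ne_recent`,
#'   `flags`, `config`.
#' @export
assess <- function(g, config = assess_config(), out_dir = NULL) {
  if (is.character(g)) {
    g <- if (file.exists(paste0(g, ".bed"))) read_bed_bim_fam(g)
         else read_ped_map(paste0(g, ".ped"), paste0(g, ".map"))
  }
  stopifnot(inherits(g, "genotypes"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("assessment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  qc <- stage("qc", run_qc(g, call_rate = config$call_rate, maf = config$maf,
                           hwe_p = config$hwe_p, mind = config$mind,
                           n_autosomes = config$n_autosomes))
  gq <- qc$genotypes

  div <- stage("diversity",
               diversity_summary(gq, maf_threshold = config$maf_polymorphic))

  grm <- stage("relationship", grm_vanraden(gq))
  f_g <- genomic_inbreeding_from_grm(grm)
  R <- normalize_grm(grm)
  fam <- family_clusters(R, gq$individuals$population,
                         threshold = config$family_threshold)
  D <- ibs_distance(gq)
  tree <- if (n_individuals(gq) >= 3) stage("nj", nj_tree(D)) else NULL
  pca <- stage("pca", pca_from_grm(grm, k = min(2, n_individuals(gq) - 1)))

  params <- roh_params(min_length_mb = config$roh_min_length_mb,
                       max_gap_mb = config$roh_max_gap_mb,
                       max_het = config$roh_max_het,
                       max_missing = config$roh_max_missing,
                       alpha = config$roh_alpha)
  roh <- stage("roh", detect_roh(gq, params))
  L_auto_bp <- config$L_auto_mb * 1e6
  froh <- f_roh_genome(roh, L_auto_bp = L_auto_bp)
  fhom <- f_hom(gq)
  cls <- f_roh_by_class(roh, L_auto_bp = L_auto_bp)
  corr <- stage("correlation",
                suppressWarnings(corr_froh_fhom(froh, fhom)))
  inb <- data.frame(id = names(froh),
                    population = gq$individuals$population[
                      match(names(froh), gq$individuals$id)],
                    F_ROH = as.numeric(froh),
                    F_HOM = fhom$F_HOM[match(names(froh), fhom$id)],
                    stringsAsFactors = FALSE)

  ne <- list(); ne_recent <- c()
  for (pp in unique(gq$individuals$population)) {
    tr <- tryCatch(
      ne_trajectory(gq, population = pp, bins = config$ne_bins,
                    rate_cm_per_mb = config$rate_cm_per_mb,
                    alpha_model = config$alpha_model,
                    correction = config$r2_correction,
                    min_pairs = config$ne_min_pairs),
      error = function(e) NULL)
    ne[[pp]] <- tr
    ne_recent[pp] <- if (!is.null(tr)) tr$Ne[1] else NA_real_
  }
  flags <- names(ne_recent)[!is.na(ne_recent) & ne_recent < config$ne_threshold]

  res <- structure(list(qc = qc$report, diversity = div, grm = grm,
                        inbreeding_grm = f_g, tree = tree, pca = pca,
                        families = fam, roh = roh, inbreeding = inb,
                        roh_class_means = cls$population_means_pct,
                        froh_fhom_corr = corr, ne = ne, ne_recent = ne_recent,
                        flags = flags, config = config),
                   class = "assessment")
  if (!is.null(out_dir)) write_assessment(res, out_dir)
  res
}

#' @export
print.assessment <- function(x, ...) {
  cat("== Conservation assessment ==\n\n")
  print(x$qc)
  cat("\n")
  print(x$diversity)
  nf <- attr(x$families, "n_families")
  cat("\nFamily groups (relationship >= ", x$config$family_threshold, "): ",
      paste(sprintf("%s: %d", names(nf), nf), collapse = ", "), "\n", sep = "")
  cat("\nInbreeding (population means):\n")
  ag <- stats::aggregate(cbind(F_ROH, F_HOM) ~ population, x$inbreeding, mean)
  print(ag, row.names = FALSE)
  cat("\nF_ROH/F_HOM correlation:\n")
  print(x$froh_fhom_corr, row.names = FALSE)
  cat("\nMost recent Ne estimates:\n")
  for (pp in names(x$ne_recent))
    cat(sprintf("  %s: %s\n", pp,
                ifelse(is.na(x$ne_recent[pp]), "not estimable",
                       sprintf("%.0f", x$ne_recent[pp]))))
  if (length(x$flags))
    cat("\nFLAG: recent Ne below ", x$config$ne_threshold, " for: ",
        paste(x$flags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write assessment artifacts
#'
#' Writes every component of an [assess()] result to a directory: QC report
#' (JSON + TSV), diversity and inbreeding tables (CSV), GRM and PCA (CSV),
#' family assignment (CSV), ROH segments (CSV), Ne trajectories (CSV), the
#' NJ tree (Newick), and a combined machine-readable `report.json`.
#'
#' @param x an `assessment`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_assessment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pj <- function(...) file.path(dir, ...)
  qc <- list(initial_snps = x$qc$initial_snps, steps = x$qc$steps,
             final_snps = x$qc$final_snps,
             excluded_individuals = x$qc$excluded_individuals)
  jsonlite::write_json(qc, pj("qc_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(x$qc$steps, pj("qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(x$diversity), pj("diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(x$grm$G), x$grm$G,
                              check.names = FALSE),
                   pj("grm.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(x$pca$coordinates),
                              x$pca$coordinates,
                              check.names = FALSE),
                   pj("pca.csv"), row.names = FALSE)
  utils::write.csv(x$families, pj("families.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(x$roh), pj("roh_segments.csv"),
                   row.names = FALSE)
  utils::write.csv(x$inbreeding, pj("inbreeding.csv"), row.names = FALSE)
  if (!is.null(x$tree)) ape::write.tree(x$tree, pj("nj_tree.nwk"))
  for (pp in names(x$ne))
    if (!is.null(x$ne[[pp]]))
      utils::write.csv(as.data.frame(x$ne[[pp]]),
                       pj(sprintf("ne_%s.csv", pp)), row.names = FALSE)
  summary <- list(
    populations = names(x$ne_recent),
    ne_recent = as.list(x$ne_recent),
    flags = x$flags,
    froh_fhom_corr = x$froh_fhom_corr,
    family_counts = as.list(attr(x$families, "n_families")))
  jsonlite::write_json(summary, pj("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}
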