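#' Genotype matrix container
#'
#' Bundles a diploid biallelic dosage matrix (individuals x SNPs, entries 0/1/2
#' counting copies of `allele_b`, `NA` for missing) with its SNP map and
#' per-individual population labels. All analysis functions in the package take
#' this object as input. On construction SNPs are sorted by (chromosome,
#' position); individual order is never changed.
#'
#' @param dosage integer matrix, individuals in rows, SNPs in columns.
#' @param snps data.frame with columns `id`, `chrom` (integer; 0 = unplaced),
#'   `pos_bp` (integer base pairs), `allele_a`, `allele_b` (single characters;
#'   `allele_b` is the counted allele and may be `NA` for monomorphic SNPs).
#' @param individuals data.frame with columns `id` (unique) and `population`.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(dosage, snps, individuals) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(snps), is.data.frame(individuals))
  req_snp <- c("id", "chrom", "pos_bp", "allele_a", "allele_b")
  if (!all(req_snp %in% names(snps)))
    stop("snps must have columns: ", paste(req_snp, collapse = ", "))
  if (!all(c("id", "population") %in% names(individuals)))
    stop("individuals must have columns: id, population")
  if (nrow(dosage) != nrow(individuals))
    stop("dosage rows (", nrow(dosage), ") != individuals (", nrow(individuals), ")")
  if (ncol(dosage) != nrow(snps))
    stop("dosage columns (", ncol(dosage), ") != snps (", nrow(snps), ")")
  if (anyDuplicated(individuals$id))
    stop("duplicate individual ids")
  snps$chrom <- as.integer(snps$chrom)
  snps$pos_bp <- as.integer(snps$pos_bp)
  if (any(snps$pos_bp < 0, na.rm = TRUE)) stop("negative SNP positions")
  if (any(snps$chrom < 0, na.rm = TRUE)) stop("negative chromosome labels")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  ord <- order(snps$chrom, snps$pos_bp)
  snps <- snps[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(snps) <- NULL
  rownames(individuals) <- NULL
  dimnames(dosage) <- list(individuals$id, snps$id)
  structure(list(dosage = dosage, snps = snps, individuals = individuals),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage), "SNPs\n")
  chrs <- unique(x$snps$chrom)
  cat("  chromosomes:", length(chrs),
      sprintf("(%s)", paste(range(chrs), collapse = "-")), "\n")
  pops <- table(x$individuals$population)
  cat("  populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / SNPs
#' @param g a `genotypes` object.
#' @return integer count.
#' @export
n_individuals <- function(g) nrow(g$dosage)

#' @rdname n_individuals
#' @export
n_snps <- function(g) ncol(g$dosage)

#' Subset a genotype matrix
#'
#' Retains the requested individuals and/or SNPs, preserving current order.
#'
#' @param g a `genotypes` object.
#' @param individuals character vector of individual ids, or `NULL` for all.
#' @param snps character vector of SNP ids, or `NULL` for all.
#' @return A `genotypes` object.
#' @export
subset_genotypes <- function(g, individuals = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotypes"))
  ri <- seq_len(nrow(g$dosage))
  ci <- seq_len(ncol(g$dosage))
  if (!is.null(individuals)) {
    unknown <- setdiff(individuals, g$individuals$id)
    if (length(unknown))
      stop("unknown individual id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
    ri <- ri[g$individuals$id %in% individuals]
  }
  if (!is.null(snps)) {
    unknown <- setdiff(snps, g$snps$id)
    if (length(unknown))
      stop("unknown SNP id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
    ci <- ci[g$snps$id %in% snps]
  }
  genotypes(g$dosage[ri, ci, drop = FALSE],
            g$snps[ci, , drop = FALSE],
            g$individuals[ri, , drop = FALSE])
}

# rows of `g$dosage` for a population label (or all rows if NULL)
pop_rows <- function(g, population = NULL) {
  if (is.null(population)) return(seq_len(nrow(g$dosage)))
  r <- which(g$individuals$population %in% population)
  if (!length(r)) stop("no individuals in population ", paste(population, collapse = ","))
  r
}
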