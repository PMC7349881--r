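#' Read PLINK PED/MAP text genotypes
#'
#' Parses a PLINK 1.x text fileset into a [genotypes()] object. Dosage counts
#' copies of `allele_b`, the minor allele as observed in the file (the less
#' frequent of the two alleles by count; equal counts are broken
#' alphabetically, the alphabetically first allele becoming `allele_a`). This
#' per-dataset assignment is recorded in the SNP table, and because allele
#' counts survive a write/read cycle it makes [write_ped_map()] followed by
#' `read_ped_map()` an exact identity. "0 0" genotype pairs become missing
#' (`NA`). The family-ID column of the PED file is used as the population
#' label.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (columns: chrom, id, genetic position,
#'   bp position; the genetic-position column is read but ignored).
#' @return A `genotypes` object with SNPs sorted by (chrom, pos_bp).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4) stop("MAP file must have 4 columns, found ", ncol(map))
  snps <- data.frame(id = map[[2]],
                     chrom = as.integer(map[[1]]),
                     pos_bp = as.integer(round(as.numeric(map[[4]]))),
                     allele_a = NA_character_, allele_b = NA_character_,
                     stringsAsFactors = FALSE)
  m <- nrow(snps)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  expected <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != expected))
    stop("PED row(s) with ", paste(unique(lens[lens != expected]), collapse = ","),
         " fields; expected ", expected, " for ", m, " SNPs")
  fam <- vapply(toks, `[[`, "", 1L)
  iid <- vapply(toks, `[[`, "", 2L)
  a1 <- matrix("", n, m); a2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    al <- toks[[i]][-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m, 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, 2L)]
  }
  dosage <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0" & x2 != "0"
    counts <- table(c(x1[ok], x2[ok]))
    if (length(counts) > 2)
      stop("non-biallelic SNP: ", snps$id[j], " (alleles ",
           paste(names(counts), collapse = ","), ")")
    alleles <- names(counts)
    if (length(alleles) == 2) {
      # allele_b = minor-by-observation; equal counts broken alphabetically
      if (counts[1] == counts[2]) {
        alleles <- sort(alleles)
      } else {
        alleles <- alleles[order(-as.integer(counts))]
      }
      snps$allele_a[j] <- alleles[1]
      snps$allele_b[j] <- alleles[2]
    } else if (length(alleles) == 1) {
      snps$allele_a[j] <- alleles[1]
    }
    b <- snps$allele_b[j]
    d <- rep(NA_integer_, n)
    if (is.na(b)) {
      d[ok] <- 0L
    } else {
      d[ok] <- (x1[ok] == b) + (x2[ok] == b)
    }
    dosage[, j] <- d
  }
  genotypes(dosage, snps,
            data.frame(id = iid, population = fam, stringsAsFactors = FALSE))
}

#' Write PLINK PED/MAP text genotypes
#'
#' Inverse of [read_ped_map()]: `read_ped_map()` on the output reproduces the
#' input object exactly (dosage, SNP order, labels). Missing genotypes are
#' written as "0 0"; monomorphic SNPs (no `allele_b`) are written as
#' homozygous `allele_a`.
#'
#' @param g a `genotypes` object.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_ped_map <- function(g, prefix) {
  stopifnot(inherits(g, "genotypes"))
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(g$snps$chrom, g$snps$id, rep(0, nrow(g$snps)), g$snps$pos_bp),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  a <- g$snps$allele_a; b <- g$snps$allele_b
  a[is.na(a)] <- "0"
  bfill <- ifelse(is.na(b), a, b)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    d <- g$dosage[i, ]
    x1 <- ifelse(is.na(d), "0", ifelse(d >= 1, bfill, a))
    x2 <- ifelse(is.na(d), "0", ifelse(d == 2, bfill, a))
    al <- character(2 * m)
    if (m > 0) {
      al[seq(1, 2 * m, 2)] <- x1
      al[seq(2, 2 * m, 2)] <- x2
    }
    writeLines(paste(c(g$individuals$population[i], g$individuals$id[i],
                       "0", "0", "0", "-9", al), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK BED/BIM/FAM binary genotypes
#'
#' Reads a SNP-major PLINK 1 binary fileset. The BIM A1 allele is taken as
#' `allele_b` (the counted allele) and A2 as `allele_a`, matching PLINK's
#' minor-allele-first convention, so 2-bit code 00 decodes to dosage 2,
#' 10 to 1, 11 to 0 and 01 to missing.
#'
#' @param prefix path prefix of the `.bed`, `.bim`, `.fam` files.
#' @return A `genotypes` object.
#' @export
read_bed_bim_fam <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  bm <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bm) != 6) stop("BIM file must have 6 columns")
  fm <- utils::read.table(fam, header = FALSE, colClasses = "character")
  n <- nrow(fm); m <- nrow(bm)
  snps <- data.frame(id = bm[[2]],
                     chrom = as.integer(bm[[1]]),
                     pos_bp = as.integer(round(as.numeric(bm[[4]]))),
                     allele_a = ifelse(bm[[6]] == "0", NA_character_, bm[[6]]),
                     allele_b = ifelse(bm[[5]] == "0", NA_character_, bm[[5]]),
                     stringsAsFactors = FALSE)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files are supported")
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3 != bps * m)
    stop("BED payload size does not match BIM/FAM dimensions")
  body <- raw[-(1:3)]
  # decode 2-bit codes: 00->2 (A1 hom), 10->1 (het), 11->0 (A2 hom), 01->NA
  lut <- c(2L, NA_integer_, 1L, 0L)  # index by code + 1
  ints <- as.integer(body)
  codes <- matrix(0L, 4 * bps, m)
  codes[seq(1, 4 * bps, 4), ] <- ints %% 4
  codes[seq(2, 4 * bps, 4), ] <- (ints %/% 4) %% 4
  codes[seq(3, 4 * bps, 4), ] <- (ints %/% 16) %% 4
  codes[seq(4, 4 * bps, 4), ] <- (ints %/% 64) %% 4
  dosage <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  genotypes(dosage, snps,
            data.frame(id = fm[[2]], population = fm[[1]], stringsAsFactors = FALSE))
}

#' Write PLINK BED/BIM/FAM binary genotypes
#'
#' Writes a SNP-major PLINK 1 binary fileset; [read_bed_bim_fam()] on the
#' output reproduces the input exactly. Padding bits in the final byte of each
#' SNP block are zero.
#'
#' @param g a `genotypes` object.
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_bed_bim_fam <- function(g, prefix) {
  stopifnot(inherits(g, "genotypes"))
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  a <- g$snps$allele_a; b <- g$snps$allele_b
  utils::write.table(
    data.frame(g$snps$chrom, g$snps$id, rep(0, nrow(g$snps)), g$snps$pos_bp,
               ifelse(is.na(b), "0", b), ifelse(is.na(a), "0", a)),
    bim, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  ni <- nrow(g$individuals)
  utils::write.table(
    data.frame(g$individuals$population, g$individuals$id, rep(0, ni),
               rep(0, ni), rep(0, ni), rep(-9, ni)),
    fam, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  bps <- ceiling(n / 4)
  # dosage -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bps - n
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    cd <- c(code_of(g$dosage[, j]), rep(0L, pad))
    cm <- matrix(cd, nrow = 4)
    writeBin(as.raw(colSums(cm * mult)), con)
  }
  invisible(c(bed = bed, bim = bim, fam = fam))
}
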