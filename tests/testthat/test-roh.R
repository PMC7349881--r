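test_that("minimum-SNP rule matches direct evaluation and is monotone", {
  # ln(0.25) / ln(0.5) = 2 exactly
  expect_identical(min_snp_threshold(0.25, 1, 1, 0.5), 2L)
  # the medium-density panel regime: 45,041 SNPs, 98 individuals, het 0.385
  expect_identical(min_snp_threshold(0.05, 45041, 98, 0.385), 38L)
  # non-increasing in het
  hs <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(hs, function(h) min_snp_threshold(0.05, 5e4, 100, h), 1L)
  expect_true(all(diff(ls) <= 0))
  expect_error(min_snp_threshold(0.05, 100, 10, 0), "strictly between")
  expect_error(min_snp_threshold(0.05, 100, 10, 1), "strictly between")
})

test_that("ROH scan handles canonical fixtures", {
  # fully heterozygous individual: no segments
  g <- toy_genotypes(matrix(1L, 1, 60), pos = 1:60 * 30000L)
  expect_equal(nrow(detect_roh(g, roh_params(min_snps = 5))), 0)
  # 50 homozygous SNPs spanning ~2 Mb: one segment with all 50 SNPs
  pos <- seq(1e6, 3e6, length.out = 50)
  g2 <- toy_genotypes(matrix(0L, 1, 50), pos = as.integer(pos))
  r2 <- detect_roh(g2, roh_params(min_snps = 40))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_snps, 50)
  expect_equal(r2$start_bp, 1e6)
  expect_equal(r2$end_bp, 3e6)
  # two heterozygotes mid-run split it; pieces retested against thresholds
  d <- rep(0L, 50); d[20] <- 1L; d[30] <- 1L
  g3 <- toy_genotypes(matrix(d, 1), pos = as.integer(pos))
  r3 <- detect_roh(g3, roh_params(min_snps = 10))
  ipos <- as.integer(pos)
  orc <- roh_oracle_chrom(d, ipos, 1e6, 1, 1, 1e6, 10)
  expect_equal(nrow(r3), nrow(orc))
  expect_equal(r3$n_snps, orc$n_snps)
  expect_equal(r3$start_bp, ipos[orc$start_idx])
  expect_equal(r3$end_bp, ipos[orc$end_idx])
  # a > 1 Mb gap always breaks a run
  pos4 <- c(1:30 * 30000L, 1:30 * 30000L + 5e6L)
  g4 <- toy_genotypes(matrix(2L, 1, 60), pos = pos4)
  r4 <- detect_roh(g4, roh_params(min_length_mb = 0.5, min_snps = 10))
  expect_equal(nrow(r4), 2)
})

test_that("ROH scan equals the exhaustive enumerator on random chromosomes", {
  set.seed(55)
  for (rep in 1:200) {
    ch <- random_roh_chrom()
    max_het <- sample(0:2, 1); max_miss <- sample(0:2, 1)
    min_snps <- sample(3:12, 1)
    g <- toy_genotypes(matrix(ch$d, 1), pos = ch$pos)
    got <- detect_roh(g, roh_params(min_length_mb = 1, max_gap_mb = 1,
                                    max_het = max_het, max_missing = max_miss,
                                    min_snps = min_snps))
    want <- roh_oracle_chrom(ch$d, ch$pos, 1e6, max_het, max_miss, 1e6,
                             min_snps)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_bp, ch$pos[want$start_idx])
      expect_equal(got$end_bp, ch$pos[want$end_idx])
      expect_equal(got$n_snps, want$n_snps)
      expect_equal(got$n_het, want$n_het)
      expect_equal(got$n_missing, want$n_missing)
      # every emitted segment satisfies the constraints
      expect_true(all(got$n_het <= max_het))
      expect_true(all(got$n_missing <= max_miss))
      expect_true(all(got$n_snps >= min_snps))
      expect_true(all(got$length_bp >= 1e6))
    }
  }
})

test_that("F_ROH arithmetic: genome-wide, per-chromosome and by class", {
  seg <- data.frame(individual = c("a", "a", "b"), population = "P",
                    chrom = c(1L, 2L, 1L),
                    start_bp = c(1e6, 2e6, 1e6),
                    end_bp = c(240.94e6, 12e6, 3.5e6),
                    n_snps = c(500, 60, 40), n_het = 0L, n_missing = 0L,
                    stringsAsFactors = FALSE)
  seg$length_bp <- seg$end_bp - seg$start_bp
  seg$length_class <- herdassess:::assign_length_class(seg$length_bp)
  expect_equal(seg$length_class, c(">30 Mb", "5-15 Mb", "0-5 Mb"))
  fr <- f_roh_genome(seg, ids = c("a", "b", "c"))
  # single 239.94 Mb segment = 0.1 of the 2399.4 Mb autosome
  expect_equal(unname(fr["b"]), 2.5e6 / 2399.4e6)
  expect_equal(unname(fr["a"]), (239.94e6 + 1e7) / 2399.4e6)
  expect_equal(unname(fr["c"]), 0)
  # class values share the genome denominator so they sum to the total
  cls <- f_roh_by_class(seg, ids = c("a", "b", "c"))
  expect_equal(unname(rowSums(cls$per_individual)), unname(fr),
               tolerance = 1e-12)
  # 31 Mb is in the open-ended class; 30 Mb exactly is too (lower-inclusive)
  expect_equal(herdassess:::assign_length_class(c(31e6, 30e6, 29.99e6)),
               c(">30 Mb", ">30 Mb", "15-30 Mb"))
})

test_that("chromosomal F_ROH divides by SNP-covered length", {
  pos <- as.integer(seq(1e6, 21e6, length.out = 80))
  g <- toy_genotypes(cbind(matrix(0L, 2, 80), matrix(1L, 2, 3)),
                     chrom = c(rep(1L, 80), rep(2L, 3)),
                     pos = c(pos, c(1e6L, 2e6L, 3e6L)))
  # individual 1 fully homozygous on chrom 1 -> chromosomal F_ROH = 1
  g$dosage[2, 1:80] <- 1L    # individual 2 has no ROH
  roh <- detect_roh(g, roh_params(min_snps = 10))
  fc <- f_roh_chromosome(roh, g)
  expect_equal(unname(fc["ind1", "1"]), 1)
  expect_equal(unname(fc["ind2", "1"]), 0)
  # chromosome with < 2 SNPs is excluded with a warning
  g2 <- toy_genotypes(matrix(0L, 1, 31), chrom = c(rep(1L, 30), 3L),
                      pos = c(as.integer(seq(1e6, 4e6, length.out = 30)), 5e6L))
  roh2 <- detect_roh(g2, roh_params(min_snps = 5))
  expect_warning(fc2 <- f_roh_chromosome(roh2, g2), "< 2 SNPs")
  expect_false("3" %in% colnames(fc2))
})

test_that("mean summed ROH per class divides by population size", {
  seg <- data.frame(individual = "a", population = "P", chrom = 1L,
                    start_bp = 1e6, end_bp = 11e6, n_snps = 50, n_het = 0L,
                    n_missing = 0L, stringsAsFactors = FALSE)
  seg$length_bp <- seg$end_bp - seg$start_bp
  seg$length_class <- herdassess:::assign_length_class(seg$length_bp)
  m <- mean_sum_roh_by_class(seg, populations = c(a = "P", b = "P"))
  expect_equal(unname(m["P", "5-15 Mb"]), 5)   # 10 Mb over 2 individuals
  expect_equal(sum(m), 5)
  empty <- seg[0, ]
  m0 <- mean_sum_roh_by_class(empty, populations = c(a = "P"))
  expect_equal(sum(m0), 0)
})

test_that("F_ROH/F_HOM correlation has the expected algebraic behaviour", {
  froh <- setNames(seq(0, 0.3, length.out = 20), paste0("i", 1:20))
  fhom <- 2 * froh + 0.01
  expect_equal(corr_froh_fhom(froh, fhom)$r, 1.0)
  set.seed(99)
  a <- setNames(runif(1000), paste0("i", 1:1000))
  b <- setNames(runif(1000), paste0("i", 1:1000))
  expect_lt(abs(corr_froh_fhom(a, b)$r), 0.1)
  expect_warning(corr_froh_fhom(froh[1:2], fhom[1:2]), "undefined")
})

test_that("detected segments recover true IBD segments of a pedigree", {
  base <- le_base(n = 12, n_chrom = 6, chrom_length_bp = 1e8,
                  n_snps_per_chrom = 1000, seed = 4242)
  des <- fullsib_design(base$individuals$id, nf = 6, n_off = 6)
  ps <- simulate_pedigree(base, des, seed = 4343)
  off <- ps$truth$pedigree$id[grepl("^O", ps$truth$pedigree$id)]
  go <- subset_genotypes(ps$genotypes, individuals = off)
  roh <- detect_roh(go, roh_params())
  # Jaccard overlap between detected and true autozygous intervals >= 1 Mb
  jac <- vapply(off, function(id) {
    L <- 0; I <- 0; U <- 0
    for (ch in 1:6) {
      tru <- ps$truth$ibd_segments
      tru <- tru[tru$individual == id & tru$chrom == ch &
                   tru$length_bp >= 1e6, , drop = FALSE]
      det <- roh[roh$individual == id & roh$chrom == ch, , drop = FALSE]
      cover <- function(df, grid) {
        x <- rep(FALSE, length(grid))
        for (k in seq_len(nrow(df)))
          x <- x | (grid >= df$start_bp[k] & grid <= df$end_bp[k])
        x
      }
      grid <- seq(1, 1e8, by = 1e5)
      a <- cover(tru, grid); b <- cover(det, grid)
      I <- I + sum(a & b); U <- U + sum(a | b)
    }
    if (U == 0) NA_real_ else I / U
  }, numeric(1))
  expect_gt(mean(jac, na.rm = TRUE), 0.8)
})
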