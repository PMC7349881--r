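# Small in-code fixtures used across test files.

# genotypes object from a plain dosage matrix; one chromosome unless
# chrom/pos supplied
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL, pops = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  n <- nrow(dosage)
  if (is.null(pops)) pops <- rep("P1", n)
  genotypes(dosage,
            data.frame(id = paste0("snp", seq_len(m)), chrom = chrom,
                       pos_bp = pos, allele_a = "A", allele_b = "B",
                       stringsAsFactors = FALSE),
            data.frame(id = paste0("ind", seq_len(n)), population = pops,
                       stringsAsFactors = FALSE))
}

# random dosage matrix with missingness
random_dosage <- function(n, m, miss = 0.05) {
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  d[runif(n * m) < miss] <- NA
  d
}

# mating plan: nf families, each 2 base parents -> 2 sibs -> n_off
# full-sib-mating offspring named O<f>_<j>
fullsib_design <- function(founder_ids, nf, n_off) {
  do.call(rbind, lapply(seq_len(nf), function(f) {
    p1 <- founder_ids[2 * f - 1]; p2 <- founder_ids[2 * f]
    rbind(
      data.frame(sire = p1, dam = p2, n_offspring = 2,
                 prefix = paste0("S", f), stringsAsFactors = FALSE),
      data.frame(sire = paste0("S", f, "_1"), dam = paste0("S", f, "_2"),
                 n_offspring = n_off, prefix = paste0("O", f),
                 stringsAsFactors = FALSE))
  }))
}

# near-linkage-equilibrium base population: one generation of random mating
# from a large founder pool, so sampled individuals are essentially unrelated
le_base <- function(n, n_chrom, chrom_length_bp, n_snps_per_chrom, seed,
                    pool = 500) {
  simulate_wf(sim_config(n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
                         n_snps_per_chrom = n_snps_per_chrom,
                         ne_trajectory = data.frame(generation = 1, N = pool),
                         n_sample = n, seed = seed),
              population = "BASE")$genotypes
}
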