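test_that("VanRaden GRM matches hand evaluation and a loop oracle", {
  # two individuals, one SNP, dosages (0, 2), p = 0.5:
  # Z = (-1, 1), denominator = 2 * 0.25 = 0.5 -> G = [[2,-2],[-2,2]]
  g <- toy_genotypes(matrix(c(0L, 2L), 2, 1))
  fr <- allele_freqs(g)
  G <- grm_vanraden(g, fr)
  expect_equal(unname(G$G), matrix(c(2, -2, -2, 2), 2, 2))
  expect_equal(G$denominator, 0.5)
  # loop oracle on a random matrix
  set.seed(31)
  d <- random_dosage(30, 500, miss = 0.04)
  g2 <- toy_genotypes(d, pos = 1:500 * 1000L)
  fr2 <- allele_freqs(g2)
  G2 <- grm_vanraden(g2, fr2)
  expect_lt(max(abs(G2$G - grm_oracle(d, fr2$p))), 1e-10)
  expect_lt(max(abs(G2$G - t(G2$G))), 1e-10)
  # an all-missing individual has centered row 0: off-diagonals all 0
  d[3, ] <- NA
  g3 <- toy_genotypes(d, pos = 1:500 * 1000L)
  G3 <- grm_vanraden(g3, allele_freqs(g3))
  expect_equal(unname(G3$G[3, -3]), rep(0, 29))
  # degenerate: everything monomorphic
  expect_error(grm_vanraden(toy_genotypes(matrix(0L, 3, 4))), "denominator")
})

test_that("GRM diagonal minus one behaves like an inbreeding coefficient", {
  expect_equal(genomic_inbreeding_from_grm(matrix(c(1, 0, 0, 1), 2, 2)),
               c(0, 0))
  g <- toy_genotypes(matrix(c(0L, 2L), 2, 1))
  G <- grm_vanraden(g, allele_freqs(g))
  expect_equal(unname(genomic_inbreeding_from_grm(G)), c(1, 1))
  # outbred simulated cohort: diagonal near 1, off-diagonal near 0, F near 0
  g2 <- le_base(n = 40, n_chrom = 5, chrom_length_bp = 5e7,
                n_snps_per_chrom = 400, seed = 313)
  G2 <- grm_vanraden(g2)
  expect_lt(abs(mean(diag(G2$G)) - 1), 0.05)
  # with frequencies estimated from the sample itself the off-diagonal mean
  # sits at -1/(n-1) by the centering constraint, approaching 0 with n
  expect_lt(abs(mean(G2$G[upper.tri(G2$G)]) + 1 / 39), 0.01)
  expect_lt(abs(mean(genomic_inbreeding_from_grm(G2))), 0.05)
})

test_that("full-sib-mating offspring have mean genomic inbreeding near 0.25", {
  base <- le_base(n = 24, n_chrom = 8, chrom_length_bp = 8e7,
                  n_snps_per_chrom = 500, seed = 2024)
  des <- fullsib_design(base$individuals$id, nf = 12, n_off = 10)
  ps <- simulate_pedigree(base, des, seed = 55)
  off <- ps$truth$pedigree$id[grepl("^O", ps$truth$pedigree$id)]
  expect_equal(unique(ps$truth$pedigree$F[ps$truth$pedigree$id %in% off]), 0.25)
  # reference frequencies from the outbred base population
  Gall <- grm_vanraden(ps$genotypes, allele_freqs(base))
  fg <- genomic_inbreeding_from_grm(Gall)[off]
  expect_lt(abs(mean(fg) - 0.25), 0.05)
})

test_that("normalization yields unit diagonal and matches elementwise division", {
  G <- matrix(c(2, -2, -2, 2), 2, 2)
  expect_equal(normalize_grm(G), matrix(c(1, -1, -1, 1), 2, 2))
  set.seed(17)
  A <- crossprod(matrix(rnorm(64), 8, 8)) / 8 + diag(8) * 0.5
  R <- normalize_grm(A)
  expect_equal(unname(diag(R)), rep(1, 8))
  for (i in 1:8) for (j in 1:8)
    expect_equal(R[i, j], A[i, j] / sqrt(A[i, i] * A[j, j]))
  B <- A; B[2, 2] <- -1
  rownames(B) <- colnames(B) <- paste0("id", 1:8)
  expect_error(normalize_grm(B), "id2")
})

test_that("IBS distance matches definition, limits and loop oracle", {
  g <- toy_genotypes(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(unname(ibs_distance(g)), matrix(0, 2, 2))
  g2 <- toy_genotypes(rbind(rep(0L, 4), rep(2L, 4)))
  expect_equal(unname(ibs_distance(g2)[1, 2]), 1)
  set.seed(61)
  d <- random_dosage(4, 50, miss = 0.1)
  g3 <- toy_genotypes(d, pos = 1:50 * 1000L)
  expect_lt(max(abs(ibs_distance(g3) - ibs_oracle(d))), 1e-12)
})

test_that("NJ reproduces closed-form and additive-tree solutions", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # additive 4-taxon tree: ((A:1,B:2):1,(C:3,D:1)) -> NJ recovers the split
  D4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D4["A", "B"] <- D4["B", "A"] <- 3
  D4["A", "C"] <- D4["C", "A"] <- 5
  D4["A", "D"] <- D4["D", "A"] <- 3
  D4["B", "C"] <- D4["C", "B"] <- 6
  D4["B", "D"] <- D4["D", "B"] <- 4
  D4["C", "D"] <- D4["D", "C"] <- 4
  t4 <- nj_tree(D4)
  expect_true(ape::is.monophyletic(t4, c("A", "B")))
  expect_true(ape::is.monophyletic(t4, c("C", "D")))
  # validation errors
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  Dn <- D; Dn[1, 2] <- 9
  expect_error(nj_tree(Dn), "symmetric")
  Dm <- D; Dm[1, 2] <- Dm[2, 1] <- -1
  expect_error(nj_tree(Dm), "negative")
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(88)
  for (rep in 1:5) {
    n <- 8
    X <- matrix(runif(n * 5), n)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    t1 <- nj_tree(D)
    t2 <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
    # branch lengths agree too (no ties in random distances)
    expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-8)
  }
})

test_that("PCA from the GRM satisfies the eigen definition and separates groups", {
  set.seed(19)
  A <- crossprod(matrix(rnorm(100), 10, 10)) / 10
  pc <- pca_from_grm(A, k = 3)
  expect_lte(sum(pc$variance_explained), 1)
  e <- eigen(A, symmetric = TRUE)
  for (k in 1:3)
    expect_lt(max(abs(A %*% e$vectors[, k] - e$values[k] * e$vectors[, k])),
              1e-8)
  expect_error(pca_from_grm(A, k = 10), "smaller")
  # two diverged populations separate on PC1 with sign-consistent groups
  cfg <- sim_config(n_chrom = 4, chrom_length_bp = 4e7, n_snps_per_chrom = 200,
                    ne_trajectory = data.frame(generation = 1, N = 60),
                    n_sample = 40, seed = 404)
  sb <- simulate_breeds(k = 2, divergence_generations = 40,
                        sizes = c(25, 25), cfg)
  G <- grm_vanraden(sb$genotypes)
  pc2 <- pca_from_grm(G, k = 2)
  pops <- sb$genotypes$individuals$population
  s1 <- pc2$coordinates[pops == "POP1", 1]
  s2 <- pc2$coordinates[pops == "POP2", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("family clustering recovers planted families and is order-invariant", {
  # trivial thresholds
  R <- diag(4) ; R[1, 2] <- R[2, 1] <- 0.6
  rownames(R) <- colnames(R) <- paste0("i", 1:4)
  fam_hi <- family_clusters(R, rep("P", 4), threshold = 0.9)
  expect_equal(length(unique(fam_hi$family)), 4)
  fam <- family_clusters(R, rep("P", 4), threshold = 0.25)
  expect_equal(fam$family[1], fam$family[2])
  expect_equal(length(unique(fam$family)), 3)
  # planted full-sib families in simulation
  base <- le_base(n = 6, n_chrom = 6, chrom_length_bp = 6e7,
                  n_snps_per_chrom = 400, seed = 66)
  des <- fullsib_design(base$individuals$id, nf = 3, n_off = 1)
  # keep only the sib generation: 3 disjoint families of 2 full sibs + their
  # full-sib-mating offspring = 3 members each
  ps <- simulate_pedigree(base, des, seed = 77)
  cohort <- ps$truth$pedigree$id[grepl("^[SO]", ps$truth$pedigree$id)]
  gc <- subset_genotypes(ps$genotypes, individuals = cohort)
  R2 <- normalize_grm(grm_vanraden(gc, allele_freqs(base)))
  fam2 <- family_clusters(R2, rep("P", nrow(R2)), threshold = 0.25)
  expect_equal(length(unique(fam2$family)), 3)
  planted <- sub("_.*", "", sub("^[SO]", "", fam2$id))
  expect_equal(length(unique(paste(planted, fam2$family))), 3)
  # order invariance of the partition
  perm <- sample(nrow(R2))
  fam3 <- family_clusters(R2[perm, perm], rep("P", nrow(R2)),
                          threshold = 0.25)
  sig <- function(fam) sort(vapply(split(fam$id, fam$family),
                                   function(v) paste(sort(v), collapse = ","),
                                   character(1)))
  expect_equal(unname(sig(fam2)), unname(sig(fam3)))
})
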