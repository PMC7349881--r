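#' Simulation configuration
#'
#' Parameters of the forward Wright-Fisher genotype simulator. The default
#' genome emulates a goat-like 50K array design: 29 autosomes of about
#' 82.74 Mb (2399.4 Mb total) carrying ~1550 SNPs each (~45,000 genome-wide),
#' founder allele frequencies uniform on [0.05, 0.5], and a uniform 1 cM/Mb
#' recombination map.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param n_snps_per_chrom SNPs per chromosome (positions drawn uniformly).
#' @param maf_range founder allele-frequency range (uniform draw per site).
#' @param recomb_rate_cm_per_mb uniform recombination rate.
#' @param ne_trajectory data.frame with columns `generation` (increasing,
#'   starting at 1) and `N`: the population size from that generation onward.
#'   The simulation runs to `max(generation)` generations; the default is a
#'   constant size of 100 for 100 generations.
#' @param n_sample individuals sampled (without replacement) from the final
#'   generation.
#' @param seed mandatory RNG seed (integer), for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 29, chrom_length_bp = 82.74e6,
                       n_snps_per_chrom = 1550, maf_range = c(0.05, 0.5),
                       recomb_rate_cm_per_mb = 1.0,
                       ne_trajectory = data.frame(generation = 1, N = 100),
                       n_sample = 50, seed) {
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is mandatory")
  stopifnot(n_chrom >= 1, chrom_length_bp > 0, n_snps_per_chrom >= 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            recomb_rate_cm_per_mb >= 0, n_sample >= 1,
            is.data.frame(ne_trajectory),
            all(c("generation", "N") %in% names(ne_trajectory)),
            all(ne_trajectory$N >= 2), all(diff(ne_trajectory$generation) > 0))
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length_bp = chrom_length_bp,
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 maf_range = maf_range,
                 recomb_rate_cm_per_mb = recomb_rate_cm_per_mb,
                 ne_trajectory = ne_trajectory,
                 n_sample = as.integer(n_sample),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# expand the (generation, N) step trajectory to one N per generation
expand_trajectory <- function(tr) {
  gmax <- max(tr$generation)
  idx <- findInterval(seq_len(gmax), tr$generation)
  as.integer(tr$N[idx])
}

# draw founder haplotypes and a SNP map; returns list(haps, pos_bp, pos_m, snps)
founder_genome <- function(config, n_founders) {
  C <- config$n_chrom
  haps <- vector("list", C); pos_bp <- vector("list", C)
  pos_m <- vector("list", C); p0 <- vector("list", C)
  for (c in seq_len(C)) {
    pos <- sort(sample.int(config$chrom_length_bp, config$n_snps_per_chrom))
    p <- runif(config$n_snps_per_chrom, config$maf_range[1], config$maf_range[2])
    h <- matrix(rbinom(2 * n_founders * config$n_snps_per_chrom, 1L,
                       rep(p, each = 2 * n_founders)),
                nrow = 2 * n_founders)
    haps[[c]] <- h
    pos_bp[[c]] <- pos
    pos_m[[c]] <- pos * config$recomb_rate_cm_per_mb / 1e8
    p0[[c]] <- p
  }
  snps <- data.frame(
    id = sprintf("snp%d_%d", rep(seq_len(C), vapply(pos_bp, length, 1L)),
                 unlist(lapply(pos_bp, seq_along))),
    chrom = rep(seq_len(C), vapply(pos_bp, length, 1L)),
    pos_bp = unlist(pos_bp),
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  list(haps = haps, pos_bp = pos_bp, pos_m = pos_m, snps = snps,
       founder_freqs = unlist(p0))
}

# assemble a genotypes object from per-chromosome haplotype matrices for the
# given individual indices; flips columns so allele_b is the observed minor
# allele (canonical PED-compatible coding)
haps_to_genotypes <- function(haps, snps, idx, ids, populations) {
  dos <- do.call(cbind, lapply(haps, function(h) {
    h[2 * idx - 1, , drop = FALSE] + h[2 * idx, , drop = FALSE]
  }))
  storage.mode(dos) <- "integer"
  freq <- colMeans(dos) / 2
  flip <- freq > 0.5
  if (any(flip)) {
    dos[, flip] <- 2L - dos[, flip]
    aa <- snps$allele_a
    snps$allele_a[flip] <- snps$allele_b[flip]
    snps$allele_b[flip] <- aa[flip]
  }
  genotypes(dos, snps,
            data.frame(id = ids, population = populations,
                       stringsAsFactors = FALSE))
}

#' Forward Wright-Fisher simulation
#'
#' Discrete-generation diploid Wright-Fisher simulation: each offspring draws
#' two distinct parents uniformly at random; each inherited haplotype is a
#' recombinant of the parent's two haplotypes with crossovers as a Poisson
#' process along the uniform genetic map. Founder haplotypes are drawn
#' site-wise from the configured allele-frequency distribution (linkage
#' equilibrium). The final generation is sampled without replacement. The
#' same seed always yields identical output.
#'
#' @param config a [sim_config()] object.
#' @param population label attached to the sampled individuals.
#' @return List with `genotypes` (a `genotypes` object) and `truth` (list:
#'   `n_per_generation`, `founder_freqs`, `seed`).
#' @export
simulate_wf <- function(config, population = "SIM") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_per_gen <- expand_trajectory(config$ne_trajectory)
  n0 <- n_per_gen[1]
  fg <- founder_genome(config, n0)
  haps <- wf_evolve_cpp(fg$haps, fg$pos_m, n_per_gen)
  n_final <- n_per_gen[length(n_per_gen)]
  if (config$n_sample > n_final)
    stop("n_sample (", config$n_sample, ") exceeds final population size (",
         n_final, ")")
  idx <- sort(sample.int(n_final, config$n_sample))
  ids <- sprintf("%s_%03d", population, seq_len(config$n_sample))
  g <- haps_to_genotypes(haps, fg$snps, idx, ids,
                         rep(population, config$n_sample))
  list(genotypes = g,
       truth = list(n_per_generation = n_per_gen,
                    founder_freqs = fg$founder_freqs, seed = config$seed))
}

#' Simulate diverged populations ("breeds")
#'
#' One ancestral Wright-Fisher run (per `config`) is split into `k` isolated
#' populations that then evolve independently for `divergence_generations`
#' generations at the given census `sizes`; all final individuals are
#' returned, labelled.
#'
#' @param k number of populations (>= 2).
#' @param divergence_generations generations of isolated drift after the
#'   split (0 = populations are exchangeable samples of the ancestor).
#' @param sizes integer vector of length `k`: population sizes (also the
#'   output sample sizes).
#' @param config a [sim_config()] describing the ancestral population.
#' @param labels population labels (default `POP1..POPk`).
#' @return List with `genotypes` (labelled, all populations) and `truth`.
#' @export
simulate_breeds <- function(k, divergence_generations, sizes, config,
                            labels = NULL) {
  stopifnot(k >= 2, length(sizes) == k, all(sizes >= 2),
            inherits(config, "sim_config"))
  if (is.null(labels)) labels <- sprintf("POP%d", seq_len(k))
  set.seed(config$seed)
  n_per_gen <- expand_trajectory(config$ne_trajectory)
  n0 <- n_per_gen[1]
  fg <- founder_genome(config, n0)
  anc <- wf_evolve_cpp(fg$haps, fg$pos_m, n_per_gen)
  n_anc <- n_per_gen[length(n_per_gen)]
  per_pop <- vector("list", k)
  for (b in seq_len(k)) {
    if (divergence_generations > 0) {
      hb <- wf_evolve_cpp(anc, fg$pos_m,
                          rep(as.integer(sizes[b]), divergence_generations))
      per_pop[[b]] <- lapply(hb, function(h) h)
    } else {
      idx <- sample.int(n_anc, sizes[b])
      per_pop[[b]] <- lapply(anc, function(h) {
        h[as.vector(rbind(2 * idx - 1, 2 * idx)), , drop = FALSE]
      })
    }
  }
  haps <- lapply(seq_along(per_pop[[1]]), function(c) {
    do.call(rbind, lapply(per_pop, `[[`, c))
  })
  n_tot <- sum(sizes)
  ids <- unlist(lapply(seq_len(k), function(b)
    sprintf("%s_%03d", labels[b], seq_len(sizes[b]))))
  pops <- rep(labels, sizes)
  g <- haps_to_genotypes(haps, fg$snps, seq_len(n_tot), ids, pops)
  list(genotypes = g,
       truth = list(sizes = setNames(as.integer(sizes), labels),
                    divergence_generations = divergence_generations,
                    founder_freqs = fg$founder_freqs, seed = config$seed))
}

#' Simulate a pedigree with identity-by-descent truth
#'
#' Drops gametes with recombination through an explicit mating plan, tracking
#' the founder origin of every chromosomal segment. True autozygous (IBD)
#' segments of each individual are the intervals where both haplotypes
#' descend from the same founder haplotype (reported at marker resolution);
#' true pedigree inbreeding F is computed by the tabular kinship method.
#' Founder genotypes are taken from `base` and phased randomly (sites are in
#' linkage equilibrium in a [simulate_wf()] founder draw, so random phasing
#' is exact for that case).
#'
#' @param base a `genotypes` object supplying the founders (all individuals).
#' @param design mating plan: data.frame with columns `sire`, `dam`,
#'   `n_offspring` and optionally `prefix`; rows are executed in order and
#'   may reference previously created offspring. Offspring of row `r` are
#'   named `<prefix>_<j>` (default prefix `Xr`). Selfing is rejected.
#' @param seed RNG seed.
#' @param rate_cm_per_mb recombination rate of the gamete map.
#' @return List with `genotypes` (founders + offspring), `truth` (list:
#'   `pedigree` data.frame id/sire/dam/F, `ibd_segments` data.frame
#'   individual/chrom/start_bp/end_bp/length_bp).
#' @export
simulate_pedigree <- function(base, design, seed, rate_cm_per_mb = 1.0) {
  stopifnot(inherits(base, "genotypes"), is.data.frame(design),
            all(c("sire", "dam", "n_offspring") %in% names(design)))
  set.seed(seed)
  chroms <- unique(base$snps$chrom)
  cols_by_chrom <- lapply(chroms, function(ch) which(base$snps$chrom == ch))
  pos_m <- lapply(cols_by_chrom, function(cc)
    base$snps$pos_bp[cc] * rate_cm_per_mb / 1e8)
  founders <- base$individuals$id
  # phased storage: per individual, per chromosome, 2 x S allele and origin
  A <- list(); O <- list()
  for (f in seq_along(founders)) {
    id <- founders[f]
    A[[id]] <- list(); O[[id]] <- list()
    for (c in seq_along(chroms)) {
      d <- base$dosage[f, cols_by_chrom[[c]]]
      d[is.na(d)] <- 0L  # founders assumed fully genotyped
      h1 <- as.integer(d == 2L); h2 <- h1
      het <- which(d == 1L)
      if (length(het)) {
        first <- runif(length(het)) < 0.5
        h1[het] <- as.integer(first)
        h2[het] <- as.integer(!first)
      }
      A[[id]][[c]] <- rbind(h1, h2)
      O[[id]][[c]] <- rbind(rep(2L * f - 1L, length(d)),
                            rep(2L * f, length(d)))
    }
  }
  ped <- data.frame(id = founders, sire = NA_character_, dam = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(design))) {
    sire <- design$sire[r]; dam <- design$dam[r]
    if (identical(sire, dam)) stop("selfing is not allowed (row ", r, ")")
    for (pid in c(sire, dam))
      if (is.null(A[[pid]])) stop("unknown parent id: ", pid)
    prefix <- if ("prefix" %in% names(design) && !is.na(design$prefix[r]))
      design$prefix[r] else paste0("X", r)
    for (j in seq_len(design$n_offspring[r])) {
      id <- sprintf("%s_%d", prefix, j)
      A[[id]] <- list(); O[[id]] <- list()
      for (c in seq_along(chroms)) {
        g1 <- gamete_cpp(A[[sire]][[c]][1, ], A[[sire]][[c]][2, ],
                         O[[sire]][[c]][1, ], O[[sire]][[c]][2, ], pos_m[[c]])
        g2 <- gamete_cpp(A[[dam]][[c]][1, ], A[[dam]][[c]][2, ],
                         O[[dam]][[c]][1, ], O[[dam]][[c]][2, ], pos_m[[c]])
        A[[id]][[c]] <- rbind(g1[1, ], g2[1, ])
        O[[id]][[c]] <- rbind(g1[2, ], g2[2, ])
      }
      ped <- rbind(ped, data.frame(id = id, sire = sire, dam = dam,
                                   stringsAsFactors = FALSE))
    }
  }
  ped$F <- pedigree_inbreeding(ped)
  # genotypes for the whole pedigree
  ids <- ped$id
  dos <- matrix(0L, length(ids), ncol(base$dosage))
  for (i in seq_along(ids)) {
    dos[i, ] <- unlist(lapply(seq_along(chroms), function(c)
      A[[ids[i]]][[c]][1, ] + A[[ids[i]]][[c]][2, ]))
  }
  pop <- rep("PED", length(ids))
  fidx <- match(founders, ids)
  pop[fidx] <- base$individuals$population
  snps <- base$snps[unlist(cols_by_chrom), , drop = FALSE]
  g <- genotypes(dos, snps, data.frame(id = ids, population = pop,
                                       stringsAsFactors = FALSE))
  # true autozygous segments (marker resolution)
  segs <- vector("list", 0L)
  for (id in setdiff(ids, founders)) {
    for (c in seq_along(chroms)) {
      auto <- O[[id]][[c]][1, ] == O[[id]][[c]][2, ]
      if (!any(auto)) next
      rl <- rle(auto)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      keep <- which(rl$values)
      pos <- base$snps$pos_bp[cols_by_chrom[[c]]]
      for (k in keep) {
        segs[[length(segs) + 1L]] <- data.frame(
          individual = id, chrom = chroms[c],
          start_bp = pos[starts[k]], end_bp = pos[ends[k]],
          stringsAsFactors = FALSE)
      }
    }
  }
  ibd <- if (length(segs)) do.call(rbind, segs) else
    data.frame(individual = character(0), chrom = integer(0),
               start_bp = integer(0), end_bp = integer(0))
  ibd$length_bp <- as.numeric(ibd$end_bp) - as.numeric(ibd$start_bp)
  list(genotypes = g, truth = list(pedigree = ped, ibd_segments = ibd))
}

# tabular-method pedigree inbreeding: F_i = kinship(sire_i, dam_i);
# ids must be ordered parents-before-offspring (construction guarantees it)
pedigree_inbreeding <- function(ped) {
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  Fv <- numeric(n)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) {
      Fv[i] <- phi[si[i], di[i]]
      for (j in seq_len(i - 1))
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[si[i], j] + phi[di[i], j])
    }
    phi[i, i] <- 0.5 * (1 + Fv[i])
  }
  Fv
}
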