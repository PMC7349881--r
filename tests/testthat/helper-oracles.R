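# Independent brute-force oracles. These recompute expected results from the
# definitions, by explicit enumeration or elementwise loops, without sharing
# code with the package internals.

# HWE exact p-value via a combinatorial derivation distinct from the
# package's multinomial form: P(h hets | n, nA) =
#   C(n, h) 2^h C(n - h, (nA - h)/2) / C(2n, nA)
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    choose(n, h) * 2^h * choose(n - h, (nA - h) / 2) / choose(2 * n, nA)
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# exhaustive consecutive-runs enumerator for one chromosome: window validity
# is established by brute-force checks over explicit windows; the left-to-
# right maximal-run selection mirrors the stated scanning policy
roh_oracle_chrom <- function(d, pos, max_gap_bp, max_het, max_miss,
                             min_len_bp, min_snps) {
  S <- length(d)
  hom <- !is.na(d) & d != 1L
  feasible <- function(i, k) {
    w <- d[i:k]
    sum(w == 1L, na.rm = TRUE) <= max_het &&
      sum(is.na(w)) <= max_miss &&
      all(diff(pos[i:k]) <= max_gap_bp)
  }
  out <- list()
  i <- 1L
  while (i <= S) {
    if (!hom[i]) { i <- i + 1L; next }
    k_break <- 0L
    k <- i + 1L
    while (k <= S) {
      if (!feasible(i, k)) { k_break <- k; break }
      k <- k + 1L
    }
    lim <- if (k_break) k_break - 1L else S
    j <- max(which(hom[i:lim])) + i - 1L   # last homozygous call in prefix
    if (j > i && pos[j] - pos[i] >= min_len_bp && (j - i + 1L) >= min_snps)
      out[[length(out) + 1L]] <- data.frame(
        start_idx = i, end_idx = j, n_snps = j - i + 1L,
        n_het = sum(d[i:j] == 1L, na.rm = TRUE),
        n_missing = sum(is.na(d[i:j])))
    if (!k_break) break
    gap_broke <- pos[k_break] - pos[k_break - 1L] > max_gap_bp
    i <- if (gap_broke) k_break else k_break + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_idx = integer(0), end_idx = integer(0),
               n_snps = integer(0), n_het = integer(0),
               n_missing = integer(0))
}

# random chromosome for ROH fuzzing
random_roh_chrom <- function(max_snps = 100) {
  S <- sample(5:max_snps, 1)
  pos <- sort(sample.int(5e6, S))
  d <- sample(c(0L, 0L, 2L, 2L, 1L, NA_integer_), S, replace = TRUE)
  list(d = d, pos = pos)
}

# plain-loop IBS distance
ibs_oracle <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(X[i, ]) & !is.na(X[j, ])
    D[i, j] <- sum(abs(X[i, ok] - X[j, ok])) / (2 * sum(ok))
  }
  D
}

# plain-loop VanRaden GRM
grm_oracle <- function(X, p) {
  n <- nrow(X); m <- ncol(X)
  Z <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    Z[i, j] <- if (is.na(X[i, j]) || is.na(p[j])) 0 else X[i, j] - 2 * p[j]
  }
  den <- 0
  for (j in seq_len(m)) if (!is.na(p[j])) den <- den + 2 * p[j] * (1 - p[j])
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n))
    G[i, k] <- sum(Z[i, ] * Z[k, ]) / den
  G
}
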