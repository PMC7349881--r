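#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair minimizing the Q
#' criterion `Q_ij = (n-2) d_ij - r_i - r_j`, with the standard branch-length
#' formulas. Ties in Q are broken by the lowest (row, column) index pair, so
#' the result is fully deterministic. Negative branch lengths are clamped to
#' zero with a warning (the convention of common tree viewers).
#'
#' @param D symmetric non-negative distance matrix with zero diagonal
#'   (individual ids as dimnames), at least 3 taxa.
#' @return An unrooted `phylo` tree (package \pkg{ape}), serializable with
#'   [ape::write.tree()].
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(D)) stop("distance matrix contains NA")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # working copies; each active node carries a newick fragment
  frag <- labels
  act <- seq_len(n)
  clamped <- FALSE
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (length(act) > 3) {
    m <- length(act)
    d <- D[act, act, drop = FALSE]
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (row, col) tie-break with i < j
    Q[lower.tri(Q)] <- Inf
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    }
    dij <- d[bi, bj]
    li <- clamp(dij / 2 + (r[bi] - r[bj]) / (2 * (m - 2)))
    lj <- clamp(dij - (dij / 2 + (r[bi] - r[bj]) / (2 * (m - 2))))
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[act[bi]], fmt(li),
                       frag[act[bj]], fmt(lj))
    # distances from the new node to the remaining nodes
    others <- act[-c(bi, bj)]
    dnew <- (D[act[bi], others] + D[act[bj], others] - dij) / 2
    u <- act[bi]           # reuse slot bi for the new node
    D[u, others] <- dnew
    D[others, u] <- dnew
    D[u, u] <- 0
    frag[u] <- newfrag
    act <- c(u, others)    # new node first keeps index ordering stable
    act <- sort(act)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- clamp((D[a, b] + D[a, c3] - D[b, c3]) / 2)
  lb <- clamp((D[a, b] + D[b, c3] - D[a, c3]) / 2)
  lc <- clamp((D[a, c3] + D[b, c3] - D[a, b]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], fmt(la),
                 frag[b], fmt(lb), frag[c3], fmt(lc))
  if (clamped) warning("negative NJ branch length(s) clamped to zero")
  ape::read.tree(text = nwk)
}
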