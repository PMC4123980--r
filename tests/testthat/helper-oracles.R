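# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# quick aligned-matrix fixture from equal-length strings
aln_of <- function(...) {
  s <- c(...)
  as_alignment(setNames(s, if (is.null(names(s)))
    paste0("s", seq_along(s)) else names(s)))
}

# K2P by direct formula from hand-counted P and Q
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# connected components of the d <= thr graph by boolean matrix closure
oracle_components <- function(d, thr) {
  n <- nrow(d)
  A <- (!is.na(d) & d <= thr) | diag(n) > 0
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    cid <- cid + 1L
    comp[A[i, ]] <- cid
  }
  comp
}

# exhaustive minimum spanning tree weight via Pruefer enumeration (n <= 7)
oracle_mst_weight <- function(W) {
  n <- nrow(W)
  if (n == 2L) return(W[1, 2])
  decode <- function(pr) {
    degree <- rep(1L, n)
    for (x in pr) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    ptr <- 0L
    pr2 <- pr
    for (k in seq_along(pr2)) {
      leaf <- min(which(degree == 1L))
      ptr <- ptr + 1L
      edges[ptr, ] <- c(leaf, pr2[k])
      degree[leaf] <- 0L
      degree[pr2[k]] <- degree[pr2[k]] - 1L
    }
    last <- which(degree == 1L)
    edges[n - 1L, ] <- last
    edges
  }
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2L))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    ed <- decode(as.integer(grid[r, ]))
    best <- min(best, sum(W[ed]))
  }
  best
}

# exhaustive Fitch score: minimise changes over all internal-state
# assignments of a given tree (pure-ACGT alignment)
oracle_fitch <- function(tree, aln) {
  m <- unclass(aln)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  total <- 0L
  grid <- do.call(expand.grid, c(rep(list(bases), nint),
                                 stringsAsFactors = FALSE))
  for (j in seq_len(ncol(m))) {
    tips <- m[tree$tip.label, j]
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      st <- c(tips, unlist(grid[r, ], use.names = FALSE))
      ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
      best <- min(best, ch)
    }
    total <- total + best
  }
  total
}

# exact Ewens Pr(K >= k) via integer Stirling numbers (n small)
oracle_ewens_tail <- function(n, k_obs, theta) {
  S <- matrix(0, n + 1L, n + 1L)  # |S(i, j)|
  S[1 + 1L, 1 + 1L] <- 1
  if (n >= 2) for (i in 2:n) for (j in 1:i) {
    S[i + 1L, j + 1L] <- S[i, j] + (i - 1) * S[i, j + 1L]
  }
  rising <- prod(theta + 0:(n - 1))
  probs <- vapply(1:n, function(j) S[n + 1L, j + 1L] * theta^j / rising,
                  numeric(1))
  sum(probs[k_obs:n])
}

# random pure-ACGT alignment
random_aln <- function(n, L, labels = paste0("t", seq_len(n))) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(m) <- labels
  as_alignment(m)
}
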