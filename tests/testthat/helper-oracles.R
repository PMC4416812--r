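# Independent reference implementations used to validate the package.
# They are deliberately naive (scalar loops, boolean matrix powers,
# exhaustive pair counting) and share no code with the implementation paths
# they check.

# Element-wise scalar-loop bi-random walk, following the algorithm listing
# line by line with explicit summation.
birw_scalar_oracle <- function(P, G, A, alpha, l, r) {
  P <- as.matrix(P); G <- as.matrix(G); A <- as.matrix(A)
  m <- nrow(P); n <- nrow(G)
  dp <- rowSums(P); dg <- rowSums(G)
  Pn <- matrix(0, m, m); Gn <- matrix(0, n, n)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (dp[i] > 0 && dp[j] > 0) Pn[i, j] <- P[i, j] / sqrt(dp[i] * dp[j])
  }
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (dg[u] > 0 && dg[v] > 0) Gn[u, v] <- G[u, v] / sqrt(dg[u] * dg[v])
  }
  A0 <- A / sum(A)
  R <- A0
  t_max <- max(l, r)
  if (t_max == 0) return(R)
  for (t in seq_len(t_max)) {
    cnt <- 0
    acc <- matrix(0, m, n)
    if (t <= l) {
      Lmat <- matrix(0, m, n)
      for (i in seq_len(m)) for (u in seq_len(n)) {
        s <- 0
        for (j in seq_len(m)) s <- s + Pn[i, j] * R[j, u]
        Lmat[i, u] <- alpha * s + (1 - alpha) * A0[i, u]
      }
      acc <- acc + Lmat; cnt <- cnt + 1
    }
    if (t <= r) {
      Rmat <- matrix(0, m, n)
      for (i in seq_len(m)) for (u in seq_len(n)) {
        s <- 0
        for (v in seq_len(n)) s <- s + R[i, v] * Gn[v, u]
        Rmat[i, u] <- alpha * s + (1 - alpha) * A0[i, u]
      }
      acc <- acc + Rmat; cnt <- cnt + 1
    }
    R <- acc / cnt
  }
  R
}

# All-pairs hop distances by boolean matrix powers (no igraph).
bfs_distances_oracle <- function(adj) {
  adj <- (as.matrix(adj) > 0)
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(TRUE, n)
  for (t in seq_len(n)) {
    reach_new <- reach | (reach %*% adj > 0)
    newly <- reach_new & !reach
    D[newly] <- t
    if (!any(newly)) break
    reach <- reach_new
  }
  D
}

# Per-association minimum CBG length by exhaustive partner scan on oracle
# BFS distances.
cbg_min_lengths_oracle <- function(P_adj, G_adj, pairs_idx, L_max) {
  dP <- bfs_distances_oracle(P_adj)
  dG <- bfs_distances_oracle(G_adj)
  k <- nrow(pairs_idx)
  out <- rep(Inf, k)
  for (i in seq_len(k)) {
    best <- Inf
    for (j in seq_len(k)) {
      if (i == j) next
      len <- max(dP[pairs_idx[i, 1], pairs_idx[j, 1]],
                 dG[pairs_idx[i, 2], pairs_idx[j, 2]])
      best <- min(best, len)
    }
    out[i] <- if (best <= L_max) best else Inf
  }
  out
}

# Walk-pair enumeration for the CBG count matrix: counts every pair of a
# length-l phenotype walk and a length-r gene walk ending at a known
# association, by explicit recursion over walks.
cbg_count_oracle <- function(P_adj, G_adj, A, l, r) {
  P_adj <- as.matrix(P_adj) > 0
  G_adj <- as.matrix(G_adj) > 0
  A <- as.matrix(A)
  m <- nrow(P_adj); n <- nrow(G_adj)
  walks_from <- function(adj, start, len) {
    # returns counts of walks of length len from start to each node
    v <- numeric(nrow(adj)); v[start] <- 1
    for (t in seq_len(len)) v <- as.numeric(adj %*% v)
    v
  }
  counts <- matrix(0, m, n)
  for (i in seq_len(m)) {
    wp <- walks_from(P_adj, i, l)   # walks i -> j of length l
    for (u in seq_len(n)) {
      wg <- walks_from(G_adj, u, r)
      counts[i, u] <- sum(outer(wp, wg) * A)
    }
  }
  counts
}

# Standard AUC by Mann-Whitney pair counting over all (positive, negative)
# pairs; ties cannot occur because rankings are strict orders.
mann_whitney_auc <- function(labels) {
  pos <- which(labels); neg <- which(!labels)
  wins <- 0
  for (p in pos) for (q in neg) if (p < q) wins <- wins + 1
  wins / (length(pos) * length(neg))
}

# Truncated AUC by direct pair counting among the first k negatives.
auc_at_fp_oracle <- function(labels, k) {
  neg <- which(!labels)
  n_pos <- sum(labels)
  k_eff <- min(k, length(neg))
  wins <- 0
  for (q in neg[seq_len(k_eff)]) wins <- wins + sum(labels[seq_len(q - 1)])
  extra <- if (k > length(neg)) (k - length(neg)) * n_pos else 0
  (wins + extra) / (k * n_pos)
}

# Random small heterogeneous instance for equivalence tests.
random_instance <- function(m, n, p_edge = 0.4, n_assoc = NULL, seed = NULL) {
  make <- function() {
    symm <- function(k) {
      M <- matrix(runif(k * k) < p_edge, k, k) * matrix(runif(k * k), k, k)
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      diag(M) <- 0
      M
    }
    P <- symm(m); G <- symm(n)
    if (is.null(n_assoc)) n_assoc <- max(2, round(0.2 * m * n))
    cells <- sample.int(m * n, n_assoc)
    A <- matrix(0, m, n)
    A[cells] <- 1
    list(P = P, G = G, A = A)
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

# Wrap raw matrices into package containers.
as_net <- function(inst) {
  m <- nrow(inst$P); n <- nrow(inst$G)
  pid <- sprintf("p%02d", seq_len(m)); gid <- sprintf("g%02d", seq_len(n))
  idx <- which(inst$A > 0, arr.ind = TRUE)
  hetero_net(
    as_weighted_graph(inst$P, ids = pid),
    as_weighted_graph(inst$G, ids = gid),
    association_set(tibble::tibble(phenotype = pid[idx[, 1]], gene = gid[idx[, 2]]),
                    pid, gid)
  )
}
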