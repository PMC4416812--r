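test_that("logistic weighting is monotone and strictly inside (0, 1)", {
  w <- logistic_weighting()
  s <- seq(0, 1, by = 0.1)
  vals <- logistic_weight(w, s)
  expect_true(all(vals > 0 & vals < 1))
  expect_true(all(diff(vals) > 0))
  # distance weighting: decreasing, and unreachable ~ 0
  d <- c(0, 1, 2, 5, Inf)
  dv <- distance_weight(w, d)
  expect_true(all(diff(dv) < 0))
  expect_lt(dv[5], 2e-4)
})

test_that("PRINCE propagation matches the closed-form linear solve on a path network", {
  # 5-gene path, single seeded gene
  gid <- paste0("g", 1:5)
  G <- weighted_graph(tibble::tibble(node_a = gid[1:4], node_b = gid[2:5]), ids = gid)
  pid <- c("p1", "p2")
  P <- weighted_graph(tibble::tibble(node_a = "p1", node_b = "p2", weight = 0.9),
                      ids = pid)
  A <- association_set(tibble::tibble(phenotype = "p2", gene = "g3"), pid, gid)
  net <- hetero_net(P, G, A)
  alpha <- 0.4
  scores <- prince_rank(net, "p1", alpha = alpha, tol = 1e-12, max_iter = 100000L)
  # closed form: F = (1 - alpha) (I - alpha W)^{-1} Y
  W <- as.matrix(symmetric_normalize(G$weights))
  wq <- logistic_weight(logistic_weighting(), 0.9)
  Y <- c(0, 0, wq, 0, 0); Y <- Y / sum(Y)
  F_exact <- as.numeric((1 - alpha) * solve(diag(5) - alpha * W, Y))
  expect_lt(max(abs(scores - F_exact)), 1e-8)
})

test_that("PRINCE limits behave as contractions dictate", {
  net <- fixture_suite()$fig1_shape
  # tiny alpha: scores collapse onto the prior
  s_small <- prince_rank(net, "p1", alpha = 1e-6, tol = 1e-12)
  sim <- net$P$weights["p1", ]; sim["p1"] <- 1
  w <- logistic_weighting()
  Y <- setNames(numeric(8), net$G$ids)
  for (i in seq_len(nrow(net$A$pairs))) {
    p <- net$A$pairs$phenotype[i]; g <- net$A$pairs$gene[i]
    Y[g] <- max(Y[g], logistic_weight(w, sim[p]))
  }
  Y <- Y / sum(Y)
  expect_lt(max(abs(s_small - Y)), 1e-5)
  # query with no similar phenotype carrying genes: zero prior, zero scores
  pid <- c("pa", "pb"); gid <- c("ga", "gb")
  P <- weighted_graph(tibble::tibble(node_a = character(0), node_b = character(0),
                                     weight = numeric(0)), ids = pid)
  G <- weighted_graph(tibble::tibble(node_a = "ga", node_b = "gb"), ids = gid)
  A <- association_set(tibble::tibble(phenotype = character(0), gene = character(0)),
                       pid, gid)
  s0 <- prince_rank(hetero_net(P, G, A), "pa")
  expect_equal(unname(s0), c(0, 0))
})

test_that("RWRH matches a dense stationary solve on a toy heterogeneous network", {
  pid <- paste0("p", 1:3); gid <- paste0("g", 1:3)
  P <- weighted_graph(tibble::tibble(node_a = c("p1", "p2"), node_b = c("p2", "p3"),
                                     weight = c(0.8, 0.6)), ids = pid)
  G <- weighted_graph(tibble::tibble(node_a = c("g1", "g2"), node_b = c("g2", "g3")),
                      ids = gid)
  A <- association_set(tibble::tibble(phenotype = c("p1", "p2"), gene = c("g1", "g3")),
                       pid, gid)
  net <- hetero_net(P, G, A)
  prm <- rwrh_params(0.5, 0.7, 0.5)
  scores <- rwrh_rank(net, "p1", prm, tol = 1e-14, max_iter = 100000L)
  # dense solve of x = (1 - c) M' x + c x0
  lam <- 0.5
  rowst <- function(M) { rs <- rowSums(M); M[rs > 0, ] <- M[rs > 0, ] / rs[rs > 0]; M }
  Pm <- as.matrix(P$weights); Gm <- as.matrix(G$weights); Am <- as.matrix(assoc_matrix(A))
  hp <- rowSums(Am) > 0; hg <- colSums(Am) > 0
  M <- rbind(
    cbind(diag(ifelse(hp, 1 - lam, 1)) %*% rowst(Pm), diag(ifelse(hp, lam, 0)) %*% rowst(Am)),
    cbind(diag(ifelse(hg, lam, 0)) %*% rowst(t(Am)), diag(ifelse(hg, 1 - lam, 1)) %*% rowst(Gm))
  )
  x0 <- c(0.5, 0, 0, (0.5), 0, 0) * 0  # build below
  x0 <- numeric(6); x0[1] <- 0.5; x0[3 + 1] <- 0.5  # p1 seed + its known gene g1
  x <- solve(diag(6) - (1 - 0.7) * t(M), 0.7 * x0)
  expect_lt(max(abs(scores - x[4:6])), 1e-10)
})

test_that("RWRH degenerate parameter settings collapse as expected", {
  net <- fixture_suite()$fig1_shape
  # restart probability 1: the walker never moves off the seed
  s1 <- rwrh_rank(net, "p1", rwrh_params(0.5, 1, 0.5))
  known <- net$A$pairs$gene[net$A$pairs$phenotype == "p1"]
  expect_equal(sum(s1), 0.5)  # half the restart mass sits on the gene seed
  expect_equal(unname(s1[known]), 0.5)
  # jump blocked and query without associations: gene block stays zero
  pid <- c("pa", "pb"); gid <- c("ga", "gb")
  P <- weighted_graph(tibble::tibble(node_a = "pa", node_b = "pb"), ids = pid)
  G <- weighted_graph(tibble::tibble(node_a = "ga", node_b = "gb"), ids = gid)
  A <- association_set(tibble::tibble(phenotype = "pb", gene = "ga"), pid, gid)
  s0 <- rwrh_rank(hetero_net(P, G, A), "pa", rwrh_params(0, 0.3, 0.5))
  expect_equal(unname(s0), c(0, 0))
})

test_that("CIPHER correlation scoring matches direct Pearson computation", {
  # 4 phenotypes on a path, 3 genes; hand-checkable correlation
  pid <- paste0("p", 1:4); gid <- paste0("g", 1:3)
  P <- weighted_graph(tibble::tibble(
    node_a = c("p1", "p1", "p1"), node_b = c("p2", "p3", "p4"),
    weight = c(0.9, 0.5, 0.1)), ids = pid)
  G <- weighted_graph(tibble::tibble(node_a = c("g1", "g2"), node_b = c("g2", "g3")),
                      ids = gid)
  A <- association_set(tibble::tibble(phenotype = c("p2", "p3", "p4"),
                                      gene = c("g1", "g2", "g3")), pid, gid)
  net <- hetero_net(P, G, A)
  w <- logistic_weighting()
  for (mode in c("dn", "sp")) {
    scores <- cipher_rank(net, "p1", mode = mode, weighting = w)
    simprof <- c(1, 0.9, 0.5, 0.1)
    dist_fun <- function(g, gp) {
      if (g == gp) return(0)
      Adj <- as.matrix(binarize_adjacency(net$G))
      if (mode == "dn") { if (Adj[g, gp] > 0) 1 else Inf }
      else {
        d <- bfs_distances_oracle(Adj)
        d[g, gp]
      }
    }
    causal <- list(p1 = character(0), p2 = "g1", p3 = "g2", p4 = "g3")
    for (g in gid) {
      phi <- sapply(pid, function(p) {
        gs <- causal[[p]]
        if (length(gs) == 0) return(0)
        sum(sapply(gs, function(gp) distance_weight(w, dist_fun(match(g, gid), match(gp, gid)))))
      })
      if (stats::sd(phi) == 0) expect_equal(unname(scores[g]), -Inf)
      else expect_equal(unname(scores[g]), stats::cor(phi, simprof))
    }
  }
})

test_that("CIPHER gives the sentinel to zero-variance profiles", {
  pid <- paste0("p", 1:3); gid <- c("g1", "g2", "g3")
  P <- weighted_graph(tibble::tibble(node_a = c("p1", "p1"), node_b = c("p2", "p3"),
                                     weight = c(0.8, 0.2)), ids = pid)
  # g2 isolated: every causal gene is unreachable, so its closeness profile
  # is the constant w(Inf) across all phenotypes with one causal gene each
  G <- weighted_graph(tibble::tibble(node_a = "g1", node_b = "g3"), ids = gid)
  A <- association_set(tibble::tibble(phenotype = c("p1", "p2", "p3"),
                                      gene = c("g1", "g3", "g1")),
                       pid, gid)
  scores <- cipher_rank(hetero_net(P, G, A), "p1", mode = "dn")
  expect_equal(unname(scores["g2"]), -Inf)
  expect_true(is.finite(scores["g1"]))
  # sentinel ranks last
  expect_equal(rank_scores(scores)$gene[3], "g2")
})

test_that("baseline rankings are equivariant under gene relabeling", {
  inst <- random_instance(6, 7, n_assoc = 8, seed = 1234)
  net <- as_net(inst)
  q <- "p01"
  perm <- withr::with_seed(5, sample(7))
  inst_p <- list(P = inst$P, G = inst$G[perm, perm], A = inst$A[, perm])
  net_p <- as_net(inst_p)
  for (fn in list(
    function(nt) prince_rank(nt, q, alpha = 0.3, tol = 1e-12),
    function(nt) rwrh_rank(nt, q, rwrh_params(0.5, 0.7, 0.5), tol = 1e-13),
    function(nt) cipher_rank(nt, q, mode = "sp")
  )) {
    s <- fn(net)
    sp <- fn(net_p)
    expect_equal(unname(sp), unname(s[perm]), tolerance = 1e-9)
  }
})
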