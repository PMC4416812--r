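test_that("the 2x2 hand-worked walk returns the exact closed-form scores", {
  P <- weighted_graph(tibble::tibble(node_a = "p1", node_b = "p2"), ids = c("p1", "p2"))
  G <- weighted_graph(tibble::tibble(node_a = "g1", node_b = "g2"), ids = c("g1", "g2"))
  A <- association_set(tibble::tibble(phenotype = "p1", gene = "g1"),
                       c("p1", "p2"), c("g1", "g2"))
  pred <- birw_predict(normalize_hetero(hetero_net(P, G, A)),
                       birw_params(alpha = 0.5, l = 1, r = 1))
  expect_equal(unname(pred$R), matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
})

test_that("birw_predict agrees with the scalar-loop oracle on random instances", {
  for (s in 1:20) {
    set.seed(700 + s)
    m <- sample(2:10, 1); n <- sample(2:10, 1)
    inst <- random_instance(m, n, p_edge = 0.5, n_assoc = sample(1:(m * n %/% 2), 1))
    alpha <- sample(c(0.3, 0.5, 0.8), 1)
    l <- sample(0:4, 1); r <- sample(0:4, 1)
    net <- as_net(inst)
    pred <- birw_predict(normalize_hetero(net), birw_params(alpha, l, r))
    expect_lt(max(abs(pred$R - birw_scalar_oracle(inst$P, inst$G, inst$A, alpha, l, r))),
              1e-12)
  }
})

test_that("degenerate step caps reduce to the expected special cases", {
  inst <- random_instance(5, 6, seed = 1)
  net <- normalize_hetero(as_net(inst))
  # l = r = 0: the loop never executes and the normalized A comes back
  p0 <- birw_predict(net, birw_params(0.8, 0, 0))
  expect_equal(unname(p0$R), as.matrix(net$A_norm), ignore_attr = TRUE)
  # unbalanced l = 2, r = 0 equals iterating the left update alone
  p_left <- birw_predict(net, birw_params(0.6, 2, 0))
  A <- as.matrix(net$A_norm)
  R <- A
  for (t in 1:2) R <- 0.6 * as.matrix(net$P_norm %*% R) + 0.4 * A
  expect_equal(unname(p_left$R), R, ignore_attr = TRUE)
})

test_that("increasing one entry of the seed matrix never decreases any score", {
  inst <- random_instance(6, 6, n_assoc = 6, seed = 2)
  net <- as_net(inst)
  base <- birw_predict(normalize_hetero(net), birw_params(0.8, 3, 3))
  # add one association: every propagated score can only grow
  zero_cells <- which(inst$A == 0, arr.ind = TRUE)
  cell <- zero_cells[1, ]
  inst2 <- inst
  inst2$A[cell[1], cell[2]] <- 1
  net2 <- as_net(inst2)
  nn2 <- normalize_hetero(net2)
  # compare on the un-normalized scale: rescale both by total seed mass
  pred2 <- birw_predict(nn2, birw_params(0.8, 3, 3))
  expect_true(all(pred2$R * sum(assoc_matrix(net2$A)) -
                  base$R * sum(assoc_matrix(net$A)) >= -1e-12))
})

test_that("transposing the problem transposes the balanced result exactly", {
  inst <- random_instance(5, 7, n_assoc = 8, seed = 3)
  net <- as_net(inst)
  fwd <- birw_predict(normalize_hetero(net), birw_params(0.7, 3, 3))
  # swapped problem: P <-> G, A <-> t(A), l <-> r
  idx <- which(t(inst$A) > 0, arr.ind = TRUE)
  gid <- net$G$ids; pid <- net$P$ids
  net_t <- hetero_net(net$G, net$P,
                      association_set(tibble::tibble(phenotype = gid[idx[, 1]],
                                                     gene = pid[idx[, 2]]),
                                      gid, pid))
  bwd <- birw_predict(normalize_hetero(net_t), birw_params(0.7, 3, 3))
  expect_equal(unname(bwd$R), t(unname(fwd$R)))
})

test_that("the walk is deterministic at the published human setting", {
  sim <- generate_hetero(synthetic_config(seed = 5, m = 40, n = 50,
                                          n_seed_assoc = 30))
  p1 <- birw_predict(normalize_hetero(sim$net), birw_params(0.8, 4, 4))
  p2 <- birw_predict(normalize_hetero(sim$net), birw_params(0.8, 4, 4))
  expect_identical(p1$R, p2$R)
})

test_that("fixed point satisfies its update, matches the linear solve, contracts", {
  for (s in 1:10) {
    inst <- random_instance(4, 5, n_assoc = 5, seed = 800 + s)
    net <- normalize_hetero(as_net(inst))
    alpha <- 0.8
    fp <- birw_fixed_point(net, alpha = alpha, tol = 1e-10)
    P <- as.matrix(net$P_norm); G <- as.matrix(net$G_norm); A <- as.matrix(net$A_norm)
    R <- unname(fp$R)
    # fixed-point equation holds to tolerance
    expect_lt(max(abs(alpha * (P %*% R + R %*% G) / 2 + (1 - alpha) * A - R)), 1e-9)
    # dense Kronecker-structured linear solve of the vectorized system:
    # (I - alpha/2 (G' (x) I + I (x) P)) vec(R) = (1 - alpha) vec(A)
    m <- 4; n <- 5
    K <- diag(m * n) - (alpha / 2) * (kronecker(t(G), diag(m)) + kronecker(diag(n), P))
    vecR <- solve(K, (1 - alpha) * as.vector(A))
    expect_lt(max(abs(as.vector(R) - vecR)), 1e-8)
  }
})

test_that("fixed-point residuals contract at rate at most alpha", {
  inst <- random_instance(6, 6, n_assoc = 6, seed = 9)
  net <- normalize_hetero(as_net(inst))
  alpha <- 0.9
  A <- as.matrix(net$A_norm); P <- as.matrix(net$P_norm); G <- as.matrix(net$G_norm)
  R <- A
  res <- c()
  for (it in 1:30) {
    R_new <- alpha * (P %*% R + R %*% G) / 2 + (1 - alpha) * A
    res <- c(res, sqrt(sum((R_new - R)^2)))  # Frobenius: 2-norm contraction
    R <- R_new
  }
  ratios <- res[-1] / res[-length(res)]
  expect_true(all(ratios <= alpha + 1e-9))
  # tiny alpha: the fixed point collapses onto the seed matrix
  fp_small <- birw_fixed_point(net, alpha = 1e-6, tol = 1e-12)
  expect_lt(max(abs(fp_small$R - A)), 1e-5)
  # iteration cap is a reported error
  expect_error(birw_fixed_point(net, alpha = 0.9, tol = 1e-14, max_iter = 2L),
               "converge")
})

test_that("the regularization objective matches the four-index summation", {
  for (s in 1:5) {
    set.seed(900 + s)
    inst <- random_instance(3, 3, p_edge = 0.6, n_assoc = 3)
    net <- as_net(inst)
    R <- matrix(runif(9), 3, 3)
    alpha <- 0.7
    obj <- birw_objective(R, net, alpha)
    # explicit nested-loop evaluation
    Pb <- (inst$P > 0) * 1; Gb <- (inst$G > 0) * 1
    smooth <- 0
    for (i in 1:3) for (u in 1:3) for (j in 1:3) for (v in 1:3) {
      smooth <- smooth + Pb[i, j] * Gb[u, v] * (R[i, u] - R[j, v])^2
    }
    fit <- sum((R - inst$A)^2)
    expect_equal(obj$smoothness, smooth)
    expect_equal(obj$fit, fit)
    expect_equal(obj$value, alpha * smooth + (1 - alpha) * fit)
  }
})

test_that("objective components vanish in the degenerate cases", {
  fx <- fixture_suite()$rectangle
  # constant R on a connected pattern: smoothness 0
  obj_const <- birw_objective(matrix(0.3, 2, 2), fx, 0.5)
  expect_equal(obj_const$smoothness, 0)
  # R = A with no length-1 CBG mismatch: both terms 0 when A is constant over
  # the connected cells
  A <- as.matrix(assoc_matrix(fx$A))
  Aconst <- matrix(1, 2, 2)
  obj0 <- birw_objective(Aconst, hetero_net(fx$P, fx$G,
            association_set(tibble::tibble(
              phenotype = c("p1", "p1", "p2", "p2"),
              gene = c("g1", "g2", "g1", "g2")), fx$P$ids, fx$G$ids)), 0.5)
  expect_equal(obj0$value, 0)
  expect_error(birw_objective(matrix(0, 200, 200),
                              as_net(random_instance(200, 200, n_assoc = 5, seed = 1)),
                              0.5),
               "guard")
})

test_that("gene ranking is deterministic and scale-invariant", {
  R <- matrix(c(0.5, 0.2, 0.5, 0.1), 1, 4,
              dimnames = list("p1", c("gb", "ga", "gc", "gd")))
  rk <- rank_genes(R, "p1")
  # descending score, ties broken by ascending label: gb before gc
  expect_equal(rk$gene, c("gb", "gc", "ga", "gd"))
  # all-equal scores: pure label order
  R2 <- matrix(1, 1, 3, dimnames = list("p1", c("g3", "g1", "g2")))
  expect_equal(rank_genes(R2, "p1")$gene, c("g1", "g2", "g3"))
  # positive rescaling leaves the order unchanged
  expect_equal(rank_genes(R * 7, "p1")$gene, rk$gene)
  expect_error(rank_genes(R, "nope"), "unknown phenotype")
})
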