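# Comparison baselines: PRINCE-style label propagation on the gene network,
# random walk with restart on the combined heterogeneous network (RWRH), and
# CIPHER correlation scoring (direct-neighbor and shortest-path variants).
# These follow the published sketches of the methods; they are per-query gene
# prioritizers, in contrast to the global BiRW reconstruction.

#' Logistic similarity-to-weight mapping
#'
#' The logistic curve `w(s) = 1 / (1 + exp(c * s + d))` used by PRINCE to turn
#' a phenotype similarity (or a distance mapped to a similarity) into a weight
#' strictly inside (0, 1). The defaults `c = -15`, `d = log(9999)` give
#' w(0) = 1e-4 and w(1) ~ 0.9997, so only strong similarities contribute.
#'
#' @param c,d Curve parameters; `c < 0` makes the weight increase with
#'   similarity.
#' @return A `logistic_weighting` object; call it on similarities via
#'   [logistic_weight()], or on hop distances via [distance_weight()] (which
#'   maps a distance x to the similarity `exp(-x)` first, so unreachable
#'   nodes, distance Inf, get weight w(0) ~ 0).
#' @export
logistic_weighting <- function(c = -15, d = log(9999)) {
  stopifnot(c < 0)
  structure(list(c = c, d = d), class = "logistic_weighting")
}

#' @rdname logistic_weighting
#' @param w A `logistic_weighting`.
#' @param s Similarity values.
#' @export
logistic_weight <- function(w, s) 1 / (1 + exp(w$c * s + w$d))

#' @rdname logistic_weighting
#' @param x Hop distances (Inf allowed).
#' @export
distance_weight <- function(w, x) logistic_weight(w, exp(-x))

# known genes of each phenotype as a list keyed by phenotype label
causal_gene_sets <- function(A) {
  split(A$pairs$gene, factor(A$pairs$phenotype, levels = A$row_ids))
}

#' PRINCE-style label propagation
#'
#' Builds a prior over genes from the causative genes of phenotypes similar to
#' the query (each phenotype contributes its logistic-weighted similarity; a
#' gene keeps the maximum over its phenotypes; the prior is normalized to unit
#' sum), then propagates it on the symmetric-normalized gene network via
#' `F <- alpha * W %*% F + (1 - alpha) * Y` to convergence.
#'
#' @param net A `birw_heteronet`.
#' @param query_phenotype Phenotype label.
#' @param alpha Propagation weight in (0, 1).
#' @param weighting A [logistic_weighting()].
#' @param tol,max_iter Convergence control; non-convergence is an error.
#' @return Named numeric vector of gene scores.
#' @export
prince_rank <- function(net, query_phenotype, alpha = 0.1,
                        weighting = logistic_weighting(),
                        tol = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(net, "birw_heteronet"), alpha > 0, alpha < 1)
  if (!query_phenotype %in% net$P$ids) abort("unknown query phenotype")
  sim <- net$P$weights[query_phenotype, ]
  sim[query_phenotype] <- 1  # the query is maximally similar to itself
  Y <- setNames(numeric(net$n), net$G$ids)
  pw <- logistic_weight(weighting, sim)
  for (i in seq_len(nrow(net$A$pairs))) {
    p <- net$A$pairs$phenotype[i]; g <- net$A$pairs$gene[i]
    Y[g] <- max(Y[g], pw[p])
  }
  if (sum(Y) > 0) Y <- Y / sum(Y)
  W <- symmetric_normalize(net$G$weights)
  F_vec <- Y
  for (it in seq_len(max_iter)) {
    F_new <- alpha * as.numeric(W %*% F_vec) + (1 - alpha) * Y
    res <- max(abs(F_new - F_vec))
    F_vec <- F_new
    if (res < tol) return(setNames(F_vec, net$G$ids))
  }
  abort(sprintf("PRINCE propagation did not converge in %d iterations (residual %.3g)",
                max_iter, res))
}

#' RWRH parameter triple
#'
#' @param jump_prob Probability of jumping between the phenotype and gene
#'   subnetworks through the bipartite associations.
#' @param restart_prob Restart probability.
#' @param seed_balance Fraction of the restart mass placed on the phenotype
#'   seed (the rest goes to the query's known genes, when any exist).
#'   The published triple is (0.5, 0.7, 0.5), read in this order.
#' @return An `rwrh_params` list.
#' @export
rwrh_params <- function(jump_prob = 0.5, restart_prob = 0.7, seed_balance = 0.5) {
  stopifnot(jump_prob >= 0, jump_prob <= 1, restart_prob >= 0, restart_prob <= 1,
            seed_balance >= 0, seed_balance <= 1)
  structure(list(jump_prob = jump_prob, restart_prob = restart_prob,
                 seed_balance = seed_balance), class = "rwrh_params")
}

row_stochastic <- function(M) {
  rs <- Matrix::rowSums(M)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  Diagonal(x = inv) %*% M
}

#' Random walk with restart on the heterogeneous network
#'
#' Builds the (m + n) x (m + n) transition operator over the combined network:
#' within-network moves use the row-normalized P and G; nodes incident to at
#' least one association divert `jump_prob` of their mass across the bipartite
#' edges. The walker restarts at the query-seed distribution with probability
#' `restart_prob` each step; the converged gene-block occupancy is the score.
#'
#' @param net A `birw_heteronet`.
#' @param query_phenotype Phenotype label.
#' @param params An [rwrh_params()].
#' @param tol,max_iter Convergence control.
#' @return Named numeric vector of gene scores.
#' @export
rwrh_rank <- function(net, query_phenotype, params = rwrh_params(),
                      tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(net, "birw_heteronet"), inherits(params, "rwrh_params"))
  if (!query_phenotype %in% net$P$ids) abort("unknown query phenotype")
  m <- net$m; n <- net$n
  A <- assoc_matrix(net$A)
  lam <- params$jump_prob
  Pn <- row_stochastic(net$P$weights)
  Gn <- row_stochastic(net$G$weights)
  An <- row_stochastic(A)
  Atn <- row_stochastic(Matrix::t(A))
  has_assoc_p <- Matrix::rowSums(A) > 0
  has_assoc_g <- Matrix::colSums(A) > 0
  # rows: phenotype nodes then gene nodes
  PP <- Diagonal(x = ifelse(has_assoc_p, 1 - lam, 1)) %*% Pn
  PG <- Diagonal(x = ifelse(has_assoc_p, lam, 0)) %*% An
  GG <- Diagonal(x = ifelse(has_assoc_g, 1 - lam, 1)) %*% Gn
  GP <- Diagonal(x = ifelse(has_assoc_g, lam, 0)) %*% Atn
  M <- rbind(cbind(PP, PG), cbind(GP, GG))
  # seed distribution
  x0 <- numeric(m + n)
  qi <- match(query_phenotype, net$P$ids)
  known <- net$A$pairs$gene[net$A$pairs$phenotype == query_phenotype]
  if (length(known) > 0) {
    x0[qi] <- params$seed_balance
    gi <- m + match(known, net$G$ids)
    x0[gi] <- (1 - params$seed_balance) / length(known)
  } else {
    x0[qi] <- 1
  }
  Mt <- Matrix::t(M)
  x <- x0
  rp <- params$restart_prob
  for (it in seq_len(max_iter)) {
    x_new <- (1 - rp) * as.numeric(Mt %*% x) + rp * x0
    res <- max(abs(x_new - x))
    x <- x_new
    if (res < tol) return(setNames(x[(m + 1):(m + n)], net$G$ids))
  }
  abort(sprintf("RWRH did not converge in %d iterations (residual %.3g)",
                max_iter, res))
}

#' CIPHER correlation scoring
#'
#' For each candidate gene g, builds the gene-phenotype closeness profile
#' `Phi_g(p) = sum over known causative genes g' of p of weight(d(g, g'))`,
#' where d is the self/adjacency indicator distance (0 self, 1 adjacent, Inf
#' otherwise; mode `"dn"`) or the shortest-path hop distance on the unweighted
#' gene network (mode `"sp"`), mapped to a weight by the logistic curve (an
#' unreachable gene contributes ~0). The score of g is the Pearson
#' correlation of `Phi_g` with the query's phenotype-similarity profile
#' (self-similarity 1). Zero-variance profiles get the sentinel `-Inf` and
#' rank last.
#'
#' @param net A `birw_heteronet` with at least 2 phenotypes.
#' @param query_phenotype Phenotype label.
#' @param mode `"dn"` (direct neighbor) or `"sp"` (shortest path).
#' @param weighting A [logistic_weighting()].
#' @return Named numeric vector of gene scores (possibly `-Inf`).
#' @export
cipher_rank <- function(net, query_phenotype, mode = c("dn", "sp"),
                        weighting = logistic_weighting()) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "birw_heteronet"), net$m >= 2)
  if (!query_phenotype %in% net$P$ids) abort("unknown query phenotype")
  gene_ids <- net$G$ids
  causal <- unique(net$A$pairs$gene)
  simprof <- as.numeric(net$P$weights[query_phenotype, ])
  simprof[match(query_phenotype, net$P$ids)] <- 1
  if (length(causal) == 0 || sd(simprof) == 0) {
    return(setNames(rep(-Inf, net$n), gene_ids))
  }
  if (mode == "dn") {
    Adj <- binarize_adjacency(net$G)
    D <- matrix(Inf, net$n, length(causal), dimnames = list(gene_ids, causal))
    D[as.matrix(Adj[, causal, drop = FALSE]) > 0] <- 1
    D[cbind(match(causal, gene_ids), seq_along(causal))] <- 0
  } else {
    ig <- graph_from_weights(net$G)
    D <- igraph::distances(ig, to = match(causal, gene_ids))
    dimnames(D) <- list(gene_ids, causal)
  }
  Wd <- distance_weight(weighting, D)          # genes x causal genes
  Inc <- sparseMatrix(                         # causal genes x phenotypes
    i = match(net$A$pairs$gene, causal),
    j = match(net$A$pairs$phenotype, net$P$ids),
    x = 1, dims = c(length(causal), net$m)
  )
  Phi <- as.matrix(Wd %*% Inc)                 # genes x phenotypes
  scores <- suppressWarnings(as.numeric(cor(t(Phi), simprof)))
  scores[!is.finite(scores)] <- -Inf           # zero-variance profiles rank last
  setNames(scores, gene_ids)
}
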