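# The bi-random walk: alternating left (phenotype-side) and right (gene-side)
# propagation of the normalized association matrix, with decay factor alpha
# and independent step caps l and r. Capping the two sides separately lets
# the walk match the different neighborhood structure of the phenotype
# similarity network and the gene interaction network.

#' BiRW parameter set
#'
#' @param alpha Decay factor in (0, 1); down-weights circular bigraphs with
#'   longer paths. Published settings: 0.8 for the human OMIM networks, 0.7
#'   for mouse.
#' @param l Maximum left (phenotype-side) walk steps, >= 0 (human: 4; mouse: 5).
#' @param r Maximum right (gene-side) walk steps, >= 0 (human: 4; mouse: 1).
#' @return A `birw_params` list.
#' @export
birw_params <- function(alpha = 0.8, l = 4, r = 4) {
  stopifnot(alpha > 0, alpha < 1, l >= 0, r >= 0,
            l == as.integer(l), r == as.integer(r))
  structure(list(alpha = alpha, l = as.integer(l), r = as.integer(r)),
            class = "birw_params")
}

new_birw_prediction <- function(R, phenotype_ids, gene_ids, params, iterations) {
  dimnames(R) <- list(phenotype_ids, gene_ids)
  structure(list(R = R, phenotype_ids = phenotype_ids, gene_ids = gene_ids,
                 params = params, iterations = iterations),
            class = "birw_prediction")
}

#' Predict the complete association matrix by bi-random walk
#'
#' Starting from the sum-normalized association matrix `R_0 = A / sum(A)`, the
#' walk iterates for `t = 1..max(l, r)`:
#' a left update `alpha * P_norm %*% R + (1 - alpha) * A_norm` while `t <= l`,
#' a right update `alpha * R %*% G_norm + (1 - alpha) * A_norm` while
#' `t <= r`, and sets `R_t` to the average of the updates active at step `t`.
#' No convergence test is applied: the walk runs exactly `max(l, r)` steps, so
#' the score of a cell aggregates circular bigraphs with phenotype paths up to
#' `l` and gene paths up to `r`, geometrically discounted by `alpha`. The
#' result is a global reconstruction: scores for every phenotype at once, not
#' a per-query ranking.
#'
#' @param net A `birw_normnet` from [normalize_hetero()] (or a
#'   `birw_heteronet`, normalized on the fly).
#' @param params A [birw_params()].
#' @return A `birw_prediction` holding the dense m x n score matrix `R`;
#'   `tidy()` returns the long score table.
#' @examples
#' net <- fixture_suite()$rectangle
#' birw_predict(net, birw_params(alpha = 0.5, l = 1, r = 1))
#' @export
birw_predict <- function(net, params = birw_params()) {
  if (inherits(net, "birw_heteronet")) net <- normalize_hetero(net)
  stopifnot(inherits(net, "birw_normnet"), inherits(params, "birw_params"))
  alpha <- params$alpha; l <- params$l; r <- params$r
  A <- as.matrix(net$A_norm)
  P <- net$P_norm
  G <- net$G_norm
  R <- A
  t_max <- max(l, r)
  for (t in seq_len(t_max)) {
    left_on <- t <= l
    right_on <- t <= r
    acc <- 0
    if (left_on) acc <- acc + (alpha * as.matrix(P %*% R) + (1 - alpha) * A)
    if (right_on) acc <- acc + (alpha * as.matrix(R %*% G) + (1 - alpha) * A)
    R <- acc / (left_on + right_on)
    if (any(!is.finite(R))) abort("non-finite values in bi-random walk iterate")
  }
  new_birw_prediction(R, net$phenotype_ids, net$gene_ids, params, t_max)
}

#' @export
print.birw_prediction <- function(x, ...) {
  cat(sprintf("<birw_prediction> %d x %d scores (alpha = %g, l = %d, r = %d)\n",
              nrow(x$R), ncol(x$R), x$params$alpha, x$params$l, x$params$r))
  invisible(x)
}

#' @export
tidy.birw_prediction <- function(x, ...) {
  tibble(
    phenotype = rep(x$phenotype_ids, times = length(x$gene_ids)),
    gene = rep(x$gene_ids, each = length(x$phenotype_ids)),
    score = as.vector(x$R)
  )
}

#' @export
glance.birw_prediction <- function(x, ...) {
  tibble(m = nrow(x$R), n = ncol(x$R), alpha = x$params$alpha,
         l = x$params$l, r = x$params$r, iterations = x$iterations,
         total_score = sum(x$R))
}

#' @export
autoplot.birw_prediction <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$phenotype,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank()) +
    ggplot2::labs(title = "Predicted phenotype-gene association scores")
}

#' Balanced BiRW fixed point
#'
#' Iterates the balanced (infinite-walk) update
#' `R <- alpha * (P_norm %*% R + R %*% G_norm) / 2 + (1 - alpha) * A_norm`
#' until the maximum absolute change drops below `tol`. Because both
#' normalized operators have spectral radius at most 1, the update is a
#' contraction with factor at most `alpha` and converges geometrically to the
#' unique fixed point.
#'
#' @param net A `birw_normnet` (or `birw_heteronet`).
#' @param alpha Decay factor in (0, 1).
#' @param tol Convergence tolerance on the max-abs change; > 0.
#' @param max_iter Iteration cap; exceeding it is an error reporting the last
#'   residual.
#' @return A `birw_prediction` (with `iterations` the number used).
#' @export
birw_fixed_point <- function(net, alpha = 0.8, tol = 1e-10, max_iter = 1000L) {
  if (inherits(net, "birw_heteronet")) net <- normalize_hetero(net)
  stopifnot(alpha > 0, alpha < 1, tol > 0)
  A <- as.matrix(net$A_norm)
  P <- net$P_norm
  G <- net$G_norm
  R <- A
  for (it in seq_len(max_iter)) {
    R_new <- alpha * (as.matrix(P %*% R) + as.matrix(R %*% G)) / 2 + (1 - alpha) * A
    res <- max(abs(R_new - R))
    R <- R_new
    if (res < tol) {
      params <- structure(list(alpha = alpha, l = Inf, r = Inf), class = "birw_params")
      out <- new_birw_prediction(R, net$phenotype_ids, net$gene_ids, params, it)
      out$residual <- res
      return(out)
    }
  }
  abort(sprintf("balanced BiRW did not converge in %d iterations (last residual %.3g)",
                max_iter, res))
}

#' Kronecker-product regularization objective
#'
#' Evaluates the graph-regularization objective that the bi-random walk
#' minimizes:
#' `alpha * sum_{(i,u),(j,v)} (P (x) G)[(i,u),(j,v)] * (R[i,u] - R[j,v])^2 +
#'  (1 - alpha) * sum (R - A)^2`,
#' where `P (x) G` is the Kronecker product of the (binary) phenotype and gene
#' adjacency matrices: the smoothness term asks neighboring (phenotype, gene)
#' cells — those forming a circular bigraph of length 1 — to carry similar
#' scores, and the fit term anchors `R` to the known associations. The
#' smoothness sum runs over ordered index pairs, and is computed as the
#' quadratic form `2 * rhat' (D - P (x) G) rhat` with `D` the row-sum diagonal.
#'
#' Guarded to `m * n <= 10000` (the Kronecker product is dense).
#'
#' @param R m x n score matrix.
#' @param net A `birw_heteronet` (raw, un-normalized: the objective is stated
#'   on the binary adjacency).
#' @param alpha Trade-off in (0, 1).
#' @return A list of class `birw_objective` with `value`, `smoothness`, `fit`.
#' @export
birw_objective <- function(R, net, alpha) {
  stopifnot(inherits(net, "birw_heteronet"), alpha > 0, alpha < 1)
  R <- as.matrix(R)
  m <- net$m; n <- net$n
  stopifnot(nrow(R) == m, ncol(R) == n)
  if (m * n > 10000) abort("birw_objective: m * n exceeds the dense-Kronecker guard (10000)")
  Pb <- as.matrix(binarize_adjacency(net$P))
  Gb <- as.matrix(binarize_adjacency(net$G))
  W <- kronecker(Pb, Gb)           # index (i, u) -> (i - 1) * n + u
  rhat <- as.vector(t(R))          # row-major: matches the (i, u) indexing
  A <- as.matrix(assoc_matrix(net$A))
  ahat <- as.vector(t(A))
  d <- rowSums(W)
  smooth <- 2 * (sum(d * rhat^2) - as.numeric(rhat %*% W %*% rhat))
  fit <- sum((rhat - ahat)^2)
  structure(list(value = alpha * smooth + (1 - alpha) * fit,
                 smoothness = smooth, fit = fit, alpha = alpha),
            class = "birw_objective")
}

#' @export
print.birw_objective <- function(x, ...) {
  cat(sprintf("<birw_objective> value = %.6g (smoothness %.6g, fit %.6g, alpha %g)\n",
              x$value, x$smoothness, x$fit, x$alpha))
  invisible(x)
}

#' Rank candidate genes for one phenotype
#'
#' Sorts candidates by descending predicted score; ties are broken by
#' ascending gene label so rankings are deterministic.
#'
#' @param prediction A `birw_prediction` (or a bare score matrix with
#'   dimnames).
#' @param phenotype Phenotype label.
#' @param candidate_genes Genes to rank; default all genes.
#' @return Tibble with columns `rank`, `gene`, `score`.
#' @export
rank_genes <- function(prediction, phenotype, candidate_genes = NULL) {
  R <- if (inherits(prediction, "birw_prediction")) prediction$R else as.matrix(prediction)
  if (!phenotype %in% rownames(R)) abort(sprintf("unknown phenotype '%s'", phenotype))
  scores <- R[phenotype, ]
  if (is.null(candidate_genes)) candidate_genes <- colnames(R)
  missing <- setdiff(candidate_genes, colnames(R))
  if (length(missing) > 0) abort("candidate genes absent from the score matrix")
  s <- scores[candidate_genes]
  ord <- order(-s, candidate_genes)
  tibble(rank = seq_along(ord), gene = candidate_genes[ord],
         score = unname(s[ord]))
}

#' Rank an arbitrary score vector deterministically
#'
#' @param scores Named numeric vector (names = gene labels).
#' @return Tibble `rank`, `gene`, `score` sorted by descending score then
#'   ascending label.
#' @export
rank_scores <- function(scores) {
  ord <- order(-scores, names(scores))
  tibble(rank = seq_along(ord), gene = names(scores)[ord],
         score = unname(scores[ord]))
}
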