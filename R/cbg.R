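# Circular bigraph (CBG) statistics. A CBG joins two phenotype-gene
# associations by a phenotype path and a gene path; its length is the larger
# of the two path lengths, and degenerate length-0 paths give the triangle
# cases (shared phenotype or shared gene).

binarize_adjacency <- function(g) {
  W <- if (inherits(g, "birw_graph")) g$weights else g
  (W > 0) * 1
}

graph_from_weights <- function(g) {
  W <- binarize_adjacency(g)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", diag = FALSE)
}

# Unweighted shortest-path distances restricted to the node subsets used by
# the associations; rows/cols indexed by node index.
hop_distances <- function(g, from_idx) {
  ig <- graph_from_weights(g)
  d <- igraph::distances(ig, v = from_idx, to = from_idx)
  d
}

#' Minimum CBG length per known association
#'
#' For each association (p, g), finds the smallest L >= 1 such that some other
#' association (p', g') forms with it a circular bigraph of length <= L, i.e.
#' `max(d_P(p, p'), d_G(g, g')) <= L` with d the unweighted shortest-path hop
#' distance (d(x, x) = 0, unreachable = Inf). Degenerate CBGs sharing the
#' phenotype or the gene (one path of length 0) are allowed — these are the
#' triangle patterns; the identical partner is excluded. Lengths above
#' `L_max` are reported as `Inf` ("not covered").
#'
#' The phenotype and gene networks are binarized: path length here is a hop
#' count, independent of edge weights.
#'
#' @param P,G `birw_graph`s (any positive weight counts as an edge).
#' @param A A `birw_assoc`.
#' @param L_max Truncation length, >= 1.
#' @return Object of class `cbg_coverage`: the association tibble with a
#'   `min_length` column (Inf = not covered within `L_max`), plus `L_max`.
#' @seealso [coverage_fraction()], [cbg_coverage_curve()]
#' @export
cbg_min_lengths <- function(P, G, A, L_max) {
  stopifnot(L_max >= 1)
  pairs <- A$pairs
  k <- nrow(pairs)
  min_len <- rep(Inf, k)
  if (k >= 2) {
    pi <- match(pairs$phenotype, A$row_ids)
    gi <- match(pairs$gene, A$col_ids)
    up <- sort(unique(pi)); ug <- sort(unique(gi))
    dP <- hop_distances(P, up)
    dG <- hop_distances(G, ug)
    DP <- dP[match(pi, up), match(pi, up), drop = FALSE]
    DG <- dG[match(gi, ug), match(gi, ug), drop = FALSE]
    M <- pmax(DP, DG)
    diag(M) <- Inf  # a pair is not its own partner
    min_len <- apply(M, 1, min)
    min_len[min_len > L_max] <- Inf
    min_len[min_len < 1] <- 1  # cannot occur (distinct pairs), guard only
  }
  structure(list(
    associations = mutate(pairs, min_length = unname(min_len)),
    L_max = L_max
  ), class = "cbg_coverage")
}

#' @export
print.cbg_coverage <- function(x, ...) {
  cat(sprintf("<cbg_coverage> %d associations, L_max = %d, covered at L_max: %.1f%%\n",
              nrow(x$associations), x$L_max,
              100 * coverage_fraction(x, x$L_max)))
  invisible(x)
}

#' @export
tidy.cbg_coverage <- function(x, ...) x$associations

#' Fraction of associations covered by a CBG of length at most L
#'
#' @param cov A `cbg_coverage` from [cbg_min_lengths()].
#' @param L Path length, >= 1.
#' @return Fraction in \[0, 1\]; non-decreasing in `L`.
#' @export
coverage_fraction <- function(cov, L) {
  stopifnot(inherits(cov, "cbg_coverage"), L >= 1)
  mean(cov$associations$min_length <= L)
}

#' Coverage curve over L = 1..L_max
#'
#' @param cov A `cbg_coverage`.
#' @return Tibble with columns `L`, `coverage`.
#' @export
cbg_coverage_curve <- function(cov) {
  L <- seq_len(cov$L_max)
  tibble(L = L, coverage = vapply(L, function(l) coverage_fraction(cov, l), numeric(1)))
}

#' @export
autoplot.cbg_coverage <- function(object, ...) {
  df <- cbg_coverage_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$L), y = .data$coverage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "CBG path length ≤ L", y = "associations covered",
                  title = "Circular-bigraph coverage of known associations")
}

#' CBG walk-count matrix P^l A G^r
#'
#' Counts, for every (phenotype, gene) cell, the number of (phenotype-walk of
#' length `l`, gene-walk of length `r`) pairs connecting it to a known
#' association: the matrix product `P^l A G^r` on the binarized adjacency
#' matrices. With `l = r = 0` this is `A` itself.
#'
#' @param P,G `birw_graph`s (binarized).
#' @param A A `birw_assoc`.
#' @param l,r Walk lengths, >= 0.
#' @return Dense integer-valued matrix (m x n) with dimnames.
#' @export
cbg_count_matrix <- function(P, G, A, l, r) {
  stopifnot(l >= 0, r >= 0)
  Pb <- binarize_adjacency(P)
  Gb <- binarize_adjacency(G)
  M <- assoc_matrix(A)
  for (t in seq_len(l)) M <- Pb %*% M
  for (t in seq_len(r)) M <- M %*% Gb
  out <- as.matrix(M)
  dimnames(out) <- list(A$row_ids, A$col_ids)
  out
}

#' Uniformly random association set
#'
#' Draws `k` distinct uniform (phenotype, gene) pairs — the randomized null
#' used to calibrate CBG coverage.
#'
#' @param phenotype_ids,gene_ids Label universes (or integer counts m, n, in
#'   which case labels `p1..pm` / `g1..gn` are used).
#' @param k Number of pairs, `k <= m * n`.
#' @param seed Optional integer; if supplied the draw is made reproducible via
#'   a local RNG state.
#' @return A `birw_assoc` with `k` pairs.
#' @export
randomize_associations <- function(phenotype_ids, gene_ids, k, seed = NULL) {
  if (is.numeric(phenotype_ids) && length(phenotype_ids) == 1) {
    phenotype_ids <- paste0("p", seq_len(phenotype_ids))
  }
  if (is.numeric(gene_ids) && length(gene_ids) == 1) {
    gene_ids <- paste0("g", seq_len(gene_ids))
  }
  m <- length(phenotype_ids); n <- length(gene_ids)
  stopifnot(k <= as.double(m) * n)
  draw <- function() sample.int(m * n, k)
  cells <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pi <- ((cells - 1L) %% m) + 1L
  gi <- ((cells - 1L) %/% m) + 1L
  association_set(tibble(phenotype = phenotype_ids[pi], gene = gene_ids[gi]),
                  phenotype_ids, gene_ids)
}

#' Coverage under the randomized-association null
#'
#' Replaces the observed associations by `k` uniform random pairs, recomputes
#' the CBG coverage curve, and repeats; reports the mean and standard
#' deviation per length L. This is the reference against which the observed
#' (non-random) coverage is judged.
#'
#' @param P,G `birw_graph`s.
#' @param k Number of random associations per replicate.
#' @param L_max Truncation length.
#' @param reps Number of replicates, >= 1.
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `L`, `mean_coverage`, `sd_coverage` (sd is NA
#'   for `reps = 1`).
#' @export
null_coverage <- function(P, G, k, L_max, reps, seed = NULL) {
  stopifnot(reps >= 1)
  run <- function() {
    vapply(seq_len(reps), function(rep) {
      A0 <- randomize_associations(P$ids, G$ids, k)
      cov <- cbg_min_lengths(P, G, A0, L_max)
      cbg_coverage_curve(cov)$coverage
    }, numeric(L_max))
  }
  covs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  covs <- matrix(covs, nrow = L_max)
  tibble(
    L = seq_len(L_max),
    mean_coverage = apply(covs, 1, mean),
    sd_coverage = apply(covs, 1, sd)
  )
}

#' Per-disease-class CBG coverage table
#'
#' Partitions associations by the disease class of their phenotype and counts,
#' per class, how many are covered by CBGs of length 1, <= 2, ..., <= L_max,
#' mirroring the per-class coverage tables of phenome-wide CBG analyses.
#' Phenotypes missing from the class map fall into class `"unknown"`.
#'
#' @param cov A `cbg_coverage`.
#' @param class_map Tibble with columns `phenotype`, `class` (see
#'   [read_class_map_tsv()]).
#' @return Tibble with one row per class: covered counts at each L, the
#'   association and phenotype counts, and coverage percentages at L <= 2 and
#'   L <= L_max.
#' @export
class_coverage_table <- function(cov, class_map) {
  stopifnot(inherits(cov, "cbg_coverage"))
  a <- cov$associations %>%
    left_join(class_map, by = "phenotype") %>%
    mutate(class = ifelse(is.na(.data$class), "unknown", .data$class))
  L_max <- cov$L_max
  rows <- a %>%
    group_by(.data$class) %>%
    summarise(
      n_assoc = n(),
      n_pheno = dplyr::n_distinct(.data$phenotype),
      covered = list(vapply(seq_len(L_max),
                            function(l) sum(.data$min_length <= l), integer(1))),
      .groups = "drop"
    )
  cov_mat <- do.call(rbind, rows$covered)
  colnames(cov_mat) <- paste0("covered_le_", seq_len(L_max))
  cov_cols <- as_tibble(cov_mat)
  out <- dplyr::bind_cols(select(rows, -"covered"), cov_cols)
  if (L_max >= 2) {
    out$pct_le_2 <- 100 * out$covered_le_2 / out$n_assoc
  }
  out[[paste0("pct_le_", L_max)]] <-
    100 * out[[paste0("covered_le_", L_max)]] / out$n_assoc
  arrange(out, .data$class)
}
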