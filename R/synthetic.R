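# Synthetic heterogeneous networks with planted circular-bigraph structure.
# The generator emulates the qualitative features the method exploits: a
# phenotype similarity network with local neighborhood structure, a
# small-world gene interaction network, and an association set in which most
# pairs have a partner association a short walk away (a planted CBG), plus
# uniform noise and an ab-initio holdout.

#' Synthetic benchmark configuration
#'
#' Defaults define the package's standard benchmark condition: 150 phenotypes
#' on a ring with 5-nearest-neighbor similarity edges, a 200-gene small-world
#' interaction network, 120 seed associations of which 80% spawn a partner
#' within path length 2 on both sides, 10% uniform noise associations, and an
#' ab-initio holdout of 20% of the associated phenotypes.
#'
#' @param m,n Phenotype and gene counts.
#' @param pheno_knn k for the phenotype kNN graph.
#' @param gene_degree Mean gene degree of the small-world network (even).
#' @param rewire_prob Small-world rewiring probability.
#' @param n_seed_assoc Number of seed associations.
#' @param expansion_prob Probability a seed spawns a partner association.
#' @param partner_radius Maximum hop distance L of the planted partner on
#'   both networks.
#' @param noise_frac Fraction of additional uniform random associations.
#' @param holdout_frac Fraction of associated phenotypes whose associations
#'   are moved, in full, to the held-out truth set.
#' @param seed Integer RNG seed; the full output is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(m = 150L, n = 200L, pheno_knn = 5L,
                             gene_degree = 2L, rewire_prob = 0.05,
                             n_seed_assoc = 120L, expansion_prob = 0.8,
                             partner_radius = 2L, noise_frac = 0.1,
                             holdout_frac = 0.2, seed = 1L) {
  stopifnot(m >= 4, n >= 4, pheno_knn >= 1, gene_degree >= 2,
            expansion_prob >= 0, expansion_prob <= 1,
            noise_frac >= 0, noise_frac <= 1,
            holdout_frac >= 0, holdout_frac < 1,
            partner_radius >= 1, n_seed_assoc >= 1)
  structure(list(m = as.integer(m), n = as.integer(n),
                 pheno_knn = as.integer(pheno_knn),
                 gene_degree = as.integer(gene_degree),
                 rewire_prob = rewire_prob,
                 n_seed_assoc = as.integer(n_seed_assoc),
                 expansion_prob = expansion_prob,
                 partner_radius = as.integer(partner_radius),
                 noise_frac = noise_frac, holdout_frac = holdout_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

ring_similarity <- function(m, tau = 2) {
  idx <- seq_len(m)
  d <- outer(idx, idx, function(i, j) pmin(abs(i - j), m - abs(i - j)))
  S <- exp(-d / tau)
  diag(S) <- 0
  S
}

#' Generate a synthetic heterogeneous network with planted CBGs
#'
#' Draws the networks and associations described in [synthetic_config()].
#' Random numbers are consumed in a fixed order (phenotype similarity noise,
#' gene network, seed associations, partner placement, noise associations,
#' holdout choice), so outputs are byte-identical across runs with the same
#' config. Partner placement that finds no admissible node within the radius
#' is skipped and counted, never retried indefinitely.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_data`:
#'   `net` (a `birw_heteronet` with the observed associations),
#'   `truth` (a `birw_assoc` of held-out associations),
#'   `associations` (tibble of all generated pairs with `planted` — member of
#'   an intentionally created CBG pair — and `held_out` flags),
#'   `holdout_phenotypes`, `n_skipped` and `config`.
#' @export
generate_hetero <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_hetero_impl(config))
}

generate_hetero_impl <- function(cfg) {
  m <- cfg$m; n <- cfg$n
  phen_ids <- sprintf("p%03d", seq_len(m))
  gene_ids <- sprintf("g%03d", seq_len(n))

  # 1. phenotype similarity: ring locality, jittered to break kNN ties
  S <- ring_similarity(m)
  noise <- matrix(runif(m * m, 0.9, 1.0), m, m)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  S <- pmin(S * noise, 1)
  diag(S) <- 0
  P <- knn_sparsify(as_weighted_graph(S, ids = phen_ids), cfg$pheno_knn)

  # 2. gene network: Watts-Strogatz small world, unit weights
  ig <- igraph::sample_smallworld(1, n, cfg$gene_degree %/% 2, cfg$rewire_prob)
  Gadj <- igraph::as_adjacency_matrix(ig, sparse = TRUE)
  Gadj <- ((Gadj + Matrix::t(Gadj)) > 0) * 1
  G <- as_weighted_graph(Gadj, ids = gene_ids)

  # hop distances used for partner placement (same graphs the analysis sees)
  dP <- igraph::distances(graph_from_weights(P))
  dG <- igraph::distances(graph_from_weights(G))

  # 3. seed associations, uniform distinct
  cells <- sample.int(m * n, cfg$n_seed_assoc)
  seed_p <- ((cells - 1L) %% m) + 1L
  seed_g <- ((cells - 1L) %/% m) + 1L
  pair_key <- function(p, g) paste(p, g)
  existing <- pair_key(seed_p, seed_g)
  pairs <- tibble(p = seed_p, g = seed_g, planted = FALSE)

  # 4. partner placement: for each seed, with expansion_prob put a second
  # association forming a CBG of length <= L (sharing at most one end).
  # The CBG length is drawn uniformly from 1..L and the partner uniformly
  # among the cells at exactly that length, so short CBGs dominate the
  # planted structure just as they dominate real association networks.
  L <- cfg$partner_radius
  n_skipped <- 0L
  for (i in seq_len(cfg$n_seed_assoc)) {
    if (runif(1) > cfg$expansion_prob) next
    p0 <- seed_p[i]; g0 <- seed_g[i]
    cand_p <- which(dP[p0, ] <= L)
    cand_g <- which(dG[g0, ] <= L)
    grid <- expand.grid(p = cand_p, g = cand_g)
    grid$len <- pmax(dP[p0, grid$p], dG[g0, grid$g])
    grid <- grid[grid$len >= 1, , drop = FALSE]  # excludes the seed itself
    grid <- grid[!pair_key(grid$p, grid$g) %in% existing, , drop = FALSE]
    if (nrow(grid) == 0) { n_skipped <- n_skipped + 1L; next }
    target_len <- sample.int(L, 1)
    at_len <- grid[grid$len == target_len, , drop = FALSE]
    if (nrow(at_len) == 0) at_len <- grid  # fall back to the whole <= L ball
    pick <- at_len[sample.int(nrow(at_len), 1), ]
    existing <- c(existing, pair_key(pick$p, pick$g))
    pairs <- bind_rows(pairs, tibble(p = pick$p, g = pick$g, planted = TRUE))
    pairs$planted[i] <- TRUE
  }

  # 5. uniform noise associations
  n_noise <- round(cfg$noise_frac * nrow(pairs))
  added <- 0L
  while (added < n_noise) {
    p <- sample.int(m, 1); g <- sample.int(n, 1)
    if (pair_key(p, g) %in% existing) next
    existing <- c(existing, pair_key(p, g))
    pairs <- bind_rows(pairs, tibble(p = p, g = g, planted = FALSE))
    added <- added + 1L
  }

  # 6. ab-initio holdout: move all associations of a phenotype subset
  assoc_ph <- sort(unique(pairs$p))
  n_hold <- round(cfg$holdout_frac * length(assoc_ph))
  hold_ph <- sort(sample(assoc_ph, n_hold))
  pairs$held_out <- pairs$p %in% hold_ph

  all_pairs <- tibble(phenotype = phen_ids[pairs$p], gene = gene_ids[pairs$g],
                      planted = pairs$planted, held_out = pairs$held_out)
  observed <- association_set(filter(all_pairs, !.data$held_out),
                              phen_ids, gene_ids)
  truth <- association_set(filter(all_pairs, .data$held_out),
                           phen_ids, gene_ids)
  list(
    net = hetero_net(P, G, observed),
    truth = truth,
    associations = all_pairs,
    holdout_phenotypes = phen_ids[hold_ph],
    n_skipped = n_skipped,
    config = cfg
  )
}

#' Tiny named fixture networks
#'
#' Hand-built instances used across examples and tests:
#' * `rectangle` — 2 phenotypes, 2 genes, one edge on each side, two
#'   associations forming a length-1 CBG rectangle;
#' * `triangle` — 2 phenotypes sharing one causal gene (length-1 triangle,
#'   gene path of length 0);
#' * `fig1_shape` — a connected 7-phenotype / 8-gene instance shaped like a
#'   small disease-gene association subnetwork, for structural smoke tests.
#'
#' @return Named list of `birw_heteronet` objects.
#' @export
fixture_suite <- function() {
  rect_P <- weighted_graph(tibble(node_a = "p1", node_b = "p2", weight = 1),
                           ids = c("p1", "p2"))
  rect_G <- weighted_graph(tibble(node_a = "g1", node_b = "g2", weight = 1),
                           ids = c("g1", "g2"))
  rect_A <- association_set(
    tibble(phenotype = c("p1", "p2"), gene = c("g1", "g2")),
    c("p1", "p2"), c("g1", "g2"))

  tri_G <- weighted_graph(tibble(node_a = character(0), node_b = character(0),
                                 weight = numeric(0)), ids = c("g1", "g2"))
  tri_A <- association_set(
    tibble(phenotype = c("p1", "p2"), gene = c("g1", "g1")),
    c("p1", "p2"), c("g1", "g2"))

  f_ph <- sprintf("p%d", 1:7)
  f_gn <- sprintf("g%d", 1:8)
  f_P <- weighted_graph(tibble(
    node_a = c("p1", "p2", "p3", "p4", "p5", "p6", "p1"),
    node_b = c("p2", "p3", "p4", "p5", "p6", "p7", "p3"),
    weight = c(0.9, 0.8, 0.7, 0.6, 0.8, 0.9, 0.5)
  ), ids = f_ph)
  f_G <- weighted_graph(tibble(
    node_a = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g1", "g3"),
    node_b = c("g2", "g3", "g4", "g5", "g6", "g7", "g8", "g4", "g6")
  ), ids = f_gn)
  f_A <- association_set(tibble(
    phenotype = c("p1", "p2", "p3", "p4", "p5", "p6", "p7"),
    gene = c("g1", "g2", "g4", "g3", "g6", "g7", "g8")
  ), f_ph, f_gn)

  list(
    rectangle = hetero_net(rect_P, rect_G, rect_A),
    triangle = hetero_net(rect_P, tri_G, tri_A),
    fig1_shape = hetero_net(f_P, f_G, f_A)
  )
}
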