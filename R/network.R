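# Heterogeneous-network containers: a weighted undirected graph, a bipartite
# association set, and the combined phenotype-gene network.

#' Build a weighted undirected graph from an edge table
#'
#' Constructs the basic network container used throughout the package: a
#' symmetric sparse weight matrix with a zero diagonal over an ordered set of
#' node labels. Phenotype similarity networks carry weights in \[0, 1\];
#' protein interaction networks are typically binary (weight 1).
#'
#' Self-loops in the input are dropped (the diagonal is forced to zero).
#' A pair listed in both orientations is tolerated when the weights agree and
#' is an error otherwise.
#'
#' @param edges Data frame with columns `node_a`, `node_b` and optionally
#'   `weight` (default 1).
#' @param ids Optional character vector of node labels fixing the node universe
#'   and its order; defaults to the sorted labels present in `edges`. Labels in
#'   `edges` absent from `ids` are an error.
#' @param max_weight Optional upper bound on weights (use 1 for similarity
#'   networks); violations are an error.
#'
#' @return An object of class `birw_graph`: a list with `weights` (sparse
#'   symmetric `dgCMatrix`) and `ids` (character).
#' @examples
#' g <- weighted_graph(tibble::tibble(
#'   node_a = c("a", "b"), node_b = c("b", "c"), weight = c(0.9, 0.4)
#' ))
#' tidy(g)
#' @export
weighted_graph <- function(edges, ids = NULL, max_weight = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("node_a", "node_b") %in% names(edges)))
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
    abort("edge weights must be finite and non-negative")
  }
  if (!is.null(max_weight) && any(edges$weight > max_weight + 1e-12)) {
    abort(sprintf("edge weights exceed the declared maximum %g", max_weight))
  }
  if (is.null(ids)) {
    ids <- sort(unique(c(edges$node_a, edges$node_b)))
  } else {
    ids <- as.character(ids)
    if (anyDuplicated(ids)) abort("duplicate node labels in `ids`")
    unknown <- setdiff(unique(c(edges$node_a, edges$node_b)), ids)
    if (length(unknown) > 0) {
      abort(paste0("edge labels not in `ids`: ", paste(head(unknown, 5), collapse = ", ")))
    }
  }
  n <- length(ids)
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]  # drop self-loops
  i <- match(edges$node_a, ids)
  j <- match(edges$node_b, ids)
  # canonical orientation so a duplicated reversed pair lands on one cell
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    sp <- split(edges$weight, key)
    bad <- names(sp)[vapply(sp, function(w) diff(range(w)) > 1e-12, logical(1))]
    if (length(bad) > 0) {
      abort(paste0("conflicting duplicate edges (weights disagree) for ",
                   length(bad), " node pair(s)"))
    }
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
    w <- edges$weight[keep]
  } else {
    w <- edges$weight
  }
  W <- sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                    dims = c(n, n), dimnames = list(ids, ids))
  new_birw_graph(drop0(W), ids)
}

new_birw_graph <- function(weights, ids) {
  structure(list(weights = weights, ids = ids), class = "birw_graph")
}

#' Coerce a symmetric matrix to a `birw_graph`
#'
#' @param W Square symmetric non-negative matrix (dense or sparse); dimnames,
#'   if absent, are taken from `ids`.
#' @param ids Node labels; defaults to rownames or `v1..vn`.
#' @return A `birw_graph`.
#' @export
as_weighted_graph <- function(W, ids = NULL) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(W) != ncol(W)) abort("matrix must be square")
  if (!isTRUE(all.equal(max(abs(W - Matrix::t(W))), 0))) abort("matrix must be symmetric")
  if (any(W@x < 0)) abort("weights must be non-negative")
  if (is.null(ids)) ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(W)))
  diag(W) <- 0
  dimnames(W) <- list(ids, ids)
  new_birw_graph(drop0(W), ids)
}

#' @export
print.birw_graph <- function(x, ...) {
  cat(sprintf("<birw_graph> %d nodes, %d edges\n",
              length(x$ids), Matrix::nnzero(x$weights) / 2))
  invisible(x)
}

#' @export
tidy.birw_graph <- function(x, ...) {
  s <- Matrix::summary(Matrix::triu(x$weights))
  tibble(node_a = x$ids[s$i], node_b = x$ids[s$j], weight = s$x) %>%
    arrange(.data$node_a, .data$node_b)
}

n_nodes <- function(g) length(g$ids)

#' Build a bipartite phenotype-gene association set
#'
#' @param pairs Data frame with columns `phenotype` and `gene`. Duplicates are
#'   collapsed.
#' @param phenotype_ids,gene_ids Label universes (order fixed). Pairs naming
#'   labels outside these universes are an error that lists the offenders.
#' @return Object of class `birw_assoc` with the de-duplicated `pairs` tibble
#'   and the two label vectors; [assoc_matrix()] gives the binary sparse
#'   matrix view.
#' @examples
#' a <- association_set(tibble::tibble(phenotype = "p1", gene = "g2"),
#'                      c("p1", "p2"), c("g1", "g2"))
#' assoc_matrix(a)
#' @export
association_set <- function(pairs, phenotype_ids, gene_ids) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("phenotype", "gene") %in% names(pairs)))
  pairs$phenotype <- as.character(pairs$phenotype)
  pairs$gene <- as.character(pairs$gene)
  phenotype_ids <- as.character(phenotype_ids)
  gene_ids <- as.character(gene_ids)
  bad_p <- setdiff(unique(pairs$phenotype), phenotype_ids)
  bad_g <- setdiff(unique(pairs$gene), gene_ids)
  if (length(bad_p) > 0 || length(bad_g) > 0) {
    abort(paste0(
      "association labels not present in the networks: ",
      paste(head(c(bad_p, bad_g), 10), collapse = ", ")
    ))
  }
  pairs <- distinct(pairs[, c("phenotype", "gene")])
  pairs <- arrange(pairs, match(.data$phenotype, phenotype_ids),
                   match(.data$gene, gene_ids))
  structure(list(pairs = pairs, row_ids = phenotype_ids, col_ids = gene_ids),
            class = "birw_assoc")
}

#' Binary sparse matrix view of an association set
#'
#' @param a A `birw_assoc`.
#' @return An m x n sparse 0/1 matrix with phenotype rows and gene columns.
#' @export
assoc_matrix <- function(a) {
  sparseMatrix(
    i = match(a$pairs$phenotype, a$row_ids),
    j = match(a$pairs$gene, a$col_ids),
    x = 1,
    dims = c(length(a$row_ids), length(a$col_ids)),
    dimnames = list(a$row_ids, a$col_ids)
  )
}

#' @export
print.birw_assoc <- function(x, ...) {
  cat(sprintf("<birw_assoc> %d associations over %d phenotypes x %d genes\n",
              nrow(x$pairs), length(x$row_ids), length(x$col_ids)))
  invisible(x)
}

#' @export
tidy.birw_assoc <- function(x, ...) x$pairs

n_assoc <- function(a) nrow(a$pairs)

#' Assemble a heterogeneous phenotype-gene network
#'
#' Bundles the phenotype similarity graph P (m x m), the gene interaction
#' graph G (n x n) and the bipartite association set A (m x n) with consistent
#' label indices.
#'
#' @param P `birw_graph` of phenotypes.
#' @param G `birw_graph` of genes.
#' @param A `birw_assoc` whose row/col universes equal the node sets of `P`
#'   and `G` (same order).
#' @return Object of class `birw_heteronet` with elements `P`, `G`, `A`, `m`, `n`.
#' @export
hetero_net <- function(P, G, A) {
  stopifnot(inherits(P, "birw_graph"), inherits(G, "birw_graph"),
            inherits(A, "birw_assoc"))
  if (!identical(A$row_ids, P$ids) || !identical(A$col_ids, G$ids)) {
    abort("association label universes must match the phenotype and gene graphs")
  }
  structure(list(P = P, G = G, A = A, m = length(P$ids), n = length(G$ids)),
            class = "birw_heteronet")
}

#' @export
print.birw_heteronet <- function(x, ...) {
  cat(sprintf("<birw_heteronet> %d phenotypes, %d genes, %d associations\n",
              x$m, x$n, n_assoc(x$A)))
  invisible(x)
}

#' Symmetric degree normalization D^(-1/2) W D^(-1/2)
#'
#' Normalizes a symmetric non-negative weight matrix by its degree (row-sum)
#' diagonal on both sides. Rows and columns of zero-degree nodes are left
#' all-zero rather than raising a division error, so isolated components in
#' sparse interaction networks are handled gracefully. The spectral radius of
#' the result is at most 1.
#'
#' @param W Square symmetric non-negative matrix (dense or sparse).
#' @return A matrix of the same shape, symmetric, spectral radius <= 1.
#' @examples
#' W <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)  # path a-b-c
#' symmetric_normalize(W)                            # edges become 1/sqrt(2)
#' @export
symmetric_normalize <- function(W) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(W) != ncol(W)) abort("symmetric_normalize: matrix must be square")
  if (max(abs(W - Matrix::t(W))) > 1e-9) {
    abort("symmetric_normalize: matrix must be symmetric")
  }
  if (length(W@x) && any(W@x < 0)) abort("symmetric_normalize: weights must be non-negative")
  deg <- Matrix::rowSums(W)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  D <- Diagonal(x = inv_sqrt)
  out <- D %*% W %*% D
  dimnames(out) <- dimnames(W)
  out
}

#' Grand-sum normalization of an association matrix
#'
#' Divides by the sum of all entries so the matrix carries unit total mass —
#' the initial distribution of the bi-random walk.
#'
#' @param A Non-negative m x n matrix with at least one nonzero entry.
#' @return `A / sum(A)`.
#' @export
sum_normalize <- function(A) {
  s <- sum(A)
  if (s == 0) abort("empty association set: cannot normalize an all-zero matrix")
  A / s
}

#' k-nearest-neighbor sparsification of a similarity graph
#'
#' Retains the edge (i, j) iff j is among i's k highest-weight neighbors or i
#' is among j's (union symmetrization, preserving connectivity). Neighbors
#' tied with the k-th weight are all kept, so the result is deterministic and
#' idempotent. Retained edges keep their original weights. Nodes with fewer
#' than k neighbors keep all of them.
#'
#' @param S A `birw_graph` (or symmetric matrix).
#' @param k Number of nearest neighbors, >= 1.
#' @return Object of the same type as `S`, sparsified.
#' @export
knn_sparsify <- function(S, k) {
  stopifnot(k >= 1)
  is_graph <- inherits(S, "birw_graph")
  W <- if (is_graph) S$weights else methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  n <- nrow(W)
  Wt <- Matrix::t(W)  # CsparseMatrix: column slices of Wt are rows of W
  keep_i <- integer(0); keep_j <- integer(0)
  p <- Wt@p; idx <- Wt@i; val <- Wt@x
  for (row in seq_len(n)) {
    r <- (p[row] + 1):p[row + 1]
    if (p[row] == p[row + 1]) next
    nb <- idx[r] + 1L
    w <- val[r]
    pos <- w > 0
    nb <- nb[pos]; w <- w[pos]
    if (length(nb) == 0) next
    if (length(nb) > k) {
      thr <- sort(w, decreasing = TRUE)[k]
      sel <- w >= thr  # ties at the k-th weight all kept
    } else {
      sel <- rep(TRUE, length(nb))
    }
    keep_i <- c(keep_i, rep.int(row, sum(sel)))
    keep_j <- c(keep_j, nb[sel])
  }
  mask <- sparseMatrix(i = keep_i, j = keep_j, x = 1, dims = c(n, n))
  mask <- ((mask + Matrix::t(mask)) > 0) * 1  # union symmetrization
  out <- drop0(W * mask)
  dimnames(out) <- dimnames(W)
  if (is_graph) new_birw_graph(out, S$ids) else out
}

#' Normalize a heterogeneous network for the bi-random walk
#'
#' Applies [symmetric_normalize()] to both graphs and [sum_normalize()] to the
#' association matrix, caching the degree vectors.
#'
#' @param net A `birw_heteronet`.
#' @return Object of class `birw_normnet` with `P_norm`, `G_norm`, `A_norm`,
#'   `deg_P`, `deg_G` and the label vectors.
#' @export
normalize_hetero <- function(net) {
  stopifnot(inherits(net, "birw_heteronet"))
  A <- assoc_matrix(net$A)
  structure(list(
    P_norm = symmetric_normalize(net$P$weights),
    G_norm = symmetric_normalize(net$G$weights),
    A_norm = sum_normalize(A),
    deg_P = Matrix::rowSums(net$P$weights),
    deg_G = Matrix::rowSums(net$G$weights),
    phenotype_ids = net$P$ids,
    gene_ids = net$G$ids
  ), class = "birw_normnet")
}
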