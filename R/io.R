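# Readers/writers for the plain-text exchange formats:
#   graph TSV:       node_a <TAB> node_b <TAB> weight   (weight optional, 1.0)
#   association TSV: phenotype_id <TAB> gene_id
#   class map TSV:   phenotype_id <TAB> class_name
#   scores TSV:      phenotype <TAB> gene <TAB> score
# Comment lines start with '#'; no header rows.

read_tsv_lines <- function(path, n_min, n_max, what) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < n_min | nf > n_max)
  if (length(bad) > 0) {
    abort(sprintf("malformed %s line %d in '%s': expected %d-%d tab-separated fields, got %d",
                  what, rows[bad[1]], path, n_min, n_max, nf[bad[1]]))
  }
  list(parts = parts, rows = rows)
}

#' Read a weighted edge list from TSV
#'
#' Format: `node_a<TAB>node_b<TAB>weight`, the weight optional (default 1.0);
#' lines starting with `#` are comments. Malformed lines raise an error
#' carrying the line number.
#'
#' @param path File path.
#' @param ids Optional fixed node universe (see [weighted_graph()]).
#' @param max_weight Optional weight cap (1 for similarity networks).
#' @return A `birw_graph`.
#' @export
read_graph_tsv <- function(path, ids = NULL, max_weight = NULL) {
  p <- read_tsv_lines(path, 2, 3, "graph")
  w <- vapply(p$parts, function(f) if (length(f) >= 3) as.numeric(f[3]) else 1.0, numeric(1))
  if (any(is.na(w))) {
    bad <- which(is.na(w))[1]
    abort(sprintf("malformed graph line %d in '%s': non-numeric weight", p$rows[bad], path))
  }
  edges <- tibble(
    node_a = vapply(p$parts, `[`, character(1), 1),
    node_b = vapply(p$parts, `[`, character(1), 2),
    weight = w
  )
  weighted_graph(edges, ids = ids, max_weight = max_weight)
}

#' Read a phenotype-gene association list from TSV
#'
#' Format: `phenotype_id<TAB>gene_id`. Labels absent from the supplied
#' universes raise an error listing the offenders.
#'
#' @param path File path.
#' @param phenotype_ids,gene_ids Label universes.
#' @return A `birw_assoc`.
#' @export
read_associations_tsv <- function(path, phenotype_ids, gene_ids) {
  p <- read_tsv_lines(path, 2, 2, "association")
  pairs <- tibble(
    phenotype = vapply(p$parts, `[`, character(1), 1),
    gene = vapply(p$parts, `[`, character(1), 2)
  )
  association_set(pairs, phenotype_ids, gene_ids)
}

#' Read a phenotype-to-disease-class map from TSV
#'
#' Format: `phenotype_id<TAB>class_name`.
#'
#' @param path File path.
#' @return A tibble with columns `phenotype`, `class`.
#' @export
read_class_map_tsv <- function(path) {
  p <- read_tsv_lines(path, 2, 2, "class map")
  tibble(
    phenotype = vapply(p$parts, `[`, character(1), 1),
    class = vapply(p$parts, `[`, character(1), 2)
  )
}

#' Write / read a score matrix as long-format TSV
#'
#' `write_scores_tsv()` writes `phenotype<TAB>gene<TAB>score` rows at full
#' double precision (17 significant digits) so a write/read round trip
#' reproduces every value exactly. Zero scores are written too, keeping the
#' round trip lossless for dense matrices.
#'
#' @param R Numeric matrix of scores (phenotype rows, gene columns).
#' @param phenotype_ids,gene_ids Labels; default to `dimnames(R)`.
#' @param path Output / input file path.
#' @return `write_scores_tsv()` returns `path` invisibly; `read_scores_tsv()`
#'   returns a dense matrix with dimnames.
#' @export
write_scores_tsv <- function(R, path, phenotype_ids = rownames(R),
                             gene_ids = colnames(R)) {
  R <- as.matrix(R)
  stopifnot(length(phenotype_ids) == nrow(R), length(gene_ids) == ncol(R))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(R))) {
    writeLines(sprintf("%s\t%s\t%.17g", phenotype_ids[i], gene_ids, R[i, ]), con)
  }
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  p <- read_tsv_lines(path, 3, 3, "scores")
  ph <- vapply(p$parts, `[`, character(1), 1)
  gn <- vapply(p$parts, `[`, character(1), 2)
  sc <- as.numeric(vapply(p$parts, `[`, character(1), 3))
  if (any(is.na(sc))) abort(sprintf("malformed scores line in '%s': non-numeric score", path))
  phenotype_ids <- unique(ph)
  gene_ids <- unique(gn)
  R <- matrix(0, length(phenotype_ids), length(gene_ids),
              dimnames = list(phenotype_ids, gene_ids))
  R[cbind(match(ph, phenotype_ids), match(gn, gene_ids))] <- sc
  R
}

#' Write a graph or association set back to TSV
#'
#' @param x A `birw_graph` or `birw_assoc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(x, path) {
  e <- tidy(x)
  writeLines(sprintf("%s\t%s\t%.17g", e$node_a, e$node_b, e$weight), path)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
write_associations_tsv <- function(x, path) {
  writeLines(sprintf("%s\t%s", x$pairs$phenotype, x$pairs$gene), path)
  invisible(path)
}
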