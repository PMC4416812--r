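# Building a phenotype similarity network from a phenotype ontology:
# select the terms at a fixed depth, pull gene annotations up from their
# descendants, and connect terms by the Jaccard similarity of the propagated
# gene sets. This mirrors the preparation of mouse phenotype networks from
# the Mammalian Phenotype ontology, where annotation density peaks at level 5.

#' Parse a minimal OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas and their `id:`, `name:` and `is_a:` tags; all
#' other tags and relationship types (e.g. `part_of`) are ignored, and terms
#' flagged `is_obsolete: true` are skipped.
#'
#' @param path OBO file path.
#' @return An `ontology_dag`: list with `terms` (character ids), `names`
#'   (named character), `parents` (named list of is_a parents) and `root`
#'   (the unique term without parents; multiple roots are an error).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && !is.null(cur)) {
      if (grepl("^id: ", ln)) cur$id <- sub("^id: ", "", ln)
      else if (grepl("^name: ", ln)) cur$name <- sub("^name: ", "", ln)
      else if (grepl("^is_a: ", ln)) {
        target <- sub("^is_a:\\s*", "", ln)
        target <- sub("\\s*(!.*)?$", "", target)
        cur$parents <- c(cur$parents, target)
      } else if (grepl("^is_obsolete: true", ln)) cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$parents, ids))
  nms <- vapply(terms, function(t) t$name %||% NA_character_, character(1))
  ontology_dag(ids, parents, nms)
}

#' Construct an ontology DAG
#'
#' @param terms Character term ids.
#' @param parents Named list: term -> character vector of is_a parents.
#' @param names Optional named character of term names.
#' @return An `ontology_dag`; cycles and multiple roots are errors.
#' @export
ontology_dag <- function(terms, parents, names = NULL) {
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  roots <- terms[lengths(parents) == 0]
  if (length(roots) != 1) {
    abort(sprintf("ontology must have exactly one root (found %d)", length(roots)))
  }
  dag <- structure(list(terms = terms, parents = parents, root = roots,
                        names = names), class = "ontology_dag")
  term_levels(dag)  # raises on cycles / unreachable terms
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, root %s\n", length(x$terms), x$root))
  invisible(x)
}

children_map <- function(dag) {
  ch <- lapply(setNames(vector("list", length(dag$terms)), dag$terms), function(x) character(0))
  for (t in dag$terms) for (p in dag$parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  ch
}

#' Depth level of every ontology term
#'
#' `level(t) = root_level + length of the shortest is_a path from the root to
#' t` (breadth-first from the root over child edges). With the default
#' `root_level = 1` the root is level 1, so "level 5" counts the root as the
#' first level.
#'
#' @param dag An `ontology_dag`.
#' @param root_level Level assigned to the root (default 1).
#' @return Named integer vector over all terms. Terms not reachable from the
#'   root, or cycles, are errors.
#' @export
term_levels <- function(dag, root_level = 1L) {
  ch <- children_map(dag)
  lev <- setNames(rep(NA_integer_, length(dag$terms)), dag$terms)
  lev[dag$root] <- as.integer(root_level)
  frontier <- dag$root
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (t in frontier) {
      for (c in ch[[t]]) {
        if (is.na(lev[c])) {
          lev[c] <- lev[t] + 1L
          nxt <- c(nxt, c)
        }
      }
    }
    frontier <- nxt
  }
  if (anyNA(lev)) {
    abort(sprintf("%d term(s) cannot reach the root via is_a (cycle or orphan)",
                  sum(is.na(lev))))
  }
  lev
}

descendants_of <- function(dag, term) {
  ch <- children_map(dag)
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    kids <- unique(unlist(ch[frontier], use.names = FALSE))
    kids <- setdiff(kids, seen)
    seen <- c(seen, kids)
    frontier <- kids
  }
  seen
}

#' Propagate term-gene annotations up to the terms of one level
#'
#' A term t at the chosen level is associated with gene g iff t itself or any
#' descendant of t carries an annotation to g — the standard
#' true-path-rule roll-up that turns leaf-level annotations into associations
#' for the broader level-k phenotypes.
#'
#' @param dag An `ontology_dag`.
#' @param annotations Data frame with columns `term`, `gene`; terms must
#'   exist in the ontology.
#' @param level Target level (counted as in [term_levels()]).
#' @param root_level Passed to [term_levels()].
#' @return A `birw_assoc` whose phenotype universe is the level-k terms and
#'   whose gene universe is the annotated genes (sorted).
#' @export
propagate_annotations <- function(dag, annotations, level, root_level = 1L) {
  annotations <- as_tibble(annotations)
  stopifnot(all(c("term", "gene") %in% names(annotations)))
  unknown <- setdiff(unique(annotations$term), dag$terms)
  if (length(unknown) > 0) {
    abort(paste0("annotation terms absent from the ontology: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  lev <- term_levels(dag, root_level)
  level_terms <- names(lev)[lev == level]
  gene_ids <- sort(unique(annotations$gene))
  ann_by_term <- split(annotations$gene, annotations$term)
  pairs <- purrr::map_dfr(level_terms, function(t) {
    scope <- c(t, descendants_of(dag, t))
    genes <- unique(unlist(ann_by_term[intersect(scope, names(ann_by_term))],
                           use.names = FALSE))
    if (length(genes) == 0) return(tibble(phenotype = character(0), gene = character(0)))
    tibble(phenotype = t, gene = genes)
  })
  association_set(pairs, level_terms, gene_ids)
}

#' Jaccard similarity network over term gene sets
#'
#' Connects two terms by `|S_t intersect S_u| / |S_t union S_u|` over their
#' (propagated) gene sets; pairs where both sets are empty get similarity 0,
#' and the diagonal is zero.
#'
#' @param assoc A `birw_assoc` (e.g. from [propagate_annotations()]); rows
#'   are the terms.
#' @return A `birw_graph` over the terms with weights in \[0, 1\].
#' @export
jaccard_network <- function(assoc) {
  A <- assoc_matrix(assoc)
  inter <- as.matrix(Matrix::tcrossprod(A))        # |S_t ^ S_u|
  sizes <- Matrix::rowSums(A)
  uni <- outer(sizes, sizes, `+`) - inter
  W <- ifelse(uni > 0, inter / uni, 0)
  diag(W) <- 0
  as_weighted_graph(W, ids = assoc$row_ids)
}
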