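# Disease-class bi-modules: recurrent known/predicted genes across the
# phenotypes of one disease class, extracted from the reconstructed
# association matrix.

#' Extract a disease-class bi-module
#'
#' For each phenotype of the class, the candidate genes are its known disease
#' genes plus its top `ceiling(top_frac * n)` genes by predicted score (with
#' `top_frac = 0.03` and a gene universe of 2466 this is the published
#' "top 3%", 74 genes). A gene enters the module when it is a candidate for
#' at least `min(min_support, number of class phenotypes)` phenotypes of the
#' class — the fallback to the class size covers classes with fewer
#' phenotypes than the support threshold. Known disease genes always count
#' toward support, whatever their rank. Ranking ties are broken by gene
#' label, so the module is deterministic.
#'
#' @param prediction A `birw_prediction` (or score matrix with dimnames).
#' @param A A `birw_assoc` of known associations.
#' @param class_phenotypes Phenotype labels of the disease class.
#' @param top_frac Fraction of the gene universe taken per phenotype,
#'   in (0, 1\]; default 0.03.
#' @param min_support Minimum number of supporting class phenotypes;
#'   default 5.
#' @return A `birw_bimodule`: tibble of module genes with columns `gene`,
#'   `support`, `known` (TRUE if known for any class phenotype), plus
#'   attributes; empty class gives an empty module with a warning.
#' @export
extract_bimodule <- function(prediction, A, class_phenotypes,
                             top_frac = 0.03, min_support = 5L) {
  stopifnot(top_frac > 0, top_frac <= 1, min_support >= 1)
  R <- if (inherits(prediction, "birw_prediction")) prediction$R else as.matrix(prediction)
  class_phenotypes <- intersect(class_phenotypes, rownames(R))
  if (length(class_phenotypes) == 0) {
    warn("extract_bimodule: empty disease class")
    return(structure(tibble(gene = character(0), support = integer(0),
                            known = logical(0)),
                     class = c("birw_bimodule", "tbl_df", "tbl", "data.frame"),
                     class_phenotypes = character(0),
                     support_threshold = NA_integer_))
  }
  n <- ncol(R)
  top_k <- ceiling(top_frac * n)
  threshold <- min(min_support, length(class_phenotypes))
  known_by_ph <- split(A$pairs$gene, factor(A$pairs$phenotype, levels = A$row_ids))
  candidates <- purrr::map(class_phenotypes, function(p) {
    top <- rank_genes(R, p)$gene[seq_len(top_k)]
    union(known_by_ph[[p]], top)
  })
  support <- table(unlist(candidates, use.names = FALSE))
  keep <- names(support)[support >= threshold]
  known_class_genes <- unique(unlist(known_by_ph[class_phenotypes], use.names = FALSE))
  out <- tibble(gene = sort(keep),
                support = as.integer(support[sort(keep)]),
                known = sort(keep) %in% known_class_genes) %>%
    arrange(desc(.data$support), .data$gene)
  structure(out, class = c("birw_bimodule", class(out)),
            class_phenotypes = class_phenotypes,
            support_threshold = threshold)
}

#' @export
print.birw_bimodule <- function(x, ...) {
  cat(sprintf("<birw_bimodule> %d genes (%d known) over %d phenotypes, support >= %d\n",
              nrow(x), sum(x$known), length(attr(x, "class_phenotypes")),
              attr(x, "support_threshold")))
  NextMethod()
}
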