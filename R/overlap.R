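#' Panel coverage of gene phenotype annotations
#'
#' For each gene — and each requested gene combination — computes which
#' terms of a phenotype panel are covered by the union of the
#' combination's annotations (the Venn-style overlap used to rank
#' candidate causal genes against a set of enriched phenotypes).  By
#' default a panel term is covered only by an exact annotation; with
#' `closure = TRUE` an annotation to any descendant of a panel term also
#' covers it.
#'
#' @param annotations named list: gene symbol -> character vector of term
#'   ids.
#' @param panel non-empty character vector of term ids.
#' @param combinations optional list of character vectors of gene symbols;
#'   by default every single gene.
#' @param closure should descendant annotations cover a panel term?
#' @param ontology required when `closure = TRUE`.
#' @return a data frame with one row per combination: `genes`
#'   (`"+"`-joined), `n_genes`, `n_covered`, and `covered`
#'   (`";"`-joined term ids).
#' @export
overlap_phenotypes <- function(annotations, panel, combinations = NULL,
                               closure = FALSE, ontology = NULL) {
  stopifnot(is.list(annotations), !is.null(names(annotations)),
            length(panel) >= 1L)
  panel <- unique(as.character(panel))
  if (closure && is.null(ontology)) {
    stop("closure = TRUE requires an ontology")
  }
  if (is.null(combinations)) {
    combinations <- lapply(names(annotations), identity)
  }
  cover_one <- function(genes) {
    unknown <- setdiff(genes, names(annotations))
    if (length(unknown)) {
      stop("no annotations for gene(s): ", paste(unknown, collapse = ", "))
    }
    terms <- unique(unlist(annotations[genes], use.names = FALSE))
    if (closure) {
      # a descendant annotation covers its panel ancestors
      terms <- unique(unlist(lapply(terms, term_ancestors,
                                    ontology = ontology,
                                    include_self = TRUE),
                             use.names = FALSE))
    }
    intersect(panel, terms)
  }
  covered <- lapply(combinations, cover_one)
  data.frame(
    genes = vapply(combinations, paste, "", collapse = "+"),
    n_genes = lengths(combinations),
    n_covered = lengths(covered),
    covered = vapply(covered, paste, "", collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
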