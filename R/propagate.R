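# terms x terms logical incidence matrix of the ancestor-or-self relation,
# restricted to live terms; A[t, s] is TRUE when s subsumes t.
closure_matrix <- function(ontology) {
  live <- ontology$ids[!ontology$obsolete]
  A <- matrix(FALSE, length(live), length(live), dimnames = list(live, live))
  for (t in live) {
    A[t, c(t, ontology$anc[[t]])] <- TRUE
  }
  A
}

#' Induced (ancestor-closed) annotation set
#'
#' Applies the true-path rule: a patient observed with a term is implicitly
#' annotated with every ancestor of that term up to the ontology root.
#' For example, a patient observed with *Flexion contracture of the 2nd
#' finger* is implicitly annotated with *Flexion contracture of finger*
#' and *Abnormal 2nd finger morphology*, and so on to the root.  The union
#' over observed terms is deduplicated, so a term is present once no
#' matter how many observed descendants it subsumes.
#'
#' @param x a character vector of observed term ids (one patient), or a
#'   `"cohort"` object.
#' @param ontology an `"ontology"` object.
#' @return for a term vector, the closed character set; for a cohort, a
#'   named list of closed sets, one per patient.
#' @export
induce_annotations <- function(x, ontology) {
  stopifnot(inherits(ontology, "ontology"))
  close_one <- function(terms, who = NULL) {
    terms <- tryCatch(
      resolve_terms(ontology, terms),
      error = function(e) {
        if (is.null(who)) stop(e)
        stop("patient ", who, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    unique(c(terms, unlist(ontology$anc[terms], use.names = FALSE)))
  }
  if (inherits(x, "cohort")) {
    setNames(lapply(x$patient_id, function(pid) close_one(x$terms[[pid]], pid)),
             x$patient_id)
  } else {
    close_one(x)
  }
}

#' Per-term patient counts for one group
#'
#' Counts, for every term, the number of patients in the group annotated
#' with that term directly or through the ancestor closure.  Each patient
#' contributes at most once per term.  When the ontology declares a
#' phenotypic root, counting is restricted to that subtree (subtree root
#' included); ancestors above it are closed over but not reported, since
#' enrichment reports concern phenotypic abnormalities only.  Terms with a
#' zero count are omitted (sparse representation; downstream code treats
#' absent as zero).
#'
#' Monotonicity along every `is_a` edge (`count[parent] >= count[child]`)
#' is asserted on every run; a violation would indicate a closure bug.
#'
#' @param x a `"cohort"` (the group's patients).
#' @param ontology an `"ontology"` object.
#' @param group a label for the group.
#' @return an object of class `"term_counts"`: list with `group`, `size`,
#'   `counts` (named integer vector) and an ontology fingerprint.
#' @export
count_terms <- function(x, ontology, group = "group") {
  stopifnot(inherits(x, "cohort"), inherits(ontology, "ontology"))
  if (length(x) == 0L) stop("group is empty")
  induced <- induce_annotations(x, ontology)
  universe <- phenotypic_subtree(ontology)
  tab <- table(factor(unlist(induced, use.names = FALSE), levels = universe))
  counts <- as.integer(tab)
  names(counts) <- universe
  counts <- counts[counts > 0L]

  # per-edge monotonicity assertion
  cnt <- function(t) if (t %in% names(counts)) counts[[t]] else 0L
  for (child in names(counts)) {
    for (p in ontology$parents[[child]]) {
      if (p %in% universe && cnt(p) < counts[[child]]) {
        stop("count monotonicity violated on edge ", child, " -> ", p)
      }
    }
  }

  structure(list(group = group, size = length(x), counts = counts,
                 ontology = ontology_fingerprint(ontology)),
            class = "term_counts")
}

#' @export
print.term_counts <- function(x, ...) {
  cat("Term counts for group '", x$group, "': ", x$size, " patients, ",
      length(x$counts), " annotated terms\n", sep = "")
  top <- sort(x$counts, decreasing = TRUE)
  top <- utils::head(top, 5L)
  for (t in names(top)) {
    cat("  ", t, ": ", top[[t]], "\n", sep = "")
  }
  invisible(x)
}

#' Construct a term_counts object from a bare count table
#'
#' Used for packaged fixtures that encode published per-term counts
#' directly (the per-patient records behind them are not deposited).
#'
#' @param counts named integer vector (term id -> patient count).
#' @param size group size (denominator).
#' @param group group label.
#' @param ontology the ontology the counts are defined over.
#' @return a `"term_counts"` object.
#' @export
term_counts <- function(counts, size, group, ontology) {
  stopifnot(inherits(ontology, "ontology"), size >= 1L,
            all(counts >= 0L), all(counts <= size))
  counts <- counts[counts > 0L]
  resolved <- resolve_terms(ontology, names(counts))
  names(counts) <- resolved
  structure(list(group = group, size = as.integer(size),
                 counts = setNames(as.integer(counts), names(counts)),
                 ontology = ontology_fingerprint(ontology)),
            class = "term_counts")
}
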