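#' Simulate cohorts from a fitted comparison
#'
#' Parametric-bootstrap style: draws synthetic cohorts of the fitted group
#' sizes in which each observed term is included independently with its
#' group's fitted observed-annotation frequency (interior terms are drawn
#' at their observed positions; closure happens downstream as usual).
#' Useful for checking how stable the significant-term set is under the
#' fitted annotation rates.
#'
#' @param object a `"pheno_comparison"` produced by
#'   [phenotype_comparison()] (lower-level [compare_groups()] fits carry
#'   no cohort frequencies and cannot be simulated from).
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` `"cohort"` objects.
#' @export
simulate.pheno_comparison <- function(object, nsim = 1, seed = 1L, ...) {
  if (is.null(object$observed_freqs)) {
    stop("this fit carries no per-group annotation frequencies; ",
         "refit with phenotype_comparison()")
  }
  all_terms <- sort(unique(c(names(object$observed_freqs[[1L]]),
                             names(object$observed_freqs[[2L]]))))
  freq_of <- function(g) {
    f <- object$observed_freqs[[g]]
    setNames(ifelse(all_terms %in% names(f), f[all_terms], 0), all_terms)
  }
  p <- cbind(freq_of(1L), freq_of(2L))
  lapply(seq_len(nsim), function(i) {
    spec <- synthetic_cohort_spec(
      object$ontology,
      leaf_freqs = setNames(lapply(seq_len(nrow(p)), function(j) p[j, ]),
                            all_terms),
      group_sizes = object$sizes,
      genes_per_group = setNames(object$genes, object$groups),
      seed = seed + i - 1L,
      leaves_only = FALSE
    )
    generate_cohort(spec)
  })
}
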