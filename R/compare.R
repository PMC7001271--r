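#' Expected cell counts of a 2x2 contingency table
#'
#' Standard expected values from the marginals:
#' `expected[i, j] = row_total[i] * col_total[j] / n`.  These drive the
#' insufficient-data filter: a term whose table has any expected cell
#' below 5 is omitted from testing.
#'
#' @param tab a 2x2 matrix, or an integer vector `c(a, b, c, d)` laid out
#'   as rows = groups, columns = with/without phenotype.
#' @return a 2x2 numeric matrix of expected counts.
#' @examples
#' expected_counts(c(0, 93, 13, 46))   # min expected 5.05: kept
#' expected_counts(c(1, 92, 1, 58))    # min expected 0.78: filtered
#' @export
expected_counts <- function(tab) {
  tab <- as_table2x2(tab)
  n <- sum(tab)
  if (n == 0) stop("empty table (n = 0)")
  outer(rowSums(tab), colSums(tab)) / n
}

as_table2x2 <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2L, 2L)))
  } else {
    stopifnot(length(tab) == 4L)
    tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers")
  }
  tab
}

#' Pearson chi-squared test on a 2x2 table
#'
#' The one-degree-of-freedom Pearson statistic in its closed form,
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with no continuity
#' correction, and its upper-tail p-value from the chi-squared(1)
#' distribution (equivalently `erfc(sqrt(stat / 2))`).  The test is
#' two-sided by construction.  A zero observed cell is legal as long as
#' the marginals are positive; a zero marginal makes the table degenerate.
#'
#' @param tab a 2x2 matrix or `c(a, b, c, d)` vector (see
#'   [expected_counts()]).
#' @return list with elements `statistic` and `p.value`.
#' @examples
#' pearson_chi2(c(31, 62, 4, 55))   # statistic ~14.36
#' @export
pearson_chi2 <- function(tab) {
  tab <- as_table2x2(tab)
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c <- tab[2L, 1L]; d <- tab[2L, 2L]
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("degenerate table: zero marginal total")
  stat <- n * (a * d - b * c)^2 / prod(marg)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' Multiplies a raw p-value by the number of tests performed, capping at
#' 1, to control the family-wise error rate.
#'
#' @param p_raw raw p-value(s) in `[0, 1]`.
#' @param m number of tests (positive integer).
#' @return corrected p-value(s).
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(all(p_raw >= 0), all(p_raw <= 1), length(m) == 1L, m >= 1L)
  pmin(1, p_raw * m)
}

#' Compare per-term counts between two groups
#'
#' The core comparison: every term annotated in either group (absent
#' count = 0) gets a 2x2 contingency table of patients with/without the
#' term per group.  Terms with any expected cell count below 5 are omitted
#' from testing (strictly below: an expected value of exactly 5 is
#' tested).  Tested terms get the Pearson chi-squared statistic (1 df, no
#' continuity correction), the raw p-value, and a Bonferroni-corrected
#' p-value over the `m` tests actually performed.  Significance is
#' declared at `p_corrected <= alpha`.
#'
#' @param counts1,counts2 `"term_counts"` objects built over the same
#'   ontology.
#' @param ontology the `"ontology"` both count sets were built over.
#' @param alpha family-wise significance level (default 0.05).
#' @param m optional override of the Bonferroni denominator; by default
#'   the number of terms that pass the expected-count filter.  Supplying
#'   `m` supports replaying published analyses whose full tested-term
#'   universe is larger than a packaged fixture.
#' @return a `"pheno_comparison"` object; see [phenotype_comparison()].
#' @export
compare_groups <- function(counts1, counts2, ontology, alpha = 0.05,
                           m = NULL) {
  stopifnot(inherits(counts1, "term_counts"), inherits(counts2, "term_counts"),
            inherits(ontology, "ontology"),
            is.numeric(alpha), alpha > 0, alpha < 1)
  fp <- ontology_fingerprint(ontology)
  if (!identical(counts1$ontology, fp) || !identical(counts2$ontology, fp)) {
    stop("count objects were built over a different ontology")
  }
  universe <- phenotypic_subtree(ontology)
  cand <- sort(intersect(
    union(names(counts1$counts), names(counts2$counts)), universe))
  n1 <- counts1$size; n2 <- counts2$size
  cnt <- function(t, tc) if (t %in% names(tc$counts)) tc$counts[[t]] else 0L

  a <- vapply(cand, cnt, 0L, tc = counts1)
  c_ <- vapply(cand, cnt, 0L, tc = counts2)
  b <- n1 - a; d <- n2 - c_

  min_exp <- mapply(function(a, b, c, d) {
    min(expected_counts(c(a, b, c, d)))
  }, a, b, c_, d)
  min_exp <- as.numeric(min_exp)
  tested <- min_exp >= 5                     # "below 5" is strict

  m_used <- if (is.null(m)) sum(tested) else as.integer(m)
  if (m_used < 1L && any(tested)) stop("m must be >= 1")

  chi2 <- p_raw <- p_corr <- rep(NA_real_, length(cand))
  for (i in which(tested)) {
    ct <- pearson_chi2(c(a[i], b[i], c_[i], d[i]))
    chi2[i] <- ct$statistic
    p_raw[i] <- ct$p.value
    p_corr[i] <- bonferroni(ct$p.value, m_used)
  }
  significant <- tested & !is.na(p_corr) & p_corr <= alpha

  res <- data.frame(
    term_id = cand,
    term_label = unname(ontology$labels[cand]),
    count1 = unname(a), total1 = n1, pct1 = unname(100 * a / n1),
    count2 = unname(c_), total2 = n2, pct2 = unname(100 * c_ / n2),
    min_expected = unname(min_exp),
    chi2 = unname(chi2), p_raw = unname(p_raw), p_corrected = unname(p_corr),
    tested = unname(tested), significant = unname(significant),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ord <- order(!res$tested, res$p_corrected, res$term_id,
               method = "radix", na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL

  structure(list(
    results = res,
    groups = c(counts1$group, counts2$group),
    sizes = c(n1, n2),
    alpha = alpha,
    m = m_used,
    m_overridden = !is.null(m),
    n_candidates = length(cand)
  ), class = "pheno_comparison")
}

#' Term-wise phenotype comparison of two gene-defined patient groups
#'
#' The package's central fitting function.  Patients are split into the
#' partition's two groups by mutated gene, each patient's observed HPO
#' terms are closed under the ancestor relation (true-path rule), per-term
#' patient counts are tabulated per group, and every annotated term is
#' tested with a Pearson chi-squared test on its 2x2 table — omitting
#' terms with any expected cell count below 5 and Bonferroni-correcting
#' over the tests actually performed.
#'
#' @param x a `"cohort"` of curated case reports.
#' @param ontology an `"ontology"`.
#' @param partition a `"stage_partition"` mapping genes to the two groups.
#' @param alpha family-wise significance level (default 0.05).
#' @param m optional Bonferroni-denominator override (see
#'   [compare_groups()]).
#' @return an object of class `"pheno_comparison"` with components
#'   `results` (one row per candidate term: counts, percentages, minimum
#'   expected cell count, chi-squared statistic, raw and corrected p,
#'   `tested` and `significant` flags, sorted by corrected p), `groups`,
#'   `sizes`, `alpha`, `m`, and `n_unassigned`.
#' @examples
#' ont <- toy_ontology()
#' fit <- phenotype_comparison(gpi_fixture_cohort(ont), ont,
#'                             gpi_partition(), m = 211)
#' fit
#' @export
phenotype_comparison <- function(x, ontology, partition, alpha = 0.05,
                                 m = NULL) {
  stopifnot(inherits(x, "cohort"))
  x <- validate_cohort(x, ontology)
  asg <- assign_groups(x, partition)
  g <- asg$groups
  if (any(lengths(lapply(g, function(ci) ci$patient_id)) == 0L)) {
    stop("one of the partition groups is empty")
  }
  counts <- lapply(names(g), function(l) count_terms(g[[l]], ontology, l))
  fit <- compare_groups(counts[[1L]], counts[[2L]], ontology,
                        alpha = alpha, m = m)
  fit$partition <- partition$name
  fit$n_unassigned <- length(asg$unassigned)
  # per-group observed-term frequencies, kept so simulate() can draw
  # parametric-bootstrap cohorts from the fitted annotation rates
  fit$observed_freqs <- lapply(g, function(ci) {
    tab <- table(unlist(ci$terms, use.names = FALSE))
    setNames(as.numeric(tab) / length(ci), names(tab))
  })
  fit$genes <- lapply(g, function(ci) unique(ci$gene))
  fit$ontology <- ontology
  fit
}

#' @export
print.pheno_comparison <- function(x, ...) {
  cat("Term-wise phenotype comparison",
      if (!is.null(x$partition)) paste0(" (partition '", x$partition, "')"),
      "\n", sep = "")
  cat("  groups: ", x$groups[1L], " (n=", x$sizes[1L], ") vs ",
      x$groups[2L], " (n=", x$sizes[2L], ")\n", sep = "")
  cat("  candidate terms: ", x$n_candidates,
      "; tested (all expected counts >= 5): ", sum(x$results$tested),
      "; Bonferroni m = ", x$m,
      if (isTRUE(x$m_overridden)) " (overridden)", "\n", sep = "")
  cat("  significant at alpha <= ", x$alpha, ": ",
      sum(x$results$significant), " terms\n", sep = "")
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig)) {
    show <- utils::head(sig, 8L)
    cat("  top terms:\n")
    for (i in seq_len(nrow(show))) {
      cat(sprintf("    %s  %-34s %d/%d vs %d/%d  p_corr=%.5f\n",
                  show$term_id[i], substr(show$term_label[i], 1, 34),
                  show$count1[i], show$total1[i],
                  show$count2[i], show$total2[i], show$p_corrected[i]))
    }
    if (nrow(sig) > nrow(show)) {
      cat("    ... and ", nrow(sig) - nrow(show), " more\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
summary.pheno_comparison <- function(object, ...) {
  res <- object$results
  sig <- res[res$significant, , drop = FALSE]
  enriched_in <- ifelse(sig$pct1 > sig$pct2,
                        object$groups[1L], object$groups[2L])
  out <- list(
    groups = object$groups, sizes = object$sizes,
    alpha = object$alpha, m = object$m,
    n_candidates = object$n_candidates,
    n_tested = sum(res$tested),
    n_significant = nrow(sig),
    by_direction = table(factor(enriched_in, levels = object$groups)),
    significant = cbind(sig, enriched_in = enriched_in)
  )
  class(out) <- "summary.pheno_comparison"
  out
}

#' @export
print.summary.pheno_comparison <- function(x, ...) {
  cat("Phenotype comparison: ", x$groups[1L], " (n=", x$sizes[1L], ") vs ",
      x$groups[2L], " (n=", x$sizes[2L], ")\n", sep = "")
  cat("  ", x$n_tested, " of ", x$n_candidates,
      " candidate terms tested; Bonferroni m = ", x$m, "\n", sep = "")
  cat("  significant terms (alpha <= ", x$alpha, "): ",
      x$n_significant, "\n", sep = "")
  for (l in names(x$by_direction)) {
    cat("    enriched in ", l, ": ", x$by_direction[[l]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.pheno_comparison <- function(x, ...) x$results

#' Write a comparison report as TSV
#'
#' Deterministically ordered (corrected p ascending, then term id) with
#' corrected p-values printed to 5 decimal places, matching the precision
#' of published per-term tables.
#'
#' @param x a `"pheno_comparison"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(x, path) {
  stopifnot(inherits(x, "pheno_comparison"))
  res <- x$results
  out <- data.frame(
    term_id = res$term_id, term_label = res$term_label,
    count1 = res$count1, total1 = res$total1,
    pct1 = sprintf("%.2f", res$pct1),
    count2 = res$count2, total2 = res$total2,
    pct2 = sprintf("%.2f", res$pct2),
    chi2 = ifelse(is.na(res$chi2), "NA", sprintf("%.4f", res$chi2)),
    p_raw = ifelse(is.na(res$p_raw), "NA", sprintf("%.3e", res$p_raw)),
    p_corrected = ifelse(is.na(res$p_corrected), "NA",
                         sprintf("%.5f", res$p_corrected)),
    tested = res$tested, significant = res$significant,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
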