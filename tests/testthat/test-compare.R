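test_that("expected counts come from the marginals", {
  expect_equal(expected_counts(c(25, 25, 25, 25)),
               matrix(25, 2, 2, dimnames = NULL), ignore_attr = TRUE)
  # a zero observed cell can still pass the filter (expected 5.05 > 5) ...
  expect_equal(min(expected_counts(c(0, 93, 13, 46))), 59 * 13 / 152)
  expect_gte(min(expected_counts(c(0, 93, 13, 46))), 5)
  # ... while a sparse phenotype column fails it
  expect_equal(min(expected_counts(c(1, 92, 1, 58))), 2 * 59 / 152)
  expect_lt(min(expected_counts(c(1, 92, 1, 58))), 5)
  expect_error(expected_counts(c(0, 0, 0, 0)), "n = 0")
})

test_that("Pearson chi-squared matches its closed form and erfc tail", {
  flat <- pearson_chi2(c(10, 10, 10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  digit <- pearson_chi2(c(31, 62, 4, 55))
  expect_equal(digit$statistic, 14.3605, tolerance = 1e-4)
  expect_equal(digit$p.value, 1.509e-4, tolerance = 1e-3)

  tendon <- pearson_chi2(c(19, 74, 0, 59))  # zero cell is legal
  expect_equal(tendon$statistic, 13.776, tolerance = 1e-4)

  expect_error(pearson_chi2(c(0, 0, 5, 5)), "degenerate table")

  # erfc(sqrt(stat/2)) is the same upper tail
  for (tab in list(c(31, 62, 4, 55), c(5, 20, 9, 8), c(40, 53, 12, 47))) {
    ct <- pearson_chi2(tab)
    expect_equal(ct$p.value, pracma::erfc(sqrt(ct$statistic / 2)),
                 tolerance = 1e-12)
  }
})

test_that("chi-squared p-values agree with stats::chisq.test to 1e-12", {
  set.seed(99)
  for (i in 1:200) {
    repeat {  # draw tables with no zero marginal
      tab <- matrix(rpois(4, lambda = sample(3:40, 1)) + 1L, 2, 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    mine <- pearson_chi2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("chi-squared is invariant to swapping groups or columns", {
  tab <- c(17, 42, 25, 9)
  s0 <- pearson_chi2(tab)$statistic
  expect_equal(pearson_chi2(c(25, 9, 17, 42))$statistic, s0)   # swap groups
  expect_equal(pearson_chi2(c(42, 17, 9, 25))$statistic, s0)   # swap columns
})

test_that("bonferroni caps at one and reproduces a published corrected p", {
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0, 17), 0)
  expect_gte(bonferroni(1e-6, 5), 1e-6)   # never below p_raw
  p_digit <- pearson_chi2(c(31, 62, 4, 55))$p.value
  expect_equal(bonferroni(p_digit, 211), 0.03185, tolerance = 5e-4)
})

test_that("p_raw decreases in the statistic; bonferroni is monotone", {
  stats_seq <- c(0.5, 1, 4, 9, 16)
  p <- pchisq(stats_seq, 1, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  expect_true(all(diff(bonferroni(p, 7)) <= 0))
  expect_true(all(bonferroni(p, 7) >= p))
})

test_that("the expected-count filter is strict below 5 (exactly 5 is tested)", {
  ont <- chain_ontology()
  # marginals 10/10 and 10/10 give expected exactly 5 in every cell
  tc1 <- term_counts(c("X:0000001" = 3L), 10L, "g1", ont)
  tc2 <- term_counts(c("X:0000001" = 7L), 10L, "g2", ont)
  fit <- compare_groups(tc1, tc2, ont)
  row <- fit$results[fit$results$term_id == "X:0000001", ]
  expect_equal(row$min_expected, 5)
  expect_true(row$tested)
  expect_identical(fit$m, 1L)
})

test_that("self-comparison finds nothing significant", {
  ont <- toy_ontology()
  tc <- gpi_fixture_counts(ont)[[1]]
  fit <- compare_groups(tc, tc, ont)
  tested <- fit$results[fit$results$tested, ]
  expect_true(all(tested$chi2 == 0))
  expect_true(all(tested$p_corrected == 1))
  expect_false(any(fit$results$significant))
})

test_that("compare_groups rejects counts built over another ontology", {
  ont <- toy_ontology()
  other <- chain_ontology()
  tc1 <- gpi_fixture_counts(ont)[[1]]
  tc2 <- term_counts(c("X:0000001" = 2L), 10L, "g2", other)
  expect_error(compare_groups(tc1, tc2, ont), "different ontology")
})

test_that("results are ordered deterministically and flags are coherent", {
  ont <- toy_ontology()
  fx <- gpi_fixture_counts(ont)
  fit <- compare_groups(fx[[1]], fx[[2]], ont, m = 211)
  res <- fit$results
  expect_identical(res$tested, !is.na(res$p_corrected))
  expect_true(all(res$significant[res$significant] & res$tested[res$significant]))
  tested_p <- res$p_corrected[res$tested]
  expect_true(all(diff(tested_p) >= 0))
  expect_true(all(res$p_corrected >= res$p_raw, na.rm = TRUE))
  # re-running gives byte-identical results
  fit2 <- compare_groups(fx[[1]], fx[[2]], ont, m = 211)
  expect_identical(fit$results, fit2$results)
})

test_that("printed corrected p-values back-calculate to one common m", {
  tt <- gpi_term_counts()
  # rows printed to >= 3 significant figures ("0.00000" means below print
  # precision; 0.00047 carries only 2 significant figures)
  tt <- tt[tt$p_corrected >= 0.001, ]
  p_raw <- vapply(seq_len(nrow(tt)), function(i) {
    pearson_chi2(c(tt$count_synthesis[i], 93 - tt$count_synthesis[i],
                   tt$count_tr[i], 59 - tt$count_tr[i]))$p.value
  }, 0)
  ratio <- tt$p_corrected / p_raw
  m_consensus <- median(ratio)
  expect_equal(m_consensus, 211, tolerance = 0.01)
  expect_true(all(abs(ratio - m_consensus) <= 2))
})

test_that("fit object methods expose the comparison", {
  ont <- toy_ontology()
  fit <- phenotype_comparison(gpi_fixture_cohort(ont), ont, gpi_partition(),
                              m = 211)
  expect_s3_class(fit, "pheno_comparison")
  expect_output(print(fit), "Synthesis \\(n=93\\)")
  s <- summary(fit)
  expect_identical(unname(s$by_direction["Synthesis"]), 5L)
  expect_identical(unname(s$by_direction["Transamidase+Remodeling"]), 16L)
  expect_identical(as.data.frame(fit), fit$results)

  sims <- simulate(fit, nsim = 2, seed = 3L)
  expect_length(sims, 2L)
  expect_identical(length(sims[[1]]), 152L)
  expect_false(identical(sims[[1]]$terms, sims[[2]]$terms))
})
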