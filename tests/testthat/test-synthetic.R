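test_that("generate_ontology builds seeded rooted DAGs", {
  tiny <- generate_ontology(2, 1, seed = 4)
  expect_identical(tiny$root, "T:0000001")
  expect_identical(tiny$parents[["T:0000002"]], "T:0000001")

  a <- generate_ontology(100, 3, seed = 7)
  b <- generate_ontology(100, 3, seed = 7)
  expect_identical(a$parents, b$parents)          # same seed, same edges
  c <- generate_ontology(100, 3, seed = 8)
  expect_false(identical(a$parents, c$parents))   # new seed, new edges

  big <- generate_ontology(500, 3, seed = 7)      # invariants hold at size
  expect_length(big$ids, 500L)
  expect_true(all(lengths(big$parents[setdiff(big$ids, big$root)]) >= 1))
  expect_true(all(vapply(setdiff(big$ids, big$root), function(t) {
    big$root %in% big$anc[[t]]
  }, TRUE)))
})

test_that("generate_cohort is seed-deterministic with default sizes 93/59", {
  ont <- toy_ontology()
  leaves <- ontology_leaves(ont)
  freqs <- setNames(lapply(leaves, function(l) c(0.2, 0.2)), leaves)
  spec <- synthetic_cohort_spec(ont, freqs, seed = 10)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$terms, c2$terms)
  expect_identical(length(c1), 152L)
  grp <- attr(c1, "group")
  expect_identical(sum(grp == names(spec$genes_per_group)[1]), 93L)
  expect_identical(sum(grp == names(spec$genes_per_group)[2]), 59L)
  c3 <- generate_cohort(synthetic_cohort_spec(ont, freqs, seed = 11))
  expect_false(identical(c1$terms, c3$terms))     # only the seed changed
})

test_that("spec validation rejects bad probabilities and non-leaf keys", {
  ont <- toy_ontology()
  expect_error(
    synthetic_cohort_spec(ont, list("HP:0000939" = c(1.5, 0))),
    "probabilities must lie in")
  expect_error(
    synthetic_cohort_spec(ont, list("HP:0000400" = c(0.1, 0.1))),
    "must be ontology leaves")
})

test_that("a fully separating leaf separates the groups perfectly", {
  ont <- toy_ontology()
  spec <- synthetic_cohort_spec(ont, list("HP:0000939" = c(1, 0)),
                                group_sizes = c(20L, 20L), seed = 2)
  coh <- generate_cohort(spec)
  grp <- attr(coh, "group")
  has <- vapply(coh$patient_id,
                function(p) "HP:0000939" %in% coh$terms[[p]], TRUE)
  expect_true(all(has[grp == names(spec$genes_per_group)[1]]))
  expect_false(any(has[grp == names(spec$genes_per_group)[2]]))
  # empty draws fall back to the phenotypic root, never an empty record
  expect_true(all(lengths(coh$terms) >= 1L))
  expect_true(all(vapply(coh$terms[grp == names(spec$genes_per_group)[2]],
                         identical, TRUE, y = "HP:0000118")))
})

test_that("specificity noise moves annotations to proper ancestors", {
  ont <- toy_ontology()
  spec <- synthetic_cohort_spec(ont, list("HP:0000938" = c(1, 1)),
                                group_sizes = c(60L, 60L),
                                specificity_noise = 0.5, seed = 6)
  coh <- generate_cohort(spec)
  anc <- term_ancestors(ont, "HP:0000938")
  obs <- unlist(coh$terms, use.names = FALSE)
  expect_true(all(obs %in% c("HP:0000938", anc)))
  swapped <- mean(obs != "HP:0000938")
  expect_gt(swapped, 0.35)   # binomial(120, 0.5) well inside
  expect_lt(swapped, 0.65)
})

test_that("empirical leaf frequencies converge to the specification", {
  ont <- toy_ontology()
  freqs <- list("HP:0000938" = c(0.30, 0.10), "HP:0000939" = c(0.05, 0.60))
  n <- 5000L
  spec <- synthetic_cohort_spec(ont, freqs, group_sizes = c(n, n), seed = 13)
  coh <- generate_cohort(spec)
  grp <- attr(coh, "group")
  for (t in names(freqs)) {
    for (g in 1:2) {
      ids <- coh$patient_id[grp == names(spec$genes_per_group)[g]]
      phat <- mean(vapply(ids, function(p) t %in% coh$terms[[p]], TRUE))
      p0 <- freqs[[t]][g]
      se <- sqrt(p0 * (1 - p0) / n)
      expect_lt(abs(phat - p0), 3 * se + 1e-9)
    }
  }
})

test_that("realize_counts nests descendants minimally within ancestors", {
  ont <- chain_ontology()   # A is_a B is_a C(root)
  tc1 <- term_counts(c("X:0000002" = 2L, "X:0000001" = 1L), 2L, "g1", ont)
  tc2 <- term_counts(c("X:0000002" = 1L), 2L, "g2", ont)
  coh <- realize_counts(tc1, tc2, ont)
  expect_identical(coh$terms[["g1_001"]], "X:0000001")  # child only: minimal
  expect_identical(coh$terms[["g1_002"]], "X:0000002")
  # patients beyond the largest count get the root so sizes are preserved
  expect_identical(coh$terms[["g2_002"]], "X:0000003")
  expect_length(coh, 4L)
})

test_that("realize_counts rejects infeasible fixtures naming the edge", {
  ont <- chain_ontology()
  tc1 <- term_counts(c("X:0000001" = 2L, "X:0000002" = 1L), 3L, "g1", ont)
  tc2 <- term_counts(c("X:0000002" = 1L), 3L, "g2", ont)
  expect_error(realize_counts(tc1, tc2, ont),
               "infeasible.*X:0000001 -> X:0000002")
})

test_that("realize then count round-trips random feasible fixtures", {
  set.seed(33)
  ont <- generate_ontology(25, 2, seed = 9)
  for (rep in 1:100) {
    # a random cohort's counted table is feasible by construction
    sets <- replicate(sample(4:12, 1),
                      sample(ont$ids, sample(1:3, 1)), simplify = FALSE)
    src <- make_cohort(sets)
    want1 <- count_terms(src, ont, "g1")
    sets2 <- replicate(sample(4:12, 1),
                       sample(ont$ids, sample(1:3, 1)), simplify = FALSE)
    want2 <- count_terms(make_cohort(sets2), ont, "g2")
    coh <- realize_counts(want1, want2, ont)
    asg <- assign_groups(coh, stage_partition(
      "rt", c(GENE_g1 = "g1", GENE_g2 = "g2")))
    got1 <- count_terms(asg$groups$g1, ont, "g1")
    got2 <- count_terms(asg$groups$g2, ont, "g2")
    expect_identical(got1$counts[sort(names(got1$counts))],
                     want1$counts[sort(names(want1$counts))])
    expect_identical(got2$counts[sort(names(got2$counts))],
                     want2$counts[sort(names(want2$counts))])
  }
})

test_that("a Table-3-like effect is detected in most replicates", {
  # leaf frequencies 0.33 vs 0.07 at group sizes 93/59 (the digit-row
  # effect), background leaves at 0.10 in both groups, Bonferroni
  # denominator forced to 200; frozen point estimate from this seed set
  ont <- toy_ontology()
  leaves <- ontology_leaves(ont)
  focal <- "HP:9000008"
  p <- setNames(lapply(leaves, function(l) {
    if (l == focal) c(0.33, 0.07) else c(0.1, 0.1)
  }), leaves)
  hits <- 0L
  for (r in 1:200) {
    spec <- synthetic_cohort_spec(ont, p, seed = 1000L + r)
    coh <- generate_cohort(spec)
    fit <- suppressWarnings(
      phenotype_comparison(coh, ont, spec_partition(spec), m = 200))
    row <- fit$results[fit$results$term_id == focal, ]
    if (nrow(row) == 1L && isTRUE(row$significant)) hits <- hits + 1L
  }
  expect_identical(hits, 111L)   # regression value for seeds 1001..1200
  expect_gt(hits, 100L)          # majority of replicates
})
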