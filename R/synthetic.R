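#' Generate a random rooted ontology DAG
#'
#' Builds a seeded random ontology with the structural features the
#' analysis relies on: a single root and multi-parent terms.  Term `i`
#' (in creation order) draws between 1 and `max_parents` parents uniformly
#' among the earlier terms, which guarantees acyclicity by construction.
#'
#' @param n_terms number of terms (>= 2).
#' @param max_parents maximum number of parents per non-root term.
#' @param seed integer seed; the same seed reproduces the same DAG.
#' @param prefix id prefix (default `"T"`, giving ids `T:0000001` ...).
#' @return an `"ontology"` object (no phenotypic root is set, so every
#'   term is in the reporting universe).
#' @export
generate_ontology <- function(n_terms, max_parents = 2L, seed = 1L,
                              prefix = "T") {
  stopifnot(n_terms >= 2L, max_parents >= 1L)
  ids <- sprintf("%s:%07d", prefix, seq_len(n_terms))
  parents <- with_seed(seed, {
    lapply(seq_len(n_terms), function(i) {
      if (i == 1L) return(character())
      k <- sample.int(min(max_parents, i - 1L), 1L)
      ids[sample.int(i - 1L, k)]
    })
  })
  build_ontology(ids, labels = ids, parents = setNames(parents, ids))
}

#' Specification of a synthetic cohort
#'
#' Describes a two-group cohort with the statistical structure the
#' comparison pipeline assumes: two gene-defined groups (default sizes 93
#' and 59, the cohort sizes of the motivating study), group-specific
#' annotation probabilities at ontology leaves, and a curation-depth noise
#' parameter: with probability `specificity_noise` an included leaf is
#' reported as a uniformly chosen proper ancestor instead, emulating
#' curators recording a less specific term than the patient's actual
#' phenotype.  Leaf inclusion is independent across terms; phenotype
#' correlation structure is deliberately not modelled.
#'
#' @param ontology an `"ontology"` object.
#' @param leaf_freqs named list (or 2-column matrix with term-id rownames)
#'   mapping leaf term ids to the pair of per-group inclusion
#'   probabilities.
#' @param group_sizes two positive integers (default `c(93, 59)`).
#' @param specificity_noise probability in `[0, 1]` (default 0).
#' @param genes_per_group named list of length 2: group label -> character
#'   vector of gene symbols assigned uniformly within the group.  Defaults
#'   to three placeholder genes per group (`GA1..GA3`, `GB1..GB3`).
#' @param seed integer seed.
#' @param leaves_only enforce that `leaf_freqs` keys are ontology leaves
#'   (the default; internals may switch it off for parametric-bootstrap
#'   draws at interior terms).
#' @return an object of class `"synthetic_cohort_spec"`.
#' @export
synthetic_cohort_spec <- function(ontology, leaf_freqs,
                                  group_sizes = c(93L, 59L),
                                  specificity_noise = 0,
                                  genes_per_group = NULL,
                                  seed = 1L, leaves_only = TRUE) {
  stopifnot(inherits(ontology, "ontology"),
            length(group_sizes) == 2L, all(group_sizes >= 1L),
            length(specificity_noise) == 1L,
            specificity_noise >= 0, specificity_noise <= 1)
  if (is.matrix(leaf_freqs)) {
    leaf_freqs <- setNames(
      lapply(seq_len(nrow(leaf_freqs)), function(i) leaf_freqs[i, ]),
      rownames(leaf_freqs))
  }
  stopifnot(is.list(leaf_freqs), !is.null(names(leaf_freqs)))
  p <- do.call(rbind, lapply(leaf_freqs, as.numeric))
  if (ncol(p) != 2L) stop("leaf_freqs entries must be probability pairs")
  if (any(p < 0) || any(p > 1)) {
    stop("annotation probabilities must lie in [0, 1]")
  }
  keys <- resolve_terms(ontology, names(leaf_freqs))
  if (leaves_only) {
    non_leaf <- setdiff(keys, ontology_leaves(ontology))
    if (length(non_leaf)) {
      stop("leaf_freqs keys must be ontology leaves: ",
           paste(non_leaf, collapse = ", "))
    }
  }
  if (is.null(genes_per_group)) {
    genes_per_group <- list(groupA = paste0("GA", 1:3),
                            groupB = paste0("GB", 1:3))
  }
  stopifnot(length(genes_per_group) == 2L, !is.null(names(genes_per_group)))
  structure(list(
    ontology = ontology,
    leaf_freqs = setNames(lapply(seq_along(keys), function(i) p[i, ]), keys),
    group_sizes = as.integer(group_sizes),
    specificity_noise = specificity_noise,
    genes_per_group = genes_per_group,
    seed = as.integer(seed)
  ), class = "synthetic_cohort_spec")
}

#' Partition matching a synthetic cohort specification
#'
#' @param spec a `"synthetic_cohort_spec"`.
#' @return a `"stage_partition"` placing each group's genes under its
#'   group label.
#' @export
spec_partition <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  g <- spec$genes_per_group
  stage_partition(
    "synthetic",
    setNames(rep(names(g), lengths(g)), unlist(g, use.names = FALSE))
  )
}

#' Generate a seeded synthetic cohort
#'
#' For every patient, each leaf term is included independently with its
#' group's probability; with probability `specificity_noise` an included
#' leaf is replaced by a uniformly chosen proper ancestor (curation-depth
#' noise).  Patients whose draw is empty receive the phenotypic root (or
#' the ontology root when no phenotypic root is set), so every case report
#' is non-empty.  Genes are drawn uniformly from the group's gene list.
#' Output is fully deterministic given `spec$seed`; the seed and generator
#' name are recorded as attributes.
#'
#' @param spec a `"synthetic_cohort_spec"`.
#' @return a `"cohort"` with attributes `group` (the generating group
#'   label per patient), `seed` and `rng`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  ont <- spec$ontology
  leaves <- names(spec$leaf_freqs)
  pmat <- do.call(rbind, spec$leaf_freqs)      # leaves x 2
  fallback <- ont$phenotypic_root %||% ont$root
  q <- spec$specificity_noise
  labels <- names(spec$genes_per_group)

  with_seed(spec$seed, {
    pid <- character(); pub <- character(); gene <- character()
    terms <- list(); grp <- character()
    k <- 0L
    for (g in 1:2) {
      for (i in seq_len(spec$group_sizes[g])) {
        k <- k + 1L
        incl <- leaves[runif(length(leaves)) < pmat[, g]]
        if (q > 0 && length(incl)) {
          swap <- runif(length(incl)) < q
          incl[swap] <- vapply(incl[swap], function(t) {
            anc <- ont$anc[[t]]
            if (length(anc)) sample_one(anc) else t
          }, "")
        }
        obs <- unique(incl)
        if (!length(obs)) obs <- fallback
        pid <- c(pid, sprintf("P%04d", k))
        pub <- c(pub, "synthetic")
        gene <- c(gene, sample_one(spec$genes_per_group[[g]]))
        terms[[k]] <- obs
        grp <- c(grp, labels[g])
      }
    }
    out <- cohort(pid, pub, gene, terms)
    attr(out, "group") <- setNames(grp, pid)
    attr(out, "seed") <- spec$seed
    attr(out, "rng") <- rng_description()
    out
  })
}

#' Construct a cohort that realises a published count table
#'
#' Given per-term patient counts for two groups (e.g. transcribed from a
#' published enrichment table), builds a cohort whose propagated counts
#' ([count_terms()]) reproduce the fixture exactly.  The construction
#' nests descendants within ancestors: patients are indexed 1..N and
#' patient `i` is annotated at term `t` when `i <= count[t]`, observing
#' `t` only where no counted descendant already implies it (so observed
#' sets are minimal).  Feasibility requires monotonicity: every counted
#' term's parents (within the reporting subtree, the subtree root aside)
#' must be counted at least as high; violations raise an error naming the
#' offending edge.  Patients beyond the largest count receive the
#' phenotypic root so that group sizes are preserved.
#'
#' @param counts1,counts2 `"term_counts"` objects (the fixture pair).
#' @param ontology the `"ontology"` the counts are defined over.
#' @param genes optional named list (group label -> character vector of
#'   gene symbols, recycled over patients in order) so that group
#'   assignment by partition reproduces the group sizes; defaults to one
#'   placeholder gene per group.
#' @return a `"cohort"` of `counts1$size + counts2$size` patients.
#' @examples
#' ont <- toy_ontology()
#' tc <- term_counts(c("HP:0000175" = 1L, "HP:0100737" = 2L,
#'                     "HP:0000202" = 1L), size = 2L, "g1", ont)
#' @export
realize_counts <- function(counts1, counts2, ontology, genes = NULL) {
  stopifnot(inherits(counts1, "term_counts"), inherits(counts2, "term_counts"),
            inherits(ontology, "ontology"))
  fp <- ontology_fingerprint(ontology)
  if (!identical(counts1$ontology, fp) || !identical(counts2$ontology, fp)) {
    stop("count fixtures were built over a different ontology")
  }
  pr <- ontology$phenotypic_root %||% ontology$root
  if (is.null(genes)) {
    genes <- setNames(list(paste0("GENE_", counts1$group),
                           paste0("GENE_", counts2$group)),
                      c(counts1$group, counts2$group))
  }

  realize_group <- function(tc, gene_pool, offset) {
    cts <- tc$counts
    # feasibility: parent count >= child count along every counted edge
    for (child in names(cts)) {
      for (p in ontology$parents[[child]]) {
        if (p == pr || !p %in% phenotypic_subtree(ontology)) next
        pc <- if (p %in% names(cts)) cts[[p]] else 0L
        if (pc < cts[[child]]) {
          stop("infeasible fixture: count monotonicity violated on edge ",
               child, " -> ", p, " (", cts[[child]], " > ", pc, ")")
        }
      }
    }
    # largest counted strict descendant per term: patients up to that
    # index are already annotated implicitly
    desc_max <- setNames(integer(length(cts)), names(cts))
    for (t in names(cts)) {
      dm <- 0L
      for (s in names(cts)) {
        if (s != t && t %in% ontology$anc[[s]]) dm <- max(dm, cts[[s]])
      }
      desc_max[[t]] <- dm
    }
    terms <- lapply(seq_len(tc$size), function(i) {
      obs <- names(cts)[desc_max < i & i <= cts]
      if (!length(obs)) obs <- pr
      obs
    })
    cohort(sprintf("%s_%03d", tc$group, seq_len(tc$size) + 0L),
           rep("fixture", tc$size),
           rep_len(gene_pool, tc$size),
           terms)
  }

  g1 <- realize_group(counts1, genes[[counts1$group]], 0L)
  g2 <- realize_group(counts2, genes[[counts2$group]], counts1$size)
  cohort(c(g1$patient_id, g2$patient_id),
         c(g1$publication_id, g2$publication_id),
         c(g1$gene, g2$gene),
         c(g1$terms, g2$terms))
}
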