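# In-code fixtures and independent oracles shared across test files.

# A is_a B is_a C (root C)
chain_ontology <- function() {
  build_ontology(
    ids = c("X:0000001", "X:0000002", "X:0000003"),
    labels = c("A", "B", "C"),
    parents = list("X:0000001" = "X:0000002",
                   "X:0000002" = "X:0000003",
                   "X:0000003" = character())
  )
}

# D -> {B, C}, B -> A, C -> A (two paths from D to A)
diamond_ontology <- function() {
  build_ontology(
    ids = c("X:0000001", "X:0000002", "X:0000003", "X:0000004"),
    labels = c("A", "B", "C", "D"),
    parents = list("X:0000004" = c("X:0000002", "X:0000003"),
                   "X:0000002" = "X:0000001",
                   "X:0000003" = "X:0000001",
                   "X:0000001" = character())
  )
}

# Independent reachability oracle: breadth-first traversal over a raw
# parent list, never touching the ontology's precomputed closure.
bfs_ancestors <- function(parents, term) {
  seen <- character()
  frontier <- parents[[term]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        seen)
  }
  seen
}

# Random parent list in creation order (acyclic by construction); used to
# cross-check generate_ontology-independent structures too.
random_parent_list <- function(n, max_parents = 3L) {
  ids <- sprintf("R:%07d", seq_len(n))
  parents <- setNames(vector("list", n), ids)
  parents[[1L]] <- character()
  for (i in 2:n) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    parents[[ids[i]]] <- ids[sample.int(i - 1L, k)]
  }
  parents
}

# quick cohort builder over any ontology
make_cohort <- function(term_sets, genes = NULL) {
  n <- length(term_sets)
  cohort(sprintf("P%03d", seq_len(n)), rep("PMID:1", n),
         genes %||% rep("GENE1", n), term_sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
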