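#' Construct an ontology object
#'
#' Builds a rooted directed acyclic graph of terms connected by `is_a`
#' edges, the structure used by the Human Phenotype Ontology (HPO).  Terms
#' may have several parents (e.g. *Cleft palate* sits under both *Oral
#' cleft* and *Abnormal hard palate morphology*), so the graph is a DAG,
#' not a tree.  Ancestor sets for every term are precomputed at
#' construction time.
#'
#' @param ids character vector of primary term identifiers
#'   (`"PREFIX:digits"`, e.g. `"HP:0000175"`).
#' @param labels character vector of term names, parallel to `ids`.
#' @param parents named list mapping each id to the character vector of its
#'   direct `is_a` parents (empty for the root and for obsolete terms).
#' @param alt_ids named list mapping ids to character vectors of secondary
#'   identifiers that resolve to them.
#' @param obsolete logical vector parallel to `ids`.
#' @param replaced_by named character vector mapping obsolete ids to their
#'   replacement term, where one exists.
#' @param root optional root id; if `NULL` the unique non-obsolete term
#'   without parents is used (an error is raised if it is not unique).
#' @param phenotypic_root optional id of the phenotype subtree root
#'   (HP:0000118 in the real HPO).  When set, reporting operations restrict
#'   to this term and its descendants.
#' @return an object of class `"ontology"`.
#' @seealso [parse_obo()], [term_ancestors()]
#' @export
build_ontology <- function(ids, labels, parents, alt_ids = list(),
                           obsolete = logical(length(ids)),
                           replaced_by = character(),
                           root = NULL, phenotypic_root = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate term id: ", ids[duplicated(ids)][1L])
  }
  bad <- !grepl("^[A-Za-z_]+:[0-9]+$", ids)
  if (any(bad)) {
    stop("term id does not match 'prefix:digits': ", ids[bad][1L])
  }
  labels <- setNames(as.character(labels), ids)
  obsolete <- setNames(as.logical(obsolete), ids)
  parents <- parents[ids[ids %in% names(parents)]]
  parents <- setNames(lapply(ids, function(i) {
    p <- unique(as.character(parents[[i]] %||% character()))
    if (obsolete[[i]] && length(p)) p <- character()  # obsolete: no edges
    p
  }), ids)

  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling)) {
    stop("dangling is_a target(s): ", paste(dangling, collapse = ", "))
  }

  live <- ids[!obsolete]
  n_par <- lengths(parents[live])
  if (is.null(root)) {
    cand <- live[n_par == 0L]
    if (length(cand) != 1L) {
      stop("root is not unique (", length(cand),
           " parentless non-obsolete terms); supply `root` explicitly")
    }
    root <- cand
  } else {
    if (!root %in% live) stop("declared root ", root, " is not a live term")
  }
  orphan <- setdiff(live[n_par == 0L], root)
  if (length(orphan)) {
    stop("non-root term(s) without parents: ", paste(orphan, collapse = ", "))
  }

  # children map
  children <- setNames(vector("list", length(ids)), ids)
  for (i in ids) {
    for (p in parents[[i]]) children[[p]] <- c(children[[p]], i)
  }

  # Kahn topological sort over live terms; leftovers witness a cycle
  indeg <- lengths(parents[live])
  names(indeg) <- live
  queue <- names(indeg)[indeg == 0L]
  topo <- character(0)
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      if (obsolete[[ch]]) next
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(live)) {
    member <- setdiff(live, topo)[1L]
    stop("cycle detected in is_a graph involving term ", member)
  }

  # ancestor closure (proper ancestors), parents processed before children
  anc <- setNames(vector("list", length(ids)), ids)
  for (t in topo) {
    ps <- parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }

  unreachable <- live[!vapply(live, function(t) {
    t == root || root %in% anc[[t]]
  }, logical(1L))]
  if (length(unreachable)) {
    stop("term(s) do not reach the root: ",
         paste(unreachable, collapse = ", "))
  }

  alt <- character(0)
  for (i in names(alt_ids)) {
    a <- unique(as.character(alt_ids[[i]]))
    alt <- c(alt, setNames(rep(i, length(a)), a))
  }
  if (anyDuplicated(names(alt))) {
    stop("alt_id assigned to more than one term: ",
         names(alt)[duplicated(names(alt))][1L])
  }
  clash <- intersect(names(alt), ids)
  if (length(clash)) {
    stop("alt_id collides with a primary id: ", clash[1L])
  }

  rb <- setNames(rep(NA_character_, length(ids)), ids)
  rb[names(replaced_by)] <- as.character(replaced_by)

  if (!is.null(phenotypic_root) && !phenotypic_root %in% live) {
    stop("phenotypic_root ", phenotypic_root, " is not a live term")
  }

  structure(list(
    ids = ids, labels = labels, parents = parents, children = children,
    obsolete = obsolete, replaced_by = rb, alt = alt,
    root = root, phenotypic_root = phenotypic_root,
    anc = anc, topo = topo
  ), class = "ontology")
}

#' Parse an OBO flat file into an ontology
#'
#' Reads the standard OBO 1.2/1.4 flat-file dialect (`[Term]` stanzas with
#' `id`, `name`, `is_a`, `alt_id`, `is_obsolete` and `replaced_by` tags).
#' Only `is_a` relationships become edges; all other relationship tags are
#' ignored, matching how the HPO phenotype subtree is structured.  Obsolete
#' terms are retained (flagged) but carry no edges and are excluded from
#' closure queries.
#'
#' @param x path to an OBO file, or a character vector of OBO text lines.
#' @param root,phenotypic_root see [build_ontology()].  By default the
#'   root is inferred and, if the file contains HP:0000118 (*Phenotypic
#'   abnormality*), it becomes the phenotypic root.
#' @return an `"ontology"` object.
#' @examples
#' ont <- toy_ontology()
#' ont
#' @export
parse_obo <- function(x, root = NULL, phenotypic_root = "auto") {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  # split into stanzas
  stanza_start <- grep("^\\[", lines)
  if (!length(stanza_start)) stop("no stanzas found in OBO input")
  bounds <- c(stanza_start, length(lines) + 1L)

  ids <- character(); labels <- character()
  parents <- list(); alt_ids <- list()
  obsolete <- logical(); replaced_by <- character()

  strip_comment <- function(v) sub("\\s*!.*$", "", v)

  for (k in seq_along(stanza_start)) {
    if (lines[stanza_start[k]] != "[Term]") next
    body <- lines[(stanza_start[k] + 1L):(bounds[k + 1L] - 1L)]
    body <- body[nzchar(body)]
    tags <- sub(":.*$", "", body)
    vals <- trimws(sub("^[^:]+:\\s*", "", body))

    id <- strip_comment(vals[tags == "id"])
    if (length(id) != 1L) stop("[Term] stanza without exactly one id tag")
    if (id %in% ids) stop("duplicate term id: ", id)
    nm <- vals[tags == "name"]
    obs <- any(tags == "is_obsolete" &
                 grepl("^true", strip_comment(vals), ignore.case = TRUE))

    ids <- c(ids, id)
    labels <- c(labels, if (length(nm)) nm[1L] else id)
    parents[[id]] <- strip_comment(vals[tags == "is_a"])
    alt_ids[[id]] <- strip_comment(vals[tags == "alt_id"])
    obsolete <- c(obsolete, obs)
    rb <- strip_comment(vals[tags == "replaced_by"])
    if (length(rb)) replaced_by[id] <- rb[1L]
  }

  pr <- if (identical(phenotypic_root, "auto")) {
    if ("HP:0000118" %in% ids) "HP:0000118" else NULL
  } else phenotypic_root

  build_ontology(ids, labels, parents, alt_ids, obsolete, replaced_by,
                 root = root, phenotypic_root = pr)
}

#' Write an ontology back to OBO text
#'
#' Emits one `[Term]` stanza per term with `id`, `name`, `is_a`, `alt_id`,
#' `is_obsolete` and `replaced_by` tags, so `parse_obo(write_obo(ont))`
#' round-trips the term and edge sets.
#'
#' @param ontology an `"ontology"` object.
#' @param path optional file path; if omitted the lines are returned.
#' @return invisibly (or visibly, without `path`) the OBO text lines.
#' @export
write_obo <- function(ontology, path = NULL) {
  stopifnot(inherits(ontology, "ontology"))
  out <- c("format-version: 1.2", "")
  for (id in ontology$ids) {
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ontology$labels[[id]]))
    for (a in names(ontology$alt)[ontology$alt == id]) {
      out <- c(out, paste0("alt_id: ", a))
    }
    for (p in ontology$parents[[id]]) {
      out <- c(out, paste0("is_a: ", p, " ! ", ontology$labels[[p]]))
    }
    if (ontology$obsolete[[id]]) out <- c(out, "is_obsolete: true")
    if (!is.na(ontology$replaced_by[[id]])) {
      out <- c(out, paste0("replaced_by: ", ontology$replaced_by[[id]]))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Resolve a term identifier to its primary, non-obsolete id
#'
#' Secondary (`alt_id`) identifiers are remapped to their primary term with
#' a warning; obsolete terms are remapped through `replaced_by` where one
#' exists and rejected otherwise.  Remaps are appended to [remap_log()].
#'
#' @param ontology an `"ontology"` object.
#' @param terms character vector of term ids.
#' @return character vector of resolved primary ids.
#' @export
resolve_terms <- function(ontology, terms) {
  stopifnot(inherits(ontology, "ontology"))
  terms <- as.character(terms)
  out <- terms
  for (i in seq_along(terms)) {
    t <- terms[i]
    if (t %in% names(ontology$alt)) {
      p <- unname(ontology$alt[[t]])
      warning("alt_id ", t, " remapped to ", p, call. = FALSE)
      .log_remap(t, p, "alt_id")
      t <- p
    }
    if (!t %in% ontology$ids) {
      stop("unknown term id: ", t, call. = FALSE)
    }
    if (ontology$obsolete[[t]]) {
      rb <- ontology$replaced_by[[t]]
      if (is.na(rb)) {
        stop("term ", t, " is obsolete and has no replacement", call. = FALSE)
      }
      warning("obsolete term ", t, " remapped to ", rb, call. = FALSE)
      .log_remap(t, rb, "obsolete")
      t <- rb
    }
    out[i] <- t
  }
  out
}

#' Ancestors of a term
#'
#' Transitive closure over `is_a` parent edges, deduplicated across the
#' multiple paths a DAG allows, capped at the ontology root.  This is the
#' closure used by the true-path (annotation propagation) rule.
#'
#' @param ontology an `"ontology"` object.
#' @param term a single term id (alt ids are remapped with a warning).
#' @param include_self should `term` itself be part of the returned set?
#' @return character vector of term ids.
#' @examples
#' ont <- toy_ontology()
#' term_ancestors(ont, "HP:0000175")   # Cleft palate: two parents
#' @export
term_ancestors <- function(ontology, term, include_self = FALSE) {
  stopifnot(inherits(ontology, "ontology"), length(term) == 1L)
  t <- resolve_terms(ontology, term)
  a <- ontology$anc[[t]]
  if (include_self) unique(c(t, a)) else a
}

#' Leaves of an ontology
#'
#' @param ontology an `"ontology"` object.
#' @return ids of non-obsolete terms with no non-obsolete children.
#' @export
ontology_leaves <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  live <- ontology$ids[!ontology$obsolete]
  live[vapply(live, function(t) {
    ch <- ontology$children[[t]]
    !any(!ontology$obsolete[ch])
  }, logical(1L))]
}

# ids in the reporting universe: the phenotypic subtree (root included)
# when a phenotypic root is set, otherwise every live term.
phenotypic_subtree <- function(ontology) {
  live <- ontology$ids[!ontology$obsolete]
  pr <- ontology$phenotypic_root
  if (is.null(pr)) return(live)
  live[vapply(live, function(t) t == pr || pr %in% ontology$anc[[t]],
              logical(1L))]
}

# cheap structural fingerprint used to detect count objects built over
# different ontologies
ontology_fingerprint <- function(ontology) {
  paste(length(ontology$ids), ontology$root,
        sum(lengths(ontology$parents)), sep = "/")
}

#' @export
print.ontology <- function(x, ...) {
  live <- sum(!x$obsolete)
  cat("Ontology: ", live, " terms (", sum(x$obsolete), " obsolete), ",
      sum(lengths(x$parents)), " is_a edges\n", sep = "")
  cat("  root: ", x$root, " (", x$labels[[x$root]], ")\n", sep = "")
  if (!is.null(x$phenotypic_root)) {
    cat("  phenotypic root: ", x$phenotypic_root, " (",
        x$labels[[x$phenotypic_root]], ")\n", sep = "")
  }
  invisible(x)
}

#' Packaged toy ontology
#'
#' A ~40-term synthetic miniature of the HPO built around the cleft-palate
#' neighbourhood and the phenotype branches analysed in the GPI-deficiency
#' cohort.  Term identifiers of real HPO terms are preserved where a
#' fixture pins them; purely decorative filler terms use the HP:9xxxxxx
#' range to avoid colliding with real terms.  Includes one multi-parent
#' term (*Cleft palate*), an `alt_id`, and obsolete terms with and without
#' a replacement.
#'
#' @return an `"ontology"` object.
#' @export
toy_ontology <- function() {
  parse_obo(system.file("extdata", "toy_hpo.obo", package = "phenodiff",
                        mustWork = TRUE))
}
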