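#' Construct a cohort of curated case reports
#'
#' A case report is the minimal record produced by literature biocuration:
#' the patient identifier, the publication it came from (typically a PMID),
#' the mutated gene, and the set of observed HPO terms.  Variant
#' descriptors may be carried along as free text but are never
#' interpreted; negated ("excluded") phenotype assertions are not
#' modelled.
#'
#' @param patient_id character vector, unique within the cohort.
#' @param publication_id character vector (e.g. PMIDs).
#' @param gene character vector of HGNC-style gene symbols.
#' @param terms list of character vectors of observed term ids, one per
#'   patient; duplicated ids within a patient are dropped silently (set
#'   semantics), empty sets are an error.
#' @param variant_labels optional list of free-text variant descriptors.
#' @return an object of class `"cohort"`.
#' @export
cohort <- function(patient_id, publication_id, gene, terms,
                   variant_labels = NULL) {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  stopifnot(length(publication_id) == n, length(gene) == n,
            length(terms) == n)
  if (anyDuplicated(patient_id)) {
    stop("duplicate patient_id: ",
         patient_id[duplicated(patient_id)][1L])
  }
  terms <- lapply(terms, function(t) unique(as.character(t)))
  empty <- lengths(terms) == 0L
  if (any(empty)) {
    stop("patient ", patient_id[which(empty)[1L]], " has no observed terms")
  }
  structure(list(
    patient_id = patient_id,
    publication_id = as.character(publication_id),
    gene = as.character(gene),
    terms = setNames(terms, patient_id),
    variant_labels = variant_labels
  ), class = "cohort")
}

#' @export
length.cohort <- function(x) length(x$patient_id)

#' @export
`[.cohort` <- function(x, i) {
  cohort(x$patient_id[i], x$publication_id[i], x$gene[i], x$terms[i],
         if (!is.null(x$variant_labels)) x$variant_labels[i])
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort: ", length(x), " patients, ",
      length(unique(x$publication_id)), " publications, ",
      length(unique(x$gene)), " genes\n", sep = "")
  cat("  observed terms per patient: median ",
      stats::median(lengths(x$terms)), " (range ",
      min(lengths(x$terms)), "-", max(lengths(x$terms)), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(
    patient_id = x$patient_id,
    publication_id = x$publication_id,
    gene = x$gene,
    terms = vapply(x$terms, paste, "", collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# columns a curated table must have, in the interchange dialect
.case_columns <- c("patient_id", "publication_id", "gene", "terms")

#' Read curated case reports
#'
#' Reads the package's minimal interchange formats for biocurated case
#' reports: a UTF-8 tab-delimited table with header columns `patient_id`,
#' `publication_id`, `gene`, `terms` (term ids joined by `";"`), or a JSON
#' array of objects with the same keys (`terms` as an array).  Term
#' validation against an ontology is deferred to [validate_cohort()] so
#' that cohorts can be read before an ontology is chosen.
#'
#' Columns asserting negated/excluded phenotypes are rejected explicitly
#' rather than silently dropped, because ignoring them would change the
#' meaning of the record.
#'
#' @param x a file path or literal text.
#' @param format `"tsv"` or `"json"`.
#' @return a `"cohort"` object.
#' @export
read_cases <- function(x, format = c("tsv", "json")) {
  format <- match.arg(format)
  is_path <- length(x) == 1L && !grepl("\n", x) && file.exists(x)
  if (format == "tsv") {
    df <- if (is_path) {
      utils::read.delim(x, stringsAsFactors = FALSE, colClasses = "character")
    } else {
      utils::read.delim(text = paste(x, collapse = "\n"),
                        stringsAsFactors = FALSE, colClasses = "character")
    }
    neg <- grep("negat|exclud", names(df), ignore.case = TRUE, value = TRUE)
    if (length(neg)) {
      stop("unsupported column(s) asserting negated phenotypes: ",
           paste(neg, collapse = ", "))
    }
    missing_cols <- setdiff(.case_columns, names(df))
    if (length(missing_cols)) {
      stop("missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    terms <- strsplit(df$terms, ";", fixed = TRUE)
    terms <- lapply(terms, function(t) trimws(t[nzchar(trimws(t))]))
    cohort(df$patient_id, df$publication_id, df$gene, terms)
  } else {
    recs <- if (is_path) {
      jsonlite::fromJSON(x, simplifyVector = FALSE)
    } else {
      jsonlite::fromJSON(paste(x, collapse = "\n"), simplifyVector = FALSE)
    }
    if (!is.list(recs)) stop("JSON input must be an array of case objects")
    for (i in seq_along(recs)) {
      missing_keys <- setdiff(.case_columns, names(recs[[i]]))
      if (length(missing_keys)) {
        stop("case record ", i, " is missing key(s): ",
             paste(missing_keys, collapse = ", "))
      }
    }
    cohort(
      vapply(recs, function(r) as.character(r$patient_id), ""),
      vapply(recs, function(r) as.character(r$publication_id), ""),
      vapply(recs, function(r) as.character(r$gene), ""),
      lapply(recs, function(r) unlist(r$terms, use.names = FALSE))
    )
  }
}

#' Write a cohort to the interchange formats
#'
#' @param x a `"cohort"` object.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cohort"))
  if (format == "tsv") {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    recs <- lapply(seq_along(x$patient_id), function(i) {
      list(patient_id = x$patient_id[i],
           publication_id = x$publication_id[i],
           gene = x$gene[i],
           terms = x$terms[[i]])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Validate a cohort's terms against an ontology
#'
#' Resolves every observed term (remapping alt ids and replaced obsolete
#' terms, with warnings) and errors, naming the patient and term, when a
#' term does not resolve.
#'
#' @param x a `"cohort"` object.
#' @param ontology an `"ontology"` object.
#' @return a `"cohort"` with all term ids resolved to primary ids.
#' @export
validate_cohort <- function(x, ontology) {
  stopifnot(inherits(x, "cohort"), inherits(ontology, "ontology"))
  terms <- lapply(x$patient_id, function(pid) {
    tryCatch(
      unique(resolve_terms(ontology, x$terms[[pid]])),
      error = function(e) {
        stop("patient ", pid, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  cohort(x$patient_id, x$publication_id, x$gene, terms, x$variant_labels)
}

#' Construct a two-group gene partition
#'
#' A stage partition maps every gene symbol to one of exactly two group
#' labels — e.g. the GPI-anchor biosynthesis pathway split into a
#' Synthesis stage and a Transamidase+Remodeling stage.  A synonym map
#' handles alternate symbols (e.g. MPPE1 for PGAP5).
#'
#' @param name partition name.
#' @param genes named character vector: gene symbol -> group label; exactly
#'   two distinct labels must occur.
#' @param synonyms named character vector: alternate symbol -> canonical
#'   symbol present in `genes`.
#' @return an object of class `"stage_partition"`.
#' @export
stage_partition <- function(name, genes, synonyms = character()) {
  stopifnot(is.character(genes), !is.null(names(genes)))
  labels <- unique(unname(genes))
  if (length(labels) != 2L) {
    stop("partition must use exactly 2 group labels, got ",
         length(labels), ": ", paste(labels, collapse = ", "))
  }
  if (anyDuplicated(names(genes))) {
    stop("gene mapped more than once: ",
         names(genes)[duplicated(names(genes))][1L])
  }
  if (length(synonyms)) {
    bad <- !synonyms %in% names(genes)
    if (any(bad)) {
      stop("synonym target not in partition: ", synonyms[bad][1L])
    }
  }
  structure(list(name = name, genes = genes, labels = labels,
                 synonyms = synonyms),
            class = "stage_partition")
}

#' @export
print.stage_partition <- function(x, ...) {
  cat("Stage partition '", x$name, "': ", length(x$genes), " genes\n",
      sep = "")
  for (l in x$labels) {
    cat("  ", l, ": ", sum(x$genes == l), " genes\n", sep = "")
  }
  invisible(x)
}

#' Read a partition fixture
#'
#' Partition fixtures are tab-delimited files with a `# name:` header line
#' and columns `gene`, `group`, `synonym_of`; rows with a `synonym_of`
#' entry define symbol synonyms instead of group membership.
#'
#' @param path file path.
#' @return a `"stage_partition"`.
#' @export
read_partition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name_line <- grep("^#\\s*name:", lines, value = TRUE)
  name <- if (length(name_line)) {
    trimws(sub("^#\\s*name:\\s*", "", name_line[1L]))
  } else basename(path)
  df <- utils::read.delim(text = paste(grep("^#", lines, invert = TRUE,
                                            value = TRUE), collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!"synonym_of" %in% names(df)) df$synonym_of <- ""
  df$synonym_of[is.na(df$synonym_of)] <- ""
  syn_rows <- nzchar(df$synonym_of)
  genes <- setNames(df$group[!syn_rows], df$gene[!syn_rows])
  synonyms <- setNames(df$synonym_of[syn_rows], df$gene[syn_rows])
  stage_partition(name, genes, synonyms)
}

#' Assign cohort patients to partition groups by gene
#'
#' Each patient whose gene symbol (after synonym normalisation) appears in
#' the partition is placed in exactly one group; the rest are returned as
#' unassigned, with a warning, and are excluded from downstream analysis.
#' Assignment is deterministic and preserves cohort order within groups.
#'
#' @param x a `"cohort"`.
#' @param partition a `"stage_partition"`.
#' @return a list with elements `groups` (named list of `"cohort"`
#'   objects, one per group label, in label order) and `unassigned`
#'   (a `"cohort"`, possibly empty).
#' @export
assign_groups <- function(x, partition) {
  stopifnot(inherits(x, "cohort"), inherits(partition, "stage_partition"))
  gene <- x$gene
  hit <- gene %in% names(partition$synonyms)
  gene[hit] <- unname(partition$synonyms[gene[hit]])
  grp <- rep(NA_character_, length(gene))
  known <- gene %in% names(partition$genes)
  grp[known] <- unname(partition$genes[gene[known]])
  if (any(!known)) {
    warning(sum(!known), " patient(s) with genes outside partition '",
            partition$name, "' left unassigned", call. = FALSE)
  }
  groups <- setNames(
    lapply(partition$labels, function(l) x[which(grp %in% l)]),
    partition$labels
  )
  list(groups = groups, unassigned = x[which(!known)])
}
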