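#' Packaged GPI-deficiency cohort fixtures
#'
#' The motivating study curated 152 patients from 58 publications with
#' variants in 22 genes of the GPI-anchor biosynthesis pathway and
#' compared the phenotypic spectra of gene-defined groups.  The
#' per-patient phenotype records are not deposited in machine-readable
#' form, so the package encodes what the published tables print: the
#' per-gene patient counts, the two pathway-stage gene partitions, and
#' the 21 significantly enriched terms with their per-group counts and
#' Bonferroni-corrected p-values.
#'
#' @return `gpi_gene_counts()`: data frame with columns `gene`, `stage`,
#'   `patients` (29 pathway genes; the per-stage sums are the group sizes
#'   93 and 59).
#' @name gpi_fixtures
NULL

gpi_extdata <- function(file) {
  system.file("extdata", file, package = "phenodiff", mustWork = TRUE)
}

#' @rdname gpi_fixtures
#' @export
gpi_gene_counts <- function() {
  utils::read.delim(gpi_extdata("gpi_gene_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname gpi_fixtures
#' @param name which partition: `"synthesis_vs_TR"` (anchor assembly vs
#'   protein attachment + remodeling/trafficking) or
#'   `"synTA_vs_remodeling"` (assembly + transamidase complex vs the four
#'   remodeling genes PGAP1/2/3/5).
#' @return `gpi_partition()`: a `"stage_partition"`.
#' @export
gpi_partition <- function(name = c("synthesis_vs_TR", "synTA_vs_remodeling")) {
  name <- match.arg(name)
  read_partition(gpi_extdata(paste0("partition_", name, ".tsv")))
}

#' @rdname gpi_fixtures
#' @return `gpi_term_counts()`: data frame with columns `term_id`,
#'   `label`, `count_synthesis`, `count_tr`, `p_corrected` (as printed, 5
#'   decimals; `0` means "< 0.000005", not exactly zero) and
#'   `enriched_in`.
#' @export
gpi_term_counts <- function() {
  utils::read.delim(gpi_extdata("gpi_term_counts.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c(p_corrected = "numeric"))
}

#' @rdname gpi_fixtures
#' @param ontology an ontology containing the 21 enriched terms; defaults
#'   to [toy_ontology()].
#' @return `gpi_fixture_counts()`: list of two `"term_counts"` objects
#'   (`Synthesis`, n = 93; `Transamidase+Remodeling`, n = 59) encoding the
#'   published per-term counts.
#' @export
gpi_fixture_counts <- function(ontology = toy_ontology()) {
  tt <- gpi_term_counts()
  list(
    term_counts(setNames(tt$count_synthesis, tt$term_id),
                size = 93L, group = "Synthesis", ontology = ontology),
    term_counts(setNames(tt$count_tr, tt$term_id),
                size = 59L, group = "Transamidase+Remodeling",
                ontology = ontology)
  )
}

#' @rdname gpi_fixtures
#' @return `gpi_fixture_cohort()`: a synthetic 152-patient `"cohort"`
#'   (built by [realize_counts()]) whose propagated per-term counts
#'   reproduce the published tables exactly, and whose gene assignments
#'   follow the published per-gene patient counts, so that partitioning
#'   by gene reproduces the 93/59 group sizes.
#' @export
gpi_fixture_cohort <- function(ontology = toy_ontology()) {
  fx <- gpi_fixture_counts(ontology)
  gc <- gpi_gene_counts()
  gene_pools <- list(
    "Synthesis" = rep(gc$gene[gc$stage == "Synthesis"],
                      gc$patients[gc$stage == "Synthesis"]),
    "Transamidase+Remodeling" = rep(
      gc$gene[gc$stage == "Transamidase+Remodeling"],
      gc$patients[gc$stage == "Transamidase+Remodeling"])
  )
  realize_counts(fx[[1L]], fx[[2L]], ontology, genes = gene_pools)
}
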