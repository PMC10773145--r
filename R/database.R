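#' Two-step search database reduction
#'
#' Large metagenome-derived databases inflate search space and FDR. The
#' two-step strategy first searches each run against the full tongue-coating
#' database, keeps only proteins supported by confident peptide-spectrum
#' matches (q-value at or below the cutoff), and merges these per-run
#' simplified databases with the host database into the combined database
#' used for the second search. This module consumes PSM tables produced by
#' an external search engine; it does not re-run protein inference.
#'
#' @name database_workflow
NULL

#' Read a PSM table
#'
#' TSV with columns `run`, `peptide`, `proteins` (semicolon-separated
#' accessions), `q_value` in `[0, 1]`.
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_psm_table <- function(path) {
  psms <- readr::read_tsv(path, col_types = readr::cols(
    run = readr::col_character(), peptide = readr::col_character(),
    proteins = readr::col_character(), q_value = readr::col_double()
  ), progress = FALSE)
  validate_psms(psms)
}

validate_psms <- function(psms) {
  req <- c("run", "peptide", "proteins", "q_value")
  if (!all(req %in% names(psms))) {
    abort_schema(paste("PSM table must have columns:", paste(req, collapse = ", ")))
  }
  if (nrow(psms) && (any(psms$q_value < 0 | psms$q_value > 1, na.rm = TRUE) ||
                     anyNA(psms$q_value))) {
    abort_arg("PSM q_value must lie in [0, 1]")
  }
  if (nrow(psms) && any(!nzchar(psms$proteins))) {
    abort_arg("every PSM row must name at least one protein accession")
  }
  as_tibble(psms)
}

#' Reduce a source database to PSM-supported proteins
#'
#' Keeps exactly the source records whose accession appears in at least one
#' PSM row with `q_value <= q_cutoff`, collapsing duplicates; output order
#' is first appearance in the PSM table. Retained accessions missing from
#' the source database raise a reconciliation error naming them.
#'
#' @param psms PSM tibble (see [read_psm_table()]).
#' @param source_db Protein tibble (`accession`, `sequence`, ...) or path to
#'   a FASTA file.
#' @param q_cutoff Row-level q-value cutoff (default 0.01, the search FDR).
#' @return Tibble of retained protein records.
#' @export
simplify_database <- function(psms, source_db, q_cutoff = 0.01) {
  psms <- validate_psms(psms)
  if (is.character(source_db)) source_db <- read_protein_fasta(source_db)
  hits <- psms[psms$q_value <= q_cutoff, , drop = FALSE]
  accs <- unlist(strsplit(hits$proteins, ";", fixed = TRUE), use.names = FALSE)
  accs <- accs[nzchar(accs)]
  accs <- accs[!duplicated(accs)]
  missing <- setdiff(accs, source_db$accession)
  if (length(missing)) {
    abort(paste0("PSM accession(s) absent from source database: ",
                 paste(head(missing, 10), collapse = ", ")),
          class = "linguomics_reconciliation_error")
  }
  source_db[match(accs, source_db$accession), , drop = FALSE]
}

#' Merge simplified databases with the host database
#'
#' Union of all records keyed by accession; on accession collision the host
#' record wins. Output is canonicalized by accession sort, so the merge is
#' invariant to the order of the reduced sets.
#'
#' @param reduced List of protein record tibbles (from
#'   [simplify_database()]).
#' @param host_db Protein tibble or FASTA path for the host database.
#' @return Tibble of merged records with a `source` column
#'   (`"host"`/`"reduced"`).
#' @export
merge_databases <- function(reduced, host_db) {
  if (is.data.frame(reduced)) reduced <- list(reduced)
  if (is.character(host_db)) host_db <- read_protein_fasta(host_db)
  red <- bind_rows(reduced)
  keep <- c("accession", "desc", "sequence")
  red <- red[, intersect(keep, names(red)), drop = FALSE]
  host <- as_tibble(host_db)[, intersect(keep, names(host_db)), drop = FALSE]
  if (nrow(host)) host$source <- "host"
  if (nrow(red)) red$source <- "reduced"
  merged <- bind_rows(host, red)  # host first so it wins collisions
  merged <- merged[!duplicated(merged$accession), , drop = FALSE]
  arrange(merged, .data$accession)
}
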