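#' Origin-partitioned quantification tables
#'
#' A quant table is a wide tibble: one row per feature (peptide, protein,
#' taxon, COG or KO), a `feature_id` column, optional annotation columns
#' (`origin`, `taxon_id`, `cog`, `ko`, `rank`), and one numeric column per
#' sample. A missing intensity (`NA`) means the feature was not identified
#' in that sample; identification counting therefore uses non-missing, not
#' non-zero, values. Intensities stay on their native linear scale here;
#' log transforms happen inside the statistics functions.
#'
#' @name quantification
NULL

ANNOTATION_COLS <- c("feature_id", "origin", "taxon_id", "cog", "ko", "rank")

#' Sample columns of a quant table
#' @param table Quant tibble.
#' @return Character vector of sample ids.
#' @export
quant_samples <- function(table) setdiff(names(table), ANNOTATION_COLS)

#' Extract the numeric intensity matrix (features x samples)
#' @param table Quant tibble.
#' @return Numeric matrix with feature ids as row names.
#' @export
quant_matrix <- function(table) {
  m <- as.matrix(table[, quant_samples(table), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- table$feature_id
  m
}

validate_quant <- function(table, need = character()) {
  if (!"feature_id" %in% names(table)) abort_schema("quant table needs a `feature_id` column")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort_schema(paste0("quant table lacks annotation column(s): ",
                        paste(miss, collapse = ", ")))
  }
  samples <- quant_samples(table)
  if (anyDuplicated(samples)) abort_schema("duplicate sample columns")
  m <- quant_matrix(table)
  if (any(m < 0, na.rm = TRUE)) abort_arg("negative intensities are not allowed")
  invisible(table)
}

#' Read a quant table from TSV
#'
#' Both the wide layout (feature rows, sample columns) and the long layout
#' (`feature_id`, `sample`, `intensity`, annotations repeated per row) are
#' accepted; long input is pivoted wide.
#'
#' @param path TSV file.
#' @param format `"wide"` or `"long"`.
#' @return Quant tibble.
#' @export
read_quant_table <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (format == "long") {
    ann <- intersect(ANNOTATION_COLS, names(tbl))
    tbl <- tidyr::pivot_wider(tbl, id_cols = all_of(ann),
                              names_from = "sample", values_from = "intensity")
  }
  validate_quant(tbl)
  as_tibble(tbl)
}

#' Write a quant table as wide TSV
#' @param table Quant tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `subject_id`, `center`, `group`
#' (`cancer`/`non_cancer`), `stage`, `timepoint`, `replicate`.
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Sample quality control by identification counts
#'
#' A sample is kept when it has at least `min_human` identified
#' human-derived proteins and at least `min_microbial` identified
#' microbial-derived proteins (identification = non-missing intensity). The
#' defaults are the study thresholds of 800 and 2000. The filter is
#' idempotent.
#'
#' @param protein_table Protein-level quant tibble with an `origin` column.
#' @param min_human,min_microbial Minimum identification counts.
#' @return List with `kept` (character sample ids) and `report` (tibble of
#'   per-sample counts and exclusion reason).
#' @export
qc_filter <- function(protein_table, min_human = 800, min_microbial = 2000) {
  validate_quant(protein_table, need = "origin")
  m <- quant_matrix(protein_table)
  human <- colSums(!is.na(m[protein_table$origin == "human", , drop = FALSE]))
  microb <- colSums(!is.na(m[protein_table$origin == "microbial", , drop = FALSE]))
  report <- tibble(
    sample_id = colnames(m),
    n_human = as.integer(human),
    n_microbial = as.integer(microb),
    kept = human >= min_human & microb >= min_microbial
  )
  report$reason <- dplyr::case_when(
    report$kept ~ NA_character_,
    report$n_human < min_human & report$n_microbial < min_microbial ~
      "too few human and microbial proteins",
    report$n_human < min_human ~ "too few human proteins",
    TRUE ~ "too few microbial proteins"
  )
  list(kept = report$sample_id[report$kept], report = report)
}

#' Ratio of human to microbial protein abundance per sample
#'
#' For each sample, the summed intensity of human-origin features divided by
#' the summed intensity of microbial-origin features, missing treated as 0.
#' A zero microbial total makes the ratio undefined; such samples get `NA`
#' with a classed warning.
#'
#' @param protein_table Protein-level quant tibble with `origin`.
#' @param samples Optional subset of sample ids (default all).
#' @return Tibble with `sample_id`, `human_total`, `microbial_total`,
#'   `ratio`.
#' @export
host_microbe_ratio <- function(protein_table, samples = NULL) {
  validate_quant(protein_table, need = "origin")
  m <- quant_matrix(protein_table)
  m[is.na(m)] <- 0
  samples <- samples %||% colnames(m)
  unknown <- setdiff(samples, colnames(m))
  if (length(unknown)) abort_lookup(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")))
  m <- m[, samples, drop = FALSE]
  ht <- colSums(m[protein_table$origin == "human", , drop = FALSE])
  mt <- colSums(m[protein_table$origin == "microbial", , drop = FALSE])
  if (any(mt == 0)) {
    warn(paste0("zero microbial total; ratio undefined for sample(s): ",
                paste(samples[mt == 0], collapse = ", ")),
         class = "linguomics_undefined_ratio")
  }
  tibble(sample_id = samples, human_total = unname(ht),
         microbial_total = unname(mt),
         ratio = unname(ifelse(mt == 0, NA_real_, ht / mt)))
}

#' Aggregate a quant table to a taxonomic rank or functional category
#'
#' Output intensity is the per-sample sum of member feature intensities
#' (`NA` when no member was identified). For `level = "taxon_rank"` each
#' feature's assigned taxon is mapped up its lineage to `rank`; features
#' whose lineage lacks that rank (or lacking the annotation entirely) are
#' dropped and counted in the report. Aggregation conserves total mass up
#' to the dropped features.
#'
#' @param table Quant tibble annotated with `taxon_id`, `cog` or `ko`.
#' @param level `"taxon_rank"`, `"cog"` or `"ko"`.
#' @param tree `taxonomy_tree`, required for `level = "taxon_rank"`.
#' @param rank Target rank for `level = "taxon_rank"` (e.g. `"phylum"`,
#'   `"species"`).
#' @return List with `table` (aggregated quant tibble; `feature_id` is the
#'   taxon/COG/KO id) and `report` (dropped feature count and ids).
#' @export
aggregate_quant <- function(table, level = c("taxon_rank", "cog", "ko"),
                            tree = NULL, rank = NULL) {
  level <- match.arg(level)
  if (level == "taxon_rank") {
    if (is.null(tree) || is.null(rank)) {
      abort_arg("level = 'taxon_rank' needs `tree` and `rank`")
    }
    if (!rank %in% RANK_LEVELS) abort_arg(paste0("unknown rank '", rank, "'"))
    validate_quant(table, need = "taxon_id")
    known <- !is.na(table$taxon_id) & table$taxon_id %in% tree$nodes$taxon_id
    mapped <- rep(NA_character_, nrow(table))
    uniq <- unique(table$taxon_id[known])
    up <- vapply(uniq, function(t) taxon_at_rank(tree, t, rank), "")
    mapped[known] <- up[table$taxon_id[known]]
    key <- mapped
  } else {
    validate_quant(table, need = level)
    key <- table[[level]]
  }
  dropped <- is.na(key)
  report <- tibble(
    level = if (level == "taxon_rank") paste0("taxon:", rank) else level,
    n_input = nrow(table),
    n_dropped = sum(dropped),
    dropped_features = list(table$feature_id[dropped])
  )
  kept <- table[!dropped, , drop = FALSE]
  key <- key[!dropped]
  m <- quant_matrix(kept)
  sums <- rowsum(ifelse(is.na(m), 0, m), group = key, na.rm = FALSE)
  any_id <- rowsum((!is.na(m)) * 1, group = key) > 0
  sums[!any_id] <- NA_real_
  out <- as_tibble(sums)
  out <- bind_cols(tibble(feature_id = rownames(sums)), out)
  if (level == "taxon_rank") {
    out <- bind_cols(out[, 1], tibble(rank = rank), out[, -1])
  }
  list(table = out, report = report)
}

#' Overlap report between two cohorts' identified feature sets
#'
#' The shared percentage uses the union (total identified across both
#' cohorts) as denominator: `100 * |A intersect B| / |A union B|`, reported
#' to one decimal place. It is symmetric in its arguments; two empty sets
#' are an error.
#'
#' @param set_a,set_b Character vectors of feature ids.
#' @return Tibble with `n_a`, `n_b`, `n_union`, `n_intersect`,
#'   `shared_pct`.
#' @export
cohort_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (!length(a) && !length(b)) {
    abort_arg("overlap of two empty sets is undefined")
  }
  n_union <- length(union(a, b))
  n_int <- length(intersect(a, b))
  tibble(n_a = length(a), n_b = length(b), n_union = n_union,
         n_intersect = n_int, shared_pct = round(100 * n_int / n_union, 1))
}

#' Identified feature ids of a cohort
#'
#' Features identified (non-missing) in at least one of the given samples,
#' optionally restricted by origin.
#'
#' @param table Quant tibble.
#' @param samples Sample ids defining the cohort.
#' @param origin Optional origin filter.
#' @return Character vector of feature ids.
#' @export
identified_features <- function(table, samples, origin = NULL) {
  if (!is.null(origin)) {
    validate_quant(table, need = "origin")
    table <- table[table$origin == origin, , drop = FALSE]
  }
  m <- quant_matrix(table)[, samples, drop = FALSE]
  rownames(m)[rowSums(!is.na(m)) > 0]
}
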