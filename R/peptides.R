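#' In-silico tryptic digestion and peptide-centric taxonomic annotation
#'
#' Observed DIA peptides may carry missed cleavages that a peptide-centric
#' taxonomy index (built from fully tryptic peptides) cannot match directly.
#' The tools here digest sequences in silico, canonicalize them under the
#' "equal I and L" rule, index all tryptic peptides of the host and
#' metagenome-derived databases, and annotate observed peptides by resolving
#' the taxa of their fully tryptic subpeptides with the branch rule.
#'
#' @name peptide_tools
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Tryptic digestion with missed-cleavage enumeration
#'
#' Trypsin cleaves C-terminal to K or R, but not when the next residue is
#' proline (the proline rule is the standard convention; disable it with
#' `proline_rule = FALSE`). All fragments spanning at most `max_missed`
#' internal cleavage sites are returned in order of start position (then
#' increasing length); `max_missed = 0` gives the fully tryptic partition.
#'
#' @param sequence Single amino-acid string over the 20 standard residues.
#' @param max_missed Maximum number of internal missed cleavage sites.
#' @param proline_rule Suppress cleavage before proline?
#' @return Character vector of fragments.
#' @export
#' @examples
#' tryptic_digest("MAGICKDEPTHRGAIN", 0)
#' tryptic_digest("MAGICKRPEPTIDEK", 1)
tryptic_digest <- function(sequence, max_missed = 0, proline_rule = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) abort_arg("`sequence` must be non-empty")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), AA20)
  if (length(bad)) {
    abort(paste0("non-standard residue(s) in sequence: ", paste(bad, collapse = ", ")),
          class = "linguomics_validation_error")
  }
  if (max_missed < 0) abort_arg("`max_missed` must be >= 0")
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule) cut_after <- cut_after[res[cut_after + 1] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nseg <- length(starts)
  frags <- character(0)
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed)) {
      frags <- c(frags, substr(sequence, starts[i], ends[j]))
    }
  }
  frags
}

#' Canonicalize and length-filter peptide fragments
#'
#' Applies the "equal I and L" rule by rewriting every L as I (keeping the
#' canonical string inside the 20-letter alphabet) and removes fragments
#' shorter than `min_len` or longer than `max_len` residues (bounds
#' inclusive). Order is preserved; an empty result is allowed.
#'
#' @param fragments Character vector of fragments.
#' @param min_len,max_len Inclusive length bounds (defaults 5 and 50).
#' @return Character vector of canonical fragments.
#' @export
canonicalize_peptides <- function(fragments, min_len = 5, max_len = 50) {
  out <- gsub("L", "I", fragments, fixed = TRUE)
  out[nchar(out) >= min_len & nchar(out) <= max_len]
}

# Fully tryptic, canonicalized, length-filtered subpeptides of one observed
# peptide - the unit that is looked up in the index.
subpeptides_of <- function(peptide, min_len = 5, max_len = 50, proline_rule = TRUE) {
  canonicalize_peptides(tryptic_digest(peptide, 0, proline_rule),
                        min_len = min_len, max_len = max_len)
}

parse_microbial_header <- function(headers) {
  acc <- sub("\\s.*$", "", headers)
  taxid <- stringr::str_match(headers, "taxid=([^\\s]+)")[, 2]
  tibble(accession = acc, taxon_id = taxid)
}

parse_human_header <- function(headers) {
  m <- stringr::str_match(headers, "^(?:sp|tr)\\|([^|]+)\\|")
  acc <- ifelse(is.na(m[, 2]), sub("\\s.*$", "", headers), m[, 2])
  tibble(accession = acc, taxon_id = NA_character_)
}

#' Read a protein FASTA into a tibble
#'
#' Microbial headers carry a `taxid=<id>` token
#' (`>accession taxid=1234 description`); human headers are UniProt-style
#' (`>sp|ACC|NAME ...`). With `origin = "microbial"` a header without the
#' taxid token is a header-format error.
#'
#' @param path FASTA file.
#' @param origin `"human"`, `"microbial"`, or `NULL` to keep raw headers only.
#' @return Tibble with `accession`, `desc`, `sequence` and, when `origin`
#'   is given, `origin` and `taxon_id`.
#' @export
read_protein_fasta <- function(path, origin = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  out <- tibble(
    accession = sub("\\s.*$", "", headers),
    desc = headers,
    sequence = unname(as.character(seqs))
  )
  if (!is.null(origin)) {
    origin <- match.arg(origin, c("human", "microbial"))
    parsed <- if (origin == "microbial") parse_microbial_header(headers) else parse_human_header(headers)
    if (origin == "microbial" && anyNA(parsed$taxon_id)) {
      bad <- parsed$accession[is.na(parsed$taxon_id)]
      abort(paste0("microbial FASTA header(s) without taxid= token: ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "linguomics_header_error")
    }
    out$accession <- parsed$accession
    out$origin <- origin
    out$taxon_id <- parsed$taxon_id
  }
  out
}

#' Write protein records to FASTA
#'
#' @param records Tibble with `accession`, `sequence` and optionally `desc`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- if ("desc" %in% names(records) && !anyNA(records$desc)) {
    records$desc
  } else {
    records$accession
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Build a canonical peptide-to-protein index over source databases
#'
#' Digests every protein of every database with up to `max_missed` missed
#' cleavages, canonicalizes and length-filters the fragments, and indexes
#' peptide -> (accession, origin, taxon id). Human entries carry `NA` taxon.
#' Accessions colliding across databases are kept at first occurrence with a
#' warning. `databases` may be a tibble of `(path, origin)` rows pointing at
#' FASTA files, or a protein tibble with columns `accession`, `origin`,
#' `taxon_id`, `sequence` (as produced by [generate_reference()]).
#'
#' @param databases See above.
#' @param max_missed Missed cleavages indexed (default 2, a typical search
#'   engine setting).
#' @param min_len,max_len Peptide length filter.
#' @return A `peptide_index`: tibble with columns `peptide`, `accession`,
#'   `origin`, `taxon_id`.
#' @export
build_peptide_index <- function(databases, max_missed = 2, min_len = 5, max_len = 50) {
  if (is.data.frame(databases) && "sequence" %in% names(databases)) {
    prot <- as_tibble(databases)
    if (!all(c("accession", "origin", "sequence") %in% names(prot))) {
      abort_schema("protein table needs accession, origin, sequence columns")
    }
    if (!"taxon_id" %in% names(prot)) prot$taxon_id <- NA_character_
  } else {
    prot <- purrr::pmap_dfr(as_tibble(databases), function(path, origin, ...) {
      read_protein_fasta(path, origin = origin)
    })
  }
  if (anyDuplicated(prot$accession)) {
    dup <- unique(prot$accession[duplicated(prot$accession)])
    warn(paste0("duplicate accession(s) across databases, keeping first occurrence: ",
                paste(head(dup, 5), collapse = ", ")),
         class = "linguomics_collision_warning")
    prot <- prot[!duplicated(prot$accession), ]
  }
  entries <- purrr::pmap(
    list(prot$sequence, prot$accession, prot$origin, prot$taxon_id),
    function(seq, acc, org, tax) {
      peps <- unique(canonicalize_peptides(tryptic_digest(seq, max_missed),
                                           min_len = min_len, max_len = max_len))
      if (!length(peps)) return(NULL)
      tibble(peptide = peps, accession = acc, origin = org, taxon_id = tax)
    }
  )
  idx <- bind_rows(entries)
  class(idx) <- c("peptide_index", class(idx))
  idx
}

#' Annotate observed peptides with taxa via the branch rule
#'
#' Each observed peptide (possibly carrying missed cleavages) is split into
#' its fully tryptic, canonicalized, length-filtered subpeptides. Every
#' subpeptide is looked up in the index; within a subpeptide, the taxa of
#' its hits resolve by lowest common ancestor. Subpeptides without hits are
#' dropped. The per-subpeptide taxa then resolve to the peptide's assigned
#' taxon with [resolve_taxa()] under `broad_mode`: narrowest on one branch,
#' broadest across branches. A peptide whose subpeptides hit any human
#' protein is assigned `origin = "human"` and excluded from taxonomic
#' annotation (host-first rule); a peptide with no hits at all is
#' `origin = "unassigned"` with `NA` taxon.
#'
#' @param peptides Character vector of observed peptide sequences, or a data
#'   frame with a `peptide` column.
#' @param index A `peptide_index` from [build_peptide_index()].
#' @param tree A `taxonomy_tree`.
#' @param broad_mode Passed to [resolve_taxa()].
#' @param min_len,max_len Length filter applied to subpeptides.
#' @return Tibble with `peptide`, `origin`, `taxon_id`, `rank`, `lineage`.
#' @export
annotate_peptides <- function(peptides, index, tree,
                              broad_mode = c("lca", "literal_broadest"),
                              min_len = 5, max_len = 50) {
  broad_mode <- match.arg(broad_mode)
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  stopifnot(is.character(peptides))
  # index lookup table: canonical peptide -> list of (origin, taxon_id)
  idx_split <- split(seq_len(nrow(index)), index$peptide)
  annotate_one <- function(pep) {
    subs <- subpeptides_of(pep, min_len = min_len, max_len = max_len)
    if (!length(subs)) {
      return(tibble(peptide = pep, origin = "unassigned", taxon_id = NA_character_))
    }
    sub_taxa <- character(0)
    any_hit <- FALSE
    for (s in subs) {
      rows <- idx_split[[s]]
      if (is.null(rows)) next
      any_hit <- TRUE
      if (any(index$origin[rows] == "human")) {
        return(tibble(peptide = pep, origin = "human", taxon_id = NA_character_))
      }
      taxa <- unique(index$taxon_id[rows])
      taxa <- taxa[!is.na(taxa)]
      if (length(taxa)) {
        sub_taxa <- c(sub_taxa, resolve_taxa(tree, taxa, broad_mode = "lca"))
      }
    }
    if (!any_hit || !length(sub_taxa)) {
      return(tibble(peptide = pep, origin = "unassigned", taxon_id = NA_character_))
    }
    tibble(peptide = pep, origin = "microbial",
           taxon_id = resolve_taxa(tree, unique(sub_taxa), broad_mode = broad_mode))
  }
  out <- purrr::map_dfr(peptides, annotate_one)
  out$rank <- ifelse(is.na(out$taxon_id), NA_character_, unname(tree$rank[out$taxon_id]))
  out$lineage <- purrr::map_chr(out$taxon_id, function(t) {
    if (is.na(t)) NA_character_ else lineage_string(tree, t)
  })
  out
}
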