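#' Taxonomy trees and branch-rule taxon resolution
#'
#' A `taxonomy_tree` is a rooted, rank-labelled tree over taxon identifiers.
#' It supports lineage queries, single-branch tests and the narrowest/broadest
#' resolution rule used to assign a taxon to a peptide shared between
#' organisms: conflicting taxa on one root-to-leaf path resolve to the
#' narrowest (deepest) member; taxa on different branches resolve broadly,
#' either to their lowest common ancestor or to the literally shallowest
#' member.
#'
#' @name taxonomy
NULL

RANK_LEVELS <- c("superkingdom", "phylum", "class", "order", "family",
                 "genus", "species")

new_taxonomy_tree <- function(nodes, root_id) {
  nodes <- as_tibble(nodes)
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  rank <- setNames(nodes$rank, nodes$taxon_id)
  name <- setNames(nodes$name, nodes$taxon_id)
  # depth via iterative parent chase (root depth 0); also detects cycles
  depth <- setNames(rep(NA_integer_, nrow(nodes)), nodes$taxon_id)
  depth[root_id] <- 0L
  for (id in nodes$taxon_id) {
    if (!is.na(depth[id])) next
    chain <- character()
    cur <- id
    while (is.na(depth[cur])) {
      if (cur %in% chain) {
        abort_structure(paste0("cycle detected in taxonomy at node '", cur, "'"))
      }
      chain <- c(chain, cur)
      cur <- parent[[cur]]
      if (is.na(cur) || !cur %in% nodes$taxon_id) {
        abort_structure(paste0("orphan node: parent of '", chain[length(chain)],
                               "' is absent from the taxonomy"))
      }
    }
    d <- depth[[cur]]
    for (k in rev(seq_along(chain))) {
      d <- d + 1L
      depth[chain[k]] <- d
    }
  }
  structure(
    list(nodes = nodes, root_id = root_id, parent = parent,
         rank = rank, name = name, depth = depth),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", nrow(x$nodes), " nodes, root '", x$root_id,
      "', max depth ", max(x$depth), "\n", sep = "")
  print(dplyr::count(x$nodes, rank), ...)
  invisible(x)
}

validate_taxonomy <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) {
    abort_schema(paste("taxonomy table must have columns:", paste(req, collapse = ", ")))
  }
  nodes <- as_tibble(nodes)
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$taxon_id)) {
    abort_structure("duplicate taxon_id in taxonomy")
  }
  nodes$rank <- ifelse(nodes$rank %in% RANK_LEVELS, nodes$rank, "no_rank")
  roots <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  if (length(roots) != 1) {
    abort_structure(paste0("taxonomy must have exactly one root (parent_id == taxon_id); found ",
                           length(roots)))
  }
  missing_parent <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(missing_parent)) {
    bad <- nodes$taxon_id[nodes$parent_id %in% missing_parent]
    abort_structure(paste0("orphan node(s) with absent parent: ",
                           paste(head(bad, 5), collapse = ", ")))
  }
  tree <- new_taxonomy_tree(nodes, roots)
  # named ranks must not broaden with depth along any path
  idx <- match(tree$rank, RANK_LEVELS)  # NA for no_rank
  names(idx) <- names(tree$rank)
  for (id in nodes$taxon_id) {
    if (is.na(idx[id]) || id == tree$root_id) next
    anc <- tree$parent[[id]]
    while (TRUE) {
      if (!is.na(idx[anc]) && idx[anc] >= idx[id]) {
        abort_structure(paste0("rank inversion: '", id, "' (", tree$rank[[id]],
                               ") below '", anc, "' (", tree$rank[[anc]], ")"))
      }
      if (!is.na(idx[anc])) break
      if (anc == tree$root_id) break
      anc <- tree$parent[[anc]]
    }
  }
  tree
}

#' Load a taxonomy from disk
#'
#' Two dialects are supported: a flat four-column TSV
#' (`taxon_id`, `parent_id`, `rank`, `name`, header required) and the
#' NCBI-style dump pair `nodes.dmp`/`names.dmp` (pipe-and-tab delimited;
#' only `scientific name` rows of `names.dmp` are used). Ranks outside the
#' seven canonical levels are mapped to `no_rank`. The tree is validated:
#' exactly one root, no cycles, no orphans, no rank inversions.
#'
#' @param path For `flat_tsv`, the TSV file; for `ncbi_dump`, a directory
#'   containing `nodes.dmp` and `names.dmp`.
#' @param dialect `"flat_tsv"` or `"ncbi_dump"`.
#' @return A `taxonomy_tree`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("taxon_id\tparent_id\trank\tname",
#'              "1\t1\tno_rank\troot",
#'              "2\t1\tphylum\tBacillota",
#'              "3\t1\tphylum\tBacteroidota"), tf)
#' tr <- load_taxonomy(tf, "flat_tsv")
#' taxon_lineage(tr, "2")
load_taxonomy <- function(path, dialect = c("flat_tsv", "ncbi_dump")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_tsv") {
    nodes <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  } else {
    nodes_f <- file.path(path, "nodes.dmp")
    names_f <- file.path(path, "names.dmp")
    if (!file.exists(nodes_f) || !file.exists(names_f)) {
      abort_arg("ncbi_dump dialect needs nodes.dmp and names.dmp in `path`")
    }
    parse_dmp <- function(f) {
      lines <- readLines(f)
      lines <- sub("\t\\|$", "", lines)
      strsplit(lines, "\t\\|\t")
    }
    nd <- parse_dmp(nodes_f)
    nodes <- tibble(
      taxon_id = vapply(nd, `[`, "", 1),
      parent_id = vapply(nd, `[`, "", 2),
      rank = vapply(nd, `[`, "", 3)
    )
    nm <- parse_dmp(names_f)
    nm_tbl <- tibble(
      taxon_id = vapply(nm, `[`, "", 1),
      name = vapply(nm, `[`, "", 2),
      class = vapply(nm, function(x) x[length(x)], "")
    )
    nm_tbl <- nm_tbl[nm_tbl$class == "scientific name", c("taxon_id", "name")]
    nodes <- left_join(nodes, nm_tbl, by = "taxon_id")
    nodes$name <- nodes$name %na0% nodes$taxon_id
  }
  validate_taxonomy(nodes)
}

#' Build a taxonomy tree from an in-memory node table
#'
#' @param nodes Data frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name` (the root points at itself).
#' @return A validated `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) validate_taxonomy(nodes)

check_taxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0) abort_arg("`taxa` must be non-empty")
  unknown <- setdiff(taxa, tree$nodes$taxon_id)
  if (length(unknown)) {
    abort_lookup(paste0("unknown taxon_id: ", paste(unknown, collapse = ", ")))
  }
  taxa
}

#' Root-to-taxon lineage
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id Single taxon identifier.
#' @return Character vector of taxon ids starting at the root and ending at
#'   `taxon_id`.
#' @export
taxon_lineage <- function(tree, taxon_id) {
  taxon_id <- check_taxa(tree, taxon_id)[1]
  out <- taxon_id
  cur <- taxon_id
  while (cur != tree$root_id) {
    cur <- tree$parent[[cur]]
    out <- c(cur, out)
  }
  out
}

#' Node depth (root = 0)
#' @inheritParams taxon_lineage
#' @param taxa Character vector of taxon ids.
#' @return Integer depths named by taxon id.
#' @export
taxon_depth <- function(tree, taxa) {
  taxa <- check_taxa(tree, taxa)
  tree$depth[taxa]
}

#' Do a set of taxa lie on a single root-to-leaf branch?
#'
#' True iff the taxa are pairwise in ancestor-descendant relation, i.e. the
#' lineage of the deepest member contains every other member.
#'
#' @inheritParams taxon_depth
#' @return Logical scalar.
#' @export
is_single_branch <- function(tree, taxa) {
  taxa <- check_taxa(tree, taxa)
  if (length(taxa) == 1) return(TRUE)
  deepest <- taxa[which.max(tree$depth[taxa])]
  all(taxa %in% taxon_lineage(tree, deepest))
}

#' Lowest common ancestor of a taxon set
#'
#' @inheritParams taxon_depth
#' @return A single taxon id: the deepest node ancestral-or-equal to every
#'   member of `taxa`.
#' @export
lca_taxa <- function(tree, taxa) {
  taxa <- check_taxa(tree, taxa)
  common <- taxon_lineage(tree, taxa[1])
  for (t in taxa[-1]) common <- intersect(common, taxon_lineage(tree, t))
  common[length(common)]  # lineages are root-first, so last shared is deepest
}

# deterministic "smallest id": numeric comparison when all ids are numeric,
# lexicographic otherwise
id_first <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids[order(num)][1] else sort(ids)[1]
}

#' Resolve a set of conflicting taxa to a single taxon
#'
#' Implements the branch rule for shared peptides. A singleton resolves to
#' itself. Taxa on one branch resolve to the narrowest (deepest) member.
#' Taxa spread over different branches resolve broadly: `broad_mode = "lca"`
#' (default, the standard peptide-centric semantics) returns the lowest
#' common ancestor of the whole set; `broad_mode = "literal_broadest"`
#' returns the shallowest member itself, ties broken by smallest taxon id.
#'
#' @inheritParams taxon_depth
#' @param broad_mode `"lca"` or `"literal_broadest"`.
#' @return A single taxon id.
#' @export
resolve_taxa <- function(tree, taxa, broad_mode = c("lca", "literal_broadest")) {
  broad_mode <- match.arg(broad_mode)
  taxa <- check_taxa(tree, taxa)
  if (length(taxa) == 1) return(taxa)
  if (is_single_branch(tree, taxa)) {
    return(taxa[which.max(tree$depth[taxa])])
  }
  if (broad_mode == "lca") {
    lca_taxa(tree, taxa)
  } else {
    d <- tree$depth[taxa]
    shallowest <- taxa[d == min(d)]
    id_first(shallowest)
  }
}

#' Map a taxon up its lineage to a named rank
#'
#' `no_rank` nodes participate in lineages but are skipped when reporting at
#' a named rank; returns `NA` when the lineage has no node at the requested
#' rank.
#'
#' @inheritParams taxon_lineage
#' @param rank One of the seven canonical ranks.
#' @return Taxon id at `rank`, or `NA_character_`.
#' @export
taxon_at_rank <- function(tree, taxon_id, rank) {
  if (!rank %in% RANK_LEVELS) {
    abort_arg(paste0("unknown rank '", rank, "'"))
  }
  lin <- taxon_lineage(tree, taxon_id)
  hit <- lin[tree$rank[lin] == rank]
  if (length(hit)) hit[1] else NA_character_
}

#' Lineage as a readable string of names
#' @inheritParams taxon_lineage
#' @param sep Separator.
#' @return Single string, root first.
#' @export
lineage_string <- function(tree, taxon_id, sep = ";") {
  lin <- taxon_lineage(tree, taxon_id)
  paste(tree$name[lin], collapse = sep)
}
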