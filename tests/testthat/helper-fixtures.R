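# Shared fixtures and independent oracles. Oracles are deliberately naive
# (lineage intersection, window enumeration, hypergeometric summation,
# rank-assignment enumeration) and never call the code paths they check.

# A 20-node toy taxonomy mixing ranks and no_rank nodes.
toy_nodes <- function() {
  tibble::tribble(
    ~taxon_id, ~parent_id, ~rank, ~name,
    "1", "1", "no_rank", "root",
    "2", "1", "phylum", "P1",
    "3", "1", "phylum", "P2",
    "4", "2", "class", "C1",
    "5", "2", "no_rank", "X1",
    "6", "4", "order", "O1",
    "7", "6", "family", "F1",
    "8", "6", "family", "F2",
    "9", "7", "genus", "G1",
    "10", "7", "genus", "G2",
    "11", "9", "species", "S1",
    "12", "9", "species", "S2",
    "13", "10", "species", "S3",
    "14", "8", "genus", "G3",
    "15", "14", "species", "S4",
    "16", "3", "class", "C2",
    "17", "16", "order", "O2",
    "18", "17", "genus", "G4",
    "19", "18", "species", "S5",
    "20", "18", "species", "S6"
  )
}

toy_tree <- function() linguomics::taxonomy_tree(toy_nodes())

# naive lineage: chase parents on the raw node table
oracle_lineage <- function(nodes, id) {
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  out <- id
  while (out[1] != parent[[out[1]]]) out <- c(parent[[out[1]]], out)
  out
}

oracle_depth <- function(nodes, id) length(oracle_lineage(nodes, id)) - 1L

# single branch iff, sorted by depth, each taxon is an ancestor of the next
oracle_single_branch <- function(nodes, taxa) {
  taxa <- unique(taxa)
  taxa <- taxa[order(vapply(taxa, function(t) oracle_depth(nodes, t), 0L))]
  for (i in seq_len(length(taxa) - 1)) {
    if (!taxa[i] %in% oracle_lineage(nodes, taxa[i + 1])) return(FALSE)
  }
  TRUE
}

# LCA by pairwise lineage intersection
oracle_lca <- function(nodes, taxa) {
  lin <- oracle_lineage(nodes, taxa[1])
  for (t in taxa[-1]) lin <- intersect(lin, oracle_lineage(nodes, t))
  lin[length(lin)]
}

# narrowest/broadest rule applied literally from the oracles above
oracle_resolve <- function(nodes, taxa, broad_mode = "lca") {
  taxa <- unique(taxa)
  if (length(taxa) == 1) return(taxa)
  depths <- vapply(taxa, function(t) oracle_depth(nodes, t), 0L)
  if (oracle_single_branch(nodes, taxa)) return(taxa[which.max(depths)])
  if (broad_mode == "lca") return(oracle_lca(nodes, taxa))
  sh <- taxa[depths == min(depths)]
  sh[order(as.numeric(sh))][1]
}

# brute-force tryptic digestion: mark cleavage sites, emit all windows
# spanning <= max_missed sites
oracle_digest <- function(seq, max_missed, proline_rule = TRUE) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n]
  if (proline_rule) sites <- sites[res[sites + 1] != "P"]
  bounds <- c(0, sites, n)
  # windows emitted start-position first, then increasing length: the
  # documented fragment order
  frags <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in (i + 1):length(bounds)) {
      if (j - i - 1 > max_missed) break
      frags <- c(frags, substr(seq, bounds[i] + 1, bounds[j]))
    }
  }
  frags
}

# exhaustive two-sided rank-sum p by enumerating all group assignments
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combs <- utils::combn(n, length(x))
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# two-sided Fisher p by hypergeometric summation: P(X = x) summed over all
# x with point probability <= observed (with the standard relative epsilon)
oracle_fisher_p <- function(k, n, K, N) {
  xs <- max(0, n - (N - K)):min(n, K)
  probs <- stats::dhyper(xs, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_aa <- function(n, len = 30) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) paste(sample(aa, len, replace = TRUE), collapse = ""), "")
}

# small quant table builder: intensities is a features x samples matrix
quant_tbl <- function(intensities, origin = NULL, taxon_id = NULL,
                      cog = NULL, ko = NULL) {
  tbl <- tibble::tibble(feature_id = rownames(intensities))
  if (!is.null(origin)) tbl$origin <- origin
  if (!is.null(taxon_id)) tbl$taxon_id <- taxon_id
  if (!is.null(cog)) tbl$cog <- cog
  if (!is.null(ko)) tbl$ko <- ko
  dplyr::bind_cols(tbl, tibble::as_tibble(intensities))
}

meta_tbl <- function(samples, group, subject = NULL, stage = "none") {
  tibble::tibble(sample_id = samples,
                 subject_id = subject %||% samples,
                 center = "test", group = group, stage = stage,
                 timepoint = 0, replicate = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
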