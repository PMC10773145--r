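test_that("tryptic digestion follows the K/R rule with proline suppression", {
  expect_equal(tryptic_digest("MAGICKDEPTHRGAIN", 0),
               c("MAGICK", "DEPTHR", "GAIN"))
  expect_equal(tryptic_digest("MAGICKPDEF", 0), c("MAGICKPDEF"))
  expect_equal(tryptic_digest("MAGICKPDEF", 0, proline_rule = FALSE),
               c("MAGICK", "PDEF"))
  # terminal K does not open an empty fragment
  expect_equal(tryptic_digest("AAAK", 0), "AAAK")
  expect_error(tryptic_digest("PEPTIDEB", 0), class = "linguomics_validation_error")
  expect_error(tryptic_digest("PEPTIDEB", 0), "B")
})

test_that("digestion equals the brute-force window enumerator on random 30-mers", {
  set.seed(11)
  seqs <- random_aa(200, 30)
  for (mm in 0:2) {
    for (s in seqs) {
      expect_identical(tryptic_digest(s, mm), oracle_digest(s, mm), info = s)
    }
  }
})

test_that("missed-cleavage sets are nested: k adds exactly the k-site windows", {
  set.seed(12)
  for (s in random_aa(30, 40)) {
    f0 <- tryptic_digest(s, 0)
    f1 <- tryptic_digest(s, 1)
    f2 <- tryptic_digest(s, 2)
    expect_true(all(f0 %in% f1) && all(f1 %in% f2))
    # the k-level set is exactly the (k-1)-level set plus the k-site windows
    expect_setequal(setdiff(f1, f0), setdiff(oracle_digest(s, 1), oracle_digest(s, 0)))
    expect_setequal(setdiff(f2, f1), setdiff(oracle_digest(s, 2), oracle_digest(s, 1)))
  }
})

test_that("canonicalization rewrites L as I and enforces the 5-50 length window", {
  expect_equal(canonicalize_peptides("PEPTLDEK"), "PEPTIDEK")
  expect_equal(canonicalize_peptides("GHIK"), character(0))         # length 4
  len5 <- "AAAAK"; len50 <- paste0(strrep("A", 49), "K")
  expect_equal(canonicalize_peptides(c(len5, len50)), c(len5, len50))
  expect_equal(canonicalize_peptides(strrep("A", 51)), character(0))
  # idempotence
  x <- canonicalize_peptides(c("PEPTLDEK", "ILLIK"))
  expect_equal(canonicalize_peptides(x), x)
})

make_fasta <- function(records, path) {
  writeLines(unlist(purrr::map2(records$header, records$seq,
                                ~c(paste0(">", .x), .y))), path)
  path
}

test_that("peptide index partitions origins and tracks shared peptides", {
  dir <- withr::local_tempdir()
  hum <- make_fasta(tibble::tibble(
    header = "sp|HKER1|KRT_HUMAN keratin",
    seq = "MMMMMKWWWWWWK"), file.path(dir, "h.fasta"))
  mic <- make_fasta(tibble::tibble(
    header = c("MA001 taxid=11 species one", "MA002 taxid=12 species two"),
    seq = c("AAAAAKCCCCCK", "AAAAAKDDDDDK")), file.path(dir, "m.fasta"))
  idx <- build_peptide_index(tibble::tibble(path = c(hum, mic),
                                            origin = c("human", "microbial")),
                             max_missed = 0)
  expect_setequal(unique(idx$origin), c("human", "microbial"))
  expect_true(all(is.na(idx$taxon_id[idx$origin == "human"])))
  shared <- idx[idx$peptide == "AAAAAK", ]
  expect_equal(sort(shared$taxon_id), c("11", "12"))
  # no key is shared across origins in this construction
  both <- table(idx$peptide, idx$origin)
  expect_true(all(rowSums(both > 0) == 1))
})

test_that("index key set equals per-protein digestion union on a toy database", {
  set.seed(21)
  prot <- tibble::tibble(
    accession = sprintf("T%02d", 1:10),
    origin = "microbial",
    taxon_id = as.character(11:20),
    sequence = random_aa(10, 60)
  )
  idx <- build_peptide_index(prot, max_missed = 2)
  expected <- unique(unlist(lapply(prot$sequence, function(s) {
    unique(canonicalize_peptides(oracle_digest(s, 2)))
  })))
  expect_setequal(unique(idx$peptide), expected)
})

test_that("header and collision handling", {
  dir <- withr::local_tempdir()
  bad <- make_fasta(tibble::tibble(header = "MA009 no taxon here", seq = "AAAAAK"),
                    file.path(dir, "bad.fasta"))
  expect_error(read_protein_fasta(bad, origin = "microbial"),
               class = "linguomics_header_error")
  dup <- tibble::tibble(accession = c("X1", "X1"), origin = "microbial",
                        taxon_id = c("11", "12"),
                        sequence = c("AAAAAKCCCCCK", "AAAAAKDDDDDK"))
  expect_warning(idx <- build_peptide_index(dup, max_missed = 0),
                 class = "linguomics_collision_warning")
  expect_true(all(idx$taxon_id == "11"))
})

test_that("peptide annotation applies the branch rule over subpeptide hits", {
  tr <- toy_tree()
  # proteins from species 11 and 13 (sibling genera under family 7) and a
  # genus-level protein at 9; a human protein shares one peptide
  idx <- dplyr::bind_rows(
    tibble::tibble(peptide = "AAAAAK", accession = "M1", origin = "microbial", taxon_id = "11"),
    tibble::tibble(peptide = "CCCCCK", accession = "M1", origin = "microbial", taxon_id = "11"),
    tibble::tibble(peptide = "DDDDDK", accession = "M2", origin = "microbial", taxon_id = "9"),
    tibble::tibble(peptide = "EEEEEK", accession = "M3", origin = "microbial", taxon_id = "13"),
    tibble::tibble(peptide = "WWWWWK", accession = "H1", origin = "human", taxon_id = NA)
  )
  class(idx) <- c("peptide_index", class(idx))
  # consensus species: both subpeptides hit species 11
  out <- annotate_peptides("AAAAAKCCCCCK", idx, tr)
  expect_equal(out$taxon_id, "11")
  expect_equal(out$rank, "species")
  # same branch (species 11, genus 9) -> narrowest = species
  out <- annotate_peptides("AAAAAKDDDDDK", idx, tr)
  expect_equal(out$taxon_id, "11")
  # different branches (11 vs 13) -> lca = family 7
  out <- annotate_peptides("AAAAAKEEEEEK", idx, tr)
  expect_equal(out$taxon_id, "7")
  expect_equal(out$origin, "microbial")
  # literal broadest keeps a member, tie broken by id
  out <- annotate_peptides("AAAAAKEEEEEK", idx, tr, broad_mode = "literal_broadest")
  expect_equal(out$taxon_id, "11")
  # host-first rule: any human hit wins
  out <- annotate_peptides("WWWWWKAAAAAK", idx, tr)
  expect_equal(out$origin, "human")
  expect_true(is.na(out$taxon_id))
  # zero-hit subpeptides are ignored, not vetoing
  out <- annotate_peptides("GGGGGKAAAAAK", idx, tr)
  expect_equal(out$taxon_id, "11")
  # nothing matches at all
  out <- annotate_peptides("GGGGGKHHHHHK", idx, tr)
  expect_equal(out$origin, "unassigned")
})

test_that("proteotypic peptides recover their source species end to end", {
  cfg <- generator_config(seed = 5, n_phyla = 2, genera_per_phylum = 2,
                          species_per_genus = 2, proteins_per_species = 3,
                          human_proteins = 3)
  ref <- generate_reference(cfg)
  idx <- build_peptide_index(ref$proteins, max_missed = 2)
  # fully tryptic peptides hitting exactly one microbial protein: these are
  # proteotypic and survive annotation's own subpeptide filter unchanged
  counts <- table(idx$peptide)
  proto <- idx[idx$peptide %in% names(counts)[counts == 1] &
                 idx$origin == "microbial", ]
  tryptic <- vapply(proto$peptide,
                    function(p) length(tryptic_digest(p, 0)) == 1, TRUE)
  proto <- proto[tryptic, ]
  set.seed(6)
  proto <- proto[sample.int(nrow(proto), min(40, nrow(proto))), ]
  ann <- annotate_peptides(proto$peptide, idx, ref$taxonomy)
  expect_equal(ann$taxon_id, proto$taxon_id[match(ann$peptide, proto$peptide)])
})
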