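#' Synthetic tongue-coating cohorts with known ground truth
#'
#' The generator builds a toy taxonomy, taxon-labelled protein databases,
#' cohort metadata mirroring the study designs (a time-series cohort of 5
#' subjects x 4 timepoints x 3 replicates with one subject missing the
#' final timepoint; a 120 cancer / 120 non-cancer single-center cohort; a
#' 60/60 three-center cohort) and log-normal intensity matrices with
#' subject-level random effects (intra-subject correlation above
#' inter-subject), planted differential proteins, a planted risk species
#' tied to outcome through a logistic link, and planted discriminative
#' features. Every planted effect is recorded in a truth ledger so
#' downstream recovery tests never re-derive ground truth from
#' regeneration.
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' Defaults encode the emulated study conditions: a 9:1 microbial:human
#' protein count ratio (~4:1 at peptide level), log-normal intensities with
#' origin-specific subject effects making microbial profiles stable within
#' and variable between subjects, planted 4-fold differential proteins, one
#' risk species with odds ratio 3 on the standardized log-abundance scale,
#' and 10 discriminative microbial proteins at a strong effect size.
#'
#' @param seed Integer master seed; all stages derive from it.
#' @param n_phyla,genera_per_phylum,species_per_genus Taxonomy shape
#'   (default 5 x 2 x 3 = 30 species).
#' @param proteins_per_species Microbial proteins per species (default 45,
#'   giving 1350 microbial proteins).
#' @param human_proteins Human protein count (default 150; ratio 9:1).
#' @param protein_length Length range of generated sequences.
#' @param cog_vocab,ko_vocab Sizes of the COG / KO vocabularies.
#' @param peptides_per_protein Named vector: synthetic peptide features per
#'   protein (human 16, microbial 7 keeps the ~4:1 peptide ratio).
#' @param base_log2_mean,base_log2_sd Feature baseline abundance (log2).
#' @param subject_sd Named vector: subject-level random effect sd (log2).
#' @param resid_sd Named vector: residual noise sd (log2).
#' @param missingness Missing-at-random masking rate.
#' @param n_dep_human,n_dep_microbial,dep_log2fc Planted differential
#'   proteins (half up, half down, at `dep_log2fc`).
#' @param risk_or Planted risk species odds ratio (on the z-scored log2
#'   abundance scale used by [species_risk()]); `NULL` disables.
#' @param risk_feature_sd Subject/residual sd override for the risk
#'   species' proteins, keeping its aggregate abundance cleanly measurable.
#' @param n_discriminative,discriminative_lfc Planted discriminative
#'   microbial proteins and their log2 shift in cancer.
#' @param stage_scale Named vector: multiplier of the discriminative shift
#'   for stage I-II and III-IV cancer samples.
#' @param gastritis_scale Fraction of the discriminative shift leaked into
#'   gastritis (non-cancer) samples.
#' @param couple_krt_cog Plant one latent factor shared by two human
#'   keratin-like proteins and every protein of one COG, so the
#'   (keratin, COG) pair leads the host-microbe correlation ranking.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_phyla = 5, genera_per_phylum = 2,
                             species_per_genus = 3,
                             proteins_per_species = 45,
                             human_proteins = 150,
                             protein_length = c(80, 400),
                             cog_vocab = 120, ko_vocab = 120,
                             peptides_per_protein = c(human = 16, microbial = 7),
                             base_log2_mean = 20, base_log2_sd = 2,
                             subject_sd = c(human = 0.25, microbial = 1.0),
                             resid_sd = c(human = 0.25, microbial = 0.5),
                             missingness = 0.1,
                             n_dep_human = 6, n_dep_microbial = 14,
                             dep_log2fc = 2,
                             risk_or = 3, risk_feature_sd = 0.15,
                             n_discriminative = 10, discriminative_lfc = 1.5,
                             stage_scale = c(I_II = 1, III_IV = 1.25),
                             gastritis_scale = 0.3,
                             couple_krt_cog = TRUE) {
  cfg <- as.list(environment())
  counts <- c(n_phyla, genera_per_phylum, species_per_genus,
              proteins_per_species, human_proteins)
  if (any(counts <= 0)) abort_arg("all generator counts must be positive")
  if (missingness < 0 || missingness >= 1) abort_arg("missingness must lie in [0, 1)")
  structure(cfg, class = "generator_config")
}

#' Generate the synthetic reference: taxonomy, databases, annotations
#'
#' @param config A [generator_config()].
#' @return List with `taxonomy` (a `taxonomy_tree`), `proteins` (tibble:
#'   `accession`, `origin`, `taxon_id`, `desc`, `sequence`), `annotations`
#'   (tibble: `accession`, `cog`, `ko`) and `species` (leaf taxon ids).
#' @export
generate_reference <- function(config = generator_config()) {
  with_seed(derive_seed(config$seed, "reference"), {
    # taxonomy: root (superkingdom) > phylum > genus > species
    nodes <- tibble(taxon_id = "1", parent_id = "1",
                    rank = "superkingdom", name = "Bacteria")
    nid <- 1L
    species <- character(0)
    for (p in seq_len(config$n_phyla)) {
      nid <- nid + 1L; pid <- as.character(nid)
      nodes <- bind_rows(nodes, tibble(taxon_id = pid, parent_id = "1",
                                       rank = "phylum",
                                       name = sprintf("Phylum_%02d", p)))
      for (g in seq_len(config$genera_per_phylum)) {
        nid <- nid + 1L; gid <- as.character(nid)
        nodes <- bind_rows(nodes, tibble(taxon_id = gid, parent_id = pid,
                                         rank = "genus",
                                         name = sprintf("Genus_%02d_%02d", p, g)))
        for (s in seq_len(config$species_per_genus)) {
          nid <- nid + 1L; sid <- as.character(nid)
          nodes <- bind_rows(nodes, tibble(taxon_id = sid, parent_id = gid,
                                           rank = "species",
                                           name = sprintf("Species_%02d_%02d_%02d", p, g, s)))
          species <- c(species, sid)
        }
      }
    }
    tree <- taxonomy_tree(nodes)
    rand_seq <- function(n) {
      vapply(n, function(len) paste(sample(AA20, len, replace = TRUE),
                                    collapse = ""), "")
    }
    n_mic <- length(species) * config$proteins_per_species
    mic_len <- sample(config$protein_length[1]:config$protein_length[2],
                      n_mic, replace = TRUE)
    mic <- tibble(
      accession = sprintf("MP%05d", seq_len(n_mic)),
      origin = "microbial",
      taxon_id = rep(species, each = config$proteins_per_species),
      sequence = rand_seq(mic_len)
    )
    mic$desc <- sprintf("%s taxid=%s %s protein", mic$accession, mic$taxon_id,
                        tree$name[mic$taxon_id])
    hum_len <- sample(config$protein_length[1]:config$protein_length[2],
                      config$human_proteins, replace = TRUE)
    hum <- tibble(
      accession = sprintf("HP%05d", seq_len(config$human_proteins)),
      origin = "human",
      taxon_id = NA_character_,
      sequence = rand_seq(hum_len)
    )
    hum$desc <- sprintf("sp|%s|%s_HUMAN human protein", hum$accession, hum$accession)
    proteins <- bind_rows(hum, mic)
    annotations <- tibble(
      accession = mic$accession,
      cog = sprintf("COG%04d", sample.int(config$cog_vocab, n_mic, replace = TRUE)),
      ko = sprintf("K%05d", sample.int(config$ko_vocab, n_mic, replace = TRUE))
    )
    list(taxonomy = tree, proteins = proteins, annotations = annotations,
         species = species)
  })
}

#' Generate cohort metadata for one of the study designs
#'
#' `time_series`: 5 healthy subjects sampled on days 0/3/6/9 in triplicate,
#' subject 5 absent at day 9 (57 samples). `zjc_like`: 120 cancer (stages
#' I-IV, 30 each) and 120 non-cancer (90 healthy, 30 gastritis) subjects,
#' one sample each, single center. `multicenter_like`: 60 cancer / 60
#' non-cancer over three centers. Layout is deterministic; `seed` is kept
#' for interface stability.
#'
#' @param design One of `"time_series"`, `"zjc_like"`, `"multicenter_like"`.
#' @param seed Unused placeholder (layouts are deterministic).
#' @return Metadata tibble: `sample_id`, `subject_id`, `center`, `group`,
#'   `stage`, `timepoint`, `replicate`.
#' @export
generate_cohort <- function(design = c("time_series", "zjc_like", "multicenter_like"),
                            seed = 1L) {
  design <- match.arg(design)
  if (design == "time_series") {
    grid <- tidyr::expand_grid(subject = sprintf("TS%02d", 1:5),
                               timepoint = c(0, 3, 6, 9), replicate = 1:3)
    grid <- grid[!(grid$subject == "TS05" & grid$timepoint == 9), ]
    return(tibble(
      sample_id = sprintf("%s_d%d_r%d", grid$subject, grid$timepoint, grid$replicate),
      subject_id = grid$subject, center = "time_series", group = "non_cancer",
      stage = "none", timepoint = grid$timepoint, replicate = grid$replicate
    ))
  }
  if (design == "zjc_like") {
    subj <- sprintf("ZJ%03d", 1:240)
    group <- rep(c("cancer", "non_cancer"), each = 120)
    stage <- c(rep(c("I", "II", "III", "IV"), each = 30),
               rep("none", 90), rep("gastritis", 30))
    center <- "ZJC"
  } else {
    centers <- c("WZ", "ZJT", "SCC")
    subj <- sprintf("MC%03d", 1:120)
    group <- rep(rep(c("cancer", "non_cancer"), each = 20), times = 3)
    stage <- rep(c(rep(c("I", "II", "III", "IV"), each = 5),
                   rep("none", 15), rep("gastritis", 5)), times = 3)
    center <- rep(centers, each = 40)
  }
  tibble(sample_id = paste0(subj, "_s1"), subject_id = subj, center = center,
         group = group, stage = stage, timepoint = 0, replicate = 1L)
}

# Solve the latent class shift delta so that the logistic slope on the
# z-scored exposure equals log(or): with exposure ~ N(0,1) in controls and
# N(delta,1) in cases (equal mix), slope on raw scale is delta and the
# cohort sd is sqrt(1 + delta^2/4).
risk_delta_for_or <- function(or) {
  target <- log(or)
  stats::uniroot(function(d) d * sqrt(1 + d^2 / 4) - target,
                 c(1e-6, 10))$root
}

#' Simulate intensity matrices over a cohort
#'
#' Log-normal feature intensities with origin-specific subject-level random
#' effects and residual noise, planted group effects on the log2 scale, a
#' planted risk species whose per-subject abundance shift follows the
#' normal-discriminant equivalent of a logistic link at the configured odds
#' ratio, an optional keratin-COG coupling factor, and missing-at-random
#' masking (the risk species' proteins are exempt so its planted odds ratio
#' survives aggregation). Which features carry planted effects is drawn from
#' a seed derived from the config alone, so all cohorts simulated from one
#' reference share the same planted features; the intensity noise uses
#' `seed` (or a derived default). Deterministic for a fixed config seed.
#'
#' @param reference Output of [generate_reference()].
#' @param meta Cohort metadata (any tibble with `sample_id`, `subject_id`,
#'   `group`, `stage`).
#' @param config A [generator_config()].
#' @param include_peptides Also simulate the peptide-level table?
#' @param seed Optional override of the intensity-stage seed.
#' @return List with `protein` (quant tibble), `peptide` (quant tibble or
#'   `NULL`) and `truth` (ledger list: `planted_deps`, `risk`,
#'   `discriminative`, `coupled`, `delta`).
#' @export
simulate_intensities <- function(reference, meta, config = generator_config(),
                                 include_peptides = TRUE, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, "intensities")
  meta <- as_tibble(meta)
  if (!"stage" %in% names(meta)) meta$stage <- "none"
  prot <- left_join(reference$proteins, reference$annotations, by = "accession")
  nfeat <- nrow(prot)
  samples <- meta$sample_id
  subjects <- unique(meta$subject_id)
  subj_idx <- match(meta$subject_id, subjects)
  is_cancer <- meta$group == "cancer"

  # planted-feature selection is a property of (config, reference), drawn
  # under a seed derived from the config alone, so every cohort simulated
  # from the same reference shares the same planted features
  risk_rows <- integer(0)
  risk <- NULL
  delta <- NULL
  if (!is.null(config$risk_or)) {
    risk_taxon <- reference$species[1]
    risk_rows <- which(!is.na(prot$taxon_id) & prot$taxon_id == risk_taxon)
    delta <- risk_delta_for_or(config$risk_or)
    risk <- tibble(taxon_id = risk_taxon, true_or = config$risk_or,
                   delta = delta)
  }
  plant <- with_seed(derive_seed(config$seed, "planting"), {
    hum_pool <- which(prot$origin == "human")
    mic_pool <- setdiff(which(prot$origin == "microbial"), risk_rows)
    dep_rows <- c(sample(hum_pool, min(config$n_dep_human, length(hum_pool))),
                  sample(mic_pool, min(config$n_dep_microbial, length(mic_pool))))
    disc_pool <- setdiff(mic_pool, dep_rows)
    disc_rows <- sample(disc_pool, min(config$n_discriminative, length(disc_pool)))
    krt_rows <- integer(0)
    cog_star <- NULL
    if (isTRUE(config$couple_krt_cog) && length(setdiff(hum_pool, dep_rows)) >= 2) {
      krt_rows <- setdiff(hum_pool, dep_rows)[1:2]
      cog_star <- names(sort(table(prot$cog), decreasing = TRUE))[1]
    }
    list(dep_rows = dep_rows, disc_rows = disc_rows,
         krt_rows = krt_rows, cog_star = cog_star)
  })
  dep_rows <- plant$dep_rows
  dep_sign <- rep(c(1, -1), length.out = length(dep_rows))
  planted_deps <- tibble(feature_id = prot$accession[dep_rows],
                         origin = prot$origin[dep_rows],
                         log2fc = dep_sign * config$dep_log2fc)
  disc_rows <- plant$disc_rows
  disc_sign <- rep(c(1, -1), length.out = length(disc_rows))
  discriminative <- tibble(feature_id = prot$accession[disc_rows],
                           log2fc = disc_sign * config$discriminative_lfc)
  coupled <- NULL
  couple_rows <- integer(0)
  if (length(plant$krt_rows)) {
    cog_rows <- which(!is.na(prot$cog) & prot$cog == plant$cog_star)
    couple_rows <- union(plant$krt_rows, setdiff(cog_rows, c(dep_rows, disc_rows)))
    coupled <- list(human = prot$accession[plant$krt_rows], cog = plant$cog_star)
  }

  with_seed(seed, {
    mu <- rnorm(nfeat, config$base_log2_mean, config$base_log2_sd)
    sub_sd <- unname(config$subject_sd[prot$origin])
    res_sd <- unname(config$resid_sd[prot$origin])
    z_subj <- NULL
    if (length(risk_rows)) {
      sub_sd[risk_rows] <- config$risk_feature_sd
      res_sd[risk_rows] <- config$risk_feature_sd
      subj_cancer <- vapply(subjects, function(s) {
        any(is_cancer[meta$subject_id == s])
      }, TRUE)
      z_subj <- rnorm(length(subjects)) + delta * subj_cancer
    }
    f_subj <- if (length(couple_rows)) rnorm(length(subjects), sd = 1.5) else NULL

    # assemble log2 intensity matrix: samples x features
    n <- length(samples)
    U <- matrix(rnorm(length(subjects) * nfeat), length(subjects), nfeat) *
      rep(sub_sd, each = length(subjects))
    E <- matrix(rnorm(n * nfeat), n, nfeat) * rep(res_sd, each = n)
    Y <- matrix(mu, n, nfeat, byrow = TRUE) + U[subj_idx, , drop = FALSE] + E
    if (length(risk_rows)) {
      Y[, risk_rows] <- Y[, risk_rows] + z_subj[subj_idx]
    }
    stage_mult <- dplyr::case_when(
      is_cancer & meta$stage %in% c("I", "II") ~ unname(config$stage_scale["I_II"]),
      is_cancer & meta$stage %in% c("III", "IV") ~ unname(config$stage_scale["III_IV"]),
      is_cancer ~ 1,
      meta$stage == "gastritis" ~ config$gastritis_scale,
      TRUE ~ 0
    )
    if (length(dep_rows) && any(is_cancer)) {
      Y[is_cancer, dep_rows] <- Y[is_cancer, dep_rows] +
        matrix(planted_deps$log2fc, sum(is_cancer), length(dep_rows), byrow = TRUE)
    }
    if (length(disc_rows)) {
      Y[, disc_rows] <- Y[, disc_rows] +
        outer(stage_mult, discriminative$log2fc)
    }
    if (length(couple_rows)) {
      Y[, couple_rows] <- Y[, couple_rows] + f_subj[subj_idx]
    }
    I <- 2^Y
    mask <- matrix(runif(n * nfeat) < config$missingness, n, nfeat)
    # the planted risk species stays fully identified: masking a dominant
    # member protein would add heavy-tailed noise to the species aggregate
    # and attenuate its odds ratio below the planted value
    if (length(risk_rows)) mask[, risk_rows] <- FALSE
    I[mask] <- NA_real_
    protein_tbl <- bind_cols(
      tibble(feature_id = prot$accession, origin = prot$origin,
             taxon_id = prot$taxon_id, cog = prot$cog, ko = prot$ko),
      as_tibble(t(I), .name_repair = ~samples)
    )

    peptide_tbl <- NULL
    if (include_peptides) {
      k <- unname(config$peptides_per_protein[prot$origin])
      pep_of <- rep(seq_len(nfeat), times = k)
      pep_id <- paste0(rep(prot$accession, times = k), "_pep",
                       unlist(lapply(k, seq_len)))
      off <- rnorm(length(pep_of), -3, 1)
      P <- Y[, pep_of, drop = FALSE] +
        matrix(off, n, length(pep_of), byrow = TRUE) +
        matrix(rnorm(n * length(pep_of), sd = 0.2), n, length(pep_of))
      PI <- 2^P
      PI[matrix(runif(length(PI)) < config$missingness, nrow(PI), ncol(PI))] <- NA_real_
      peptide_tbl <- bind_cols(
        tibble(feature_id = pep_id, origin = prot$origin[pep_of],
               taxon_id = prot$taxon_id[pep_of]),
        as_tibble(t(PI), .name_repair = ~samples)
      )
    }
    list(protein = protein_tbl, peptide = peptide_tbl,
         truth = list(planted_deps = planted_deps, risk = risk,
                      discriminative = discriminative, coupled = coupled,
                      delta = delta))
  })
}

#' Emit mock PSM tables for the database-reduction workflow
#'
#' For each run, a subset of database proteins is "confidently identified":
#' each contributes 1-3 fully tryptic peptides with q-values below the FDR
#' cutoff. A set of decoy rows pointing at other proteins carries q-values
#' above the cutoff, so the reduction step has something to reject. The
#' truly sampled accessions per run are returned as ground truth.
#'
#' @param reference Output of [generate_reference()].
#' @param n_runs Number of runs (default 4, one per sampled patient group).
#' @param proteins_per_run Confident proteins per run.
#' @param decoys_per_run High-q rows per run.
#' @param seed Seed (default derived from nothing: pass explicitly for
#'   reproducibility).
#' @return List with `psms` (tibble: `run`, `peptide`, `proteins`,
#'   `q_value`) and `sampled` (named list of truly sampled accessions).
#' @export
simulate_psms <- function(reference, n_runs = 4, proteins_per_run = 80,
                          decoys_per_run = 40, seed = 1L) {
  prot <- reference$proteins
  proteins_per_run <- min(proteins_per_run, nrow(prot) - 1)
  decoys_per_run <- min(decoys_per_run, nrow(prot) - proteins_per_run)
  with_seed(seed, {
    runs <- sprintf("run%02d", seq_len(n_runs))
    out <- purrr::map(runs, function(r) {
      picked <- sample(prot$accession, proteins_per_run)
      rows <- purrr::map_dfr(picked, function(acc) {
        seqc <- prot$sequence[prot$accession == acc]
        peps <- canonicalize_peptides(tryptic_digest(seqc, 0))
        if (!length(peps)) peps <- substr(seqc, 1, 8)
        peps <- head(peps, sample(1:3, 1))
        tibble(run = r, peptide = peps, proteins = acc,
               q_value = runif(length(peps), 0, 0.009))
      })
      others <- sample(setdiff(prot$accession, picked), decoys_per_run)
      decoys <- tibble(run = r,
                       peptide = paste0("DECOYPEPTIDE", seq_along(others), "K"),
                       proteins = others,
                       q_value = runif(length(others), 0.02, 0.5))
      list(psms = bind_rows(rows, decoys), sampled = picked)
    })
    list(psms = bind_rows(purrr::map(out, "psms")),
         sampled = setNames(purrr::map(out, "sampled"), runs))
  })
}

#' Write a full simulation to disk
#'
#' Writes the microbial and human FASTA databases, the flat taxonomy TSV,
#' annotation TSV, cohort metadata TSV, wide quant TSVs, PSM TSV and the
#' truth ledger JSON into `dir`.
#'
#' @param reference Output of [generate_reference()].
#' @param meta Cohort metadata.
#' @param sim Output of [simulate_intensities()].
#' @param psms Output of [simulate_psms()] (optional).
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(reference, meta, sim, psms = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    taxonomy = file.path(dir, "taxonomy.tsv"),
    microbial_fasta = file.path(dir, "microbial.fasta"),
    human_fasta = file.path(dir, "human.fasta"),
    annotations = file.path(dir, "annotations.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    protein_quant = file.path(dir, "protein_quant.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(reference$taxonomy$nodes, paths["taxonomy"], progress = FALSE)
  mic <- reference$proteins[reference$proteins$origin == "microbial", ]
  hum <- reference$proteins[reference$proteins$origin == "human", ]
  write_protein_fasta(mic, paths["microbial_fasta"])
  write_protein_fasta(hum, paths["human_fasta"])
  readr::write_tsv(reference$annotations, paths["annotations"], progress = FALSE)
  readr::write_tsv(meta, paths["metadata"], progress = FALSE)
  write_quant_table(sim$protein, paths["protein_quant"])
  if (!is.null(sim$peptide)) {
    paths["peptide_quant"] <- file.path(dir, "peptide_quant.tsv")
    write_quant_table(sim$peptide, paths["peptide_quant"])
  }
  if (!is.null(psms)) {
    paths["psms"] <- file.path(dir, "psms.tsv")
    readr::write_tsv(psms$psms, paths["psms"], progress = FALSE)
    paths["sampled"] <- file.path(dir, "psm_sampled.json")
    jsonlite::write_json(psms$sampled, paths["sampled"], auto_unbox = FALSE)
  }
  truth <- sim$truth
  truth$coupled <- truth$coupled %||% NULL
  jsonlite::write_json(
    list(planted_deps = truth$planted_deps, risk = truth$risk,
         discriminative = truth$discriminative,
         coupled = truth$coupled, delta = truth$delta),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
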