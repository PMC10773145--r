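#' End-to-end synthetic pipeline orchestration
#'
#' `run_pipeline()` executes the stages of the tongue-coating analysis in
#' dependency order on a fully synthetic dataset: simulate -> reduce-db ->
#' annotate -> quantify/qc -> stability -> differential/enrichment/risk ->
#' train/evaluate -> embed. Each stage writes its outputs under the output
#' directory and the run ends with a manifest (seeds, package version,
#' per-stage timings and output file hashes). A rerun with the same config
#' reproduces all deterministic outputs byte-identically.
#'
#' @name pipeline
NULL

PIPELINE_STAGES <- c("simulate", "reduce_db", "annotate", "quantify",
                     "stability", "differential", "risk", "model", "embed")

#' Pipeline configuration
#'
#' Consolidates every stage parameter. Analysis thresholds default to the
#' study values (peptide length 5-50, q cutoff 0.01, |log2FC| > 1,
#' alpha 0.05); the QC identification thresholds are scaled to the size of
#' the synthetic databases (the study's 800/2000 thresholds assume its
#' ~1.4k/13.8k protein databases and remain the defaults of [qc_filter()]).
#'
#' @param outdir Output directory.
#' @param seed Global seed; per-stage seeds derive from it by label hash.
#' @param stages Stages to run (subset of the full ordered list).
#' @param generator A [generator_config()] (defaults to
#'   `generator_config(seed = seed)`).
#' @param model A [model_config()].
#' @param qc_min_human,qc_min_microbial QC thresholds for the synthetic
#'   scale.
#' @param q_cutoff PSM q-value cutoff for database reduction.
#' @param lfc_threshold,alpha,adjust Differential-analysis parameters.
#' @param annotate_n_peptides Number of observed peptides run through
#'   taxonomic annotation in the annotate stage.
#' @param index_max_missed Missed cleavages in the peptide index.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("linguomics_run_"), seed = 1L,
                            stages = PIPELINE_STAGES,
                            generator = NULL, model = model_config(seed = seed),
                            qc_min_human = 100, qc_min_microbial = 1000,
                            q_cutoff = 0.01, lfc_threshold = 1, alpha = 0.05,
                            adjust = "none", annotate_n_peptides = 200,
                            index_max_missed = 2) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) abort_arg(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(list(
    outdir = outdir, seed = as.integer(seed), stages = stages,
    generator = generator %||% generator_config(seed = seed),
    model = model, qc_min_human = qc_min_human,
    qc_min_microbial = qc_min_microbial, q_cutoff = q_cutoff,
    lfc_threshold = lfc_threshold, alpha = alpha, adjust = adjust,
    annotate_n_peptides = annotate_n_peptides,
    index_max_missed = index_max_missed
  ), class = "pipeline_config")
}

need_stage <- function(state, what, needed_by) {
  if (is.null(state[[what]])) {
    abort(paste0("stage '", needed_by, "' needs the output of stage '",
                 what, "', which did not run"),
          class = "linguomics_ordering_error")
  }
}

write_stage_tsv <- function(x, dir, name) {
  p <- file.path(dir, name)
  readr::write_tsv(x, p, progress = FALSE)
  p
}

#' Run the synthetic end-to-end pipeline
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly also written to
#'   `manifest.json`. The in-memory stage state is attached as
#'   `attr(, "state")` for interactive inspection.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list(package_version = as.character(utils::packageVersion("linguomics")),
                   seed = config$seed, stages = list())
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    outputs <- fn()
    secs <- proc.time()[["elapsed"]] - t0
    hashes <- tools::md5sum(unlist(outputs))
    manifest$stages[[name]] <<- list(
      outputs = as.list(unname(unlist(outputs))),
      md5 = as.list(unname(hashes)),
      seconds = round(secs, 2)
    )
    inform(sprintf("[linguomics] stage %-12s %6.1fs  %d output(s)",
                   name, secs, length(hashes)))
  }

  run_stage("simulate", function() {
    gen <- config$generator
    state$reference <- generate_reference(gen)
    state$meta <- list(
      time_series = generate_cohort("time_series"),
      zjc = generate_cohort("zjc_like"),
      multicenter = generate_cohort("multicenter_like")
    )
    state$sim <- purrr::imap(state$meta, function(m, nm) {
      simulate_intensities(state$reference, m, gen,
                           include_peptides = (nm == "zjc"),
                           seed = derive_seed(config$seed, paste0("intens_", nm)))
    })
    state$psms <- simulate_psms(state$reference,
                                seed = derive_seed(config$seed, "psms"))
    dir <- file.path(config$outdir, "simulate")
    paths <- purrr::imap(state$sim, function(s, nm) {
      write_simulation(state$reference, state$meta[[nm]], s,
                       psms = if (nm == "zjc") state$psms else NULL,
                       dir = file.path(dir, nm))
    })
    unlist(paths)
  })

  run_stage("reduce_db", function() {
    need_stage(state, "psms", "reduce_db")
    db <- state$reference$proteins
    runs <- split(state$psms$psms, state$psms$psms$run)
    reduced <- purrr::map(runs, simplify_database, source_db = db,
                          q_cutoff = config$q_cutoff)
    host <- db[db$origin == "human", ]
    combined <- merge_databases(reduced, host)
    state$combined_db <- combined
    dir <- file.path(config$outdir, "reduce_db")
    dir.create(dir, showWarnings = FALSE)
    p <- file.path(dir, "combined_db.fasta")
    write_protein_fasta(combined, p)
    counts <- file.path(dir, "reduction_counts.json")
    jsonlite::write_json(list(
      per_run = purrr::map_int(reduced, nrow),
      combined = nrow(combined), source = nrow(db)
    ), counts, auto_unbox = TRUE)
    list(p, counts)
  })

  run_stage("annotate", function() {
    need_stage(state, "reference", "annotate")
    ref <- state$reference
    index <- build_peptide_index(ref$proteins,
                                 max_missed = config$index_max_missed)
    state$index <- index
    obs <- with_seed(derive_seed(config$seed, "annotate"), {
      mic <- ref$proteins[ref$proteins$origin == "microbial", ]
      picked <- mic[sample.int(nrow(mic), min(config$annotate_n_peptides, nrow(mic))), ]
      vapply(picked$sequence, function(s) {
        frags <- canonicalize_peptides(tryptic_digest(s, 1))
        if (length(frags)) sample(frags, 1) else substr(s, 1, 10)
      }, "", USE.NAMES = FALSE)
    })
    ann <- annotate_peptides(unique(obs), index, ref$taxonomy)
    state$annotation <- ann
    dir <- file.path(config$outdir, "annotate")
    dir.create(dir, showWarnings = FALSE)
    list(write_stage_tsv(ann, dir, "peptide_annotation.tsv"))
  })

  run_stage("quantify", function() {
    need_stage(state, "sim", "quantify")
    dir <- file.path(config$outdir, "quantify")
    dir.create(dir, showWarnings = FALSE)
    outs <- list()
    qc <- purrr::map(state$sim, function(s) {
      qc_filter(s$protein, config$qc_min_human, config$qc_min_microbial)
    })
    state$qc <- qc
    outs$qc <- write_stage_tsv(
      purrr::imap_dfr(qc, function(q, nm) bind_cols(tibble(cohort = nm), q$report)),
      dir, "qc_report.tsv")
    outs$ratio <- write_stage_tsv(
      purrr::imap_dfr(state$sim, function(s, nm) {
        bind_cols(tibble(cohort = nm),
                  host_microbe_ratio(s$protein, samples = state$qc[[nm]]$kept))
      }), dir, "host_microbe_ratio.tsv")
    tree <- state$reference$taxonomy
    state$agg <- purrr::map(state$sim, function(s) {
      mic <- s$protein[s$protein$origin == "microbial", ]
      list(species = aggregate_quant(mic, "taxon_rank", tree, "species")$table,
           phylum = aggregate_quant(mic, "taxon_rank", tree, "phylum")$table,
           cog = aggregate_quant(mic, "cog")$table)
    })
    outs$species <- write_stage_tsv(state$agg$zjc$species, dir, "zjc_species.tsv")
    outs$cog <- write_stage_tsv(state$agg$zjc$cog, dir, "zjc_cog.tsv")
    ov <- purrr::map_dfr(c(human = "human", microbial = "microbial"), function(o) {
      a <- identified_features(state$sim$zjc$protein, state$qc$zjc$kept, origin = o)
      b <- identified_features(state$sim$multicenter$protein,
                               state$qc$multicenter$kept, origin = o)
      bind_cols(tibble(layer = paste0(o, "_protein")), cohort_overlap(a, b))
    })
    outs$overlap <- write_stage_tsv(ov, dir, "cohort_overlap.tsv")
    outs
  })

  run_stage("stability", function() {
    need_stage(state, "sim", "stability")
    need_stage(state, "agg", "stability")
    ts <- state$sim$time_series$protein
    meta <- state$meta$time_series
    layers <- list(
      human_protein = ts[ts$origin == "human", ],
      microbial_protein = ts[ts$origin == "microbial", ],
      phylum = state$agg$time_series$phylum,
      cog = state$agg$time_series$cog
    )
    stab <- purrr::imap_dfr(layers, function(tbl, nm) {
      bind_cols(tibble(layer = nm), as_tibble(stability_summary(tbl, meta)))
    })
    state$stability <- stab
    dir <- file.path(config$outdir, "stability")
    dir.create(dir, showWarnings = FALSE)
    list(write_stage_tsv(stab, dir, "stability_summary.tsv"))
  })

  run_stage("differential", function() {
    need_stage(state, "qc", "differential")
    dir <- file.path(config$outdir, "differential")
    dir.create(dir, showWarnings = FALSE)
    zjc <- state$sim$zjc$protein
    meta <- state$meta$zjc
    kept <- state$qc$zjc$kept
    keep_cols <- c(ANNOTATION_COLS[ANNOTATION_COLS %in% names(zjc)], kept)
    zjc <- zjc[, intersect(names(zjc), keep_cols)]
    deps <- purrr::map(c(human = "human", microbial = "microbial"), function(o) {
      differential_proteins(zjc[zjc$origin == o, ], meta,
                            lfc_threshold = config$lfc_threshold,
                            alpha = config$alpha, adjust = config$adjust)
    })
    state$deps <- deps
    outs <- purrr::imap(deps, function(d, nm) {
      write_stage_tsv(as_tibble(d), dir, paste0("dep_", nm, ".tsv"))
    })
    cmap <- dplyr::rename(state$reference$annotations,
                          feature_id = "accession", category = "cog")
    fg <- deps$microbial$feature_id[deps$microbial$significant]
    bg <- deps$microbial$feature_id
    if (length(fg)) {
      enr <- fisher_enrichment(fg, bg, cmap[, c("feature_id", "category")])
      state$enrichment <- enr
      outs$enrichment <- write_stage_tsv(enr, dir, "enrichment_cog.tsv")
    }
    outs
  })

  run_stage("risk", function() {
    need_stage(state, "agg", "risk")
    risk <- species_risk(state$agg$zjc$species, state$meta$zjc)
    state$risk <- risk
    dir <- file.path(config$outdir, "risk")
    dir.create(dir, showWarnings = FALSE)
    list(write_stage_tsv(as_tibble(risk), dir, "species_risk.tsv"))
  })

  run_stage("model", function() {
    need_stage(state, "qc", "model")
    zjc_mic <- state$sim$zjc$protein[state$sim$zjc$protein$origin == "microbial", ]
    meta_all <- bind_rows(state$meta$zjc, state$meta$multicenter)
    split <- split_cohort(state$meta$zjc[state$meta$zjc$sample_id %in% state$qc$zjc$kept, ],
                          train_fraction = config$model$train_fraction,
                          seed = derive_seed(config$seed, "split"))
    mc_mic <- state$sim$multicenter$protein[
      state$sim$multicenter$protein$origin == "microbial", ]
    fit <- train_and_evaluate(
      zjc_mic, meta_all,
      test_tables = list(
        test = list(table = zjc_mic, samples = split$test),
        multicenter = list(table = mc_mic,
                           samples = state$qc$multicenter$kept)
      ),
      config = config$model, train_samples = split$train
    )
    state$fit <- fit
    state$split <- split
    dir <- file.path(config$outdir, "model")
    dir.create(dir, showWarnings = FALSE)
    list(
      write_stage_tsv(fit$ranking, dir, "feature_ranking.tsv"),
      write_stage_tsv(fit$metrics, dir, "evaluation_metrics.tsv"),
      write_stage_tsv(
        purrr::imap_dfr(fit$evaluations,
                        function(ev, nm) bind_cols(tibble(dataset = nm), ev$scores)),
        dir, "predictions.tsv")
    )
  })

  run_stage("embed", function() {
    need_stage(state, "fit", "embed")
    top <- state$fit$model$features
    zjc_mic <- state$sim$zjc$protein[state$sim$zjc$protein$origin == "microbial", ]
    sub <- zjc_mic[zjc_mic$feature_id %in% top, ]
    emb <- embedding_diagnostics(sub, state$meta$zjc,
                                 samples = state$qc$zjc$kept,
                                 seed = derive_seed(config$seed, "embed"))
    state$embedding <- emb
    dir <- file.path(config$outdir, "embed")
    dir.create(dir, showWarnings = FALSE)
    list(write_stage_tsv(emb$embedding, dir, "embedding.tsv"),
         write_stage_tsv(emb$group_distances, dir, "group_distances.tsv"))
  })

  manifest$config <- list(
    stages = config$stages, qc_min_human = config$qc_min_human,
    qc_min_microbial = config$qc_min_microbial, q_cutoff = config$q_cutoff,
    lfc_threshold = config$lfc_threshold, alpha = config$alpha,
    adjust = config$adjust
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "state") <- state
  invisible(manifest)
}
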