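# small labelled cohort with a given number of informative features
sim_cohort_tbl <- function(n_per_group = 30, n_feat = 60, n_informative = 0,
                           shift = 2, seed = 1) {
  set.seed(seed)
  samples <- sprintf("m%03d", seq_len(2 * n_per_group))
  group <- rep(c("cancer", "non_cancer"), each = n_per_group)
  m <- matrix(2^rnorm(n_feat * length(samples), 18, 1), n_feat, length(samples),
              dimnames = list(sprintf("MP%04d", seq_len(n_feat)), samples))
  if (n_informative > 0) {
    m[seq_len(n_informative), group == "cancer"] <-
      m[seq_len(n_informative), group == "cancer"] * 2^shift
  }
  list(table = quant_tbl(m, origin = "microbial"),
       meta = meta_tbl(samples, group))
}

test_that("cohort split is stratified, exact and reproducible", {
  meta <- meta_tbl(sprintf("s%02d", 1:16), rep(c("cancer", "non_cancer"), each = 8))
  sp <- split_cohort(meta, 0.75, seed = 3)
  expect_length(sp$train, 12)
  expect_length(sp$test, 4)
  grp <- setNames(meta$group, meta$sample_id)
  expect_equal(sum(grp[sp$train] == "cancer"), 6)
  expect_equal(sum(grp[sp$test] == "cancer"), 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_cohort(meta, 0.75, seed = 3), sp)
  expect_false(identical(split_cohort(meta, 0.75, seed = 4)$train, sp$train))

  # 233 samples at 3:1: per-class counts within 1 of (175, 58)
  meta233 <- meta_tbl(sprintf("z%03d", 1:233),
                      rep(c("cancer", "non_cancer"), c(120, 113)))
  sp233 <- split_cohort(meta233, 0.75, seed = 5)
  expect_lte(abs(length(sp233$train) - 175), 1)
  expect_lte(abs(length(sp233$test) - 58), 1)
  expect_error(split_cohort(meta_tbl("x1", "cancer")),
               class = "linguomics_argument_error")
})

test_that("a perfect predictor dominates the feature ranking", {
  d <- sim_cohort_tbl(n_per_group = 20, n_feat = 30, seed = 6)
  m <- quant_matrix(d$table)
  m["MP0001", ] <- ifelse(d$meta$group == "cancer", 1000, 1)
  tbl <- quant_tbl(m, origin = "microbial")
  cfg <- model_config(cv_folds = 5, seed = 11)
  rk <- rank_features(tbl, d$meta, cfg)
  expect_equal(rk$feature_id[1], "MP0001")
  expect_gt(rk$influence[1], 50)
  expect_equal(sum(rk$influence), 100, tolerance = 1e-6)
  expect_false(is.null(attr(rk, "cv_error")))
})

test_that("pure-noise features rank without crashing and report top-k overlap", {
  d <- sim_cohort_tbl(n_per_group = 25, n_feat = 80, seed = 7)
  r1 <- rank_features(d$table, d$meta, model_config(cv_folds = 5, seed = 1))
  r2 <- rank_features(d$table, d$meta, model_config(cv_folds = 5, seed = 2))
  overlap <- length(intersect(head(r1$feature_id, 50), head(r2$feature_id, 50)))
  expect_true(overlap >= 0 && overlap <= 50)
  expect_error(
    rank_features(quant_tbl(matrix(c(1, Inf, 2, 3), 1, 4,
                                   dimnames = list("f", sprintf("s%d", 1:4))),
                            origin = "microbial"),
                  meta_tbl(sprintf("s%d", 1:4), rep(c("cancer", "non_cancer"), 2)),
                  model_config(cv_folds = 2)),
    class = "linguomics_validation_error")
})

test_that("a separable test set evaluates to perfect accuracy and AUC", {
  d <- sim_cohort_tbl(n_per_group = 30, n_feat = 40, n_informative = 5,
                      shift = 6, seed = 8)
  sp <- split_cohort(d$meta, 0.75, seed = 9)
  fit <- train_and_evaluate(d$table, d$meta,
                            test_tables = list(test = list(table = d$table,
                                                           samples = sp$test)),
                            config = model_config(cv_folds = 5, seed = 10),
                            train_samples = sp$train)
  mt <- fit$metrics
  expect_equal(mt$auc[mt$dataset == "test"], 1.0)
  expect_equal(mt$accuracy[mt$dataset == "test"], 1.0)
  expect_true(all(mt$accuracy_ci_low <= mt$accuracy & mt$accuracy <= mt$accuracy_ci_high))
  cm <- fit$evaluations$test$confusion
  expect_equal(sum(cm), length(sp$test))
})

test_that("label permutation drives AUC to chance", {
  set.seed(60)
  scores <- runif(200)
  aucs <- replicate(20, {
    y <- sample(rep(0:1, each = 100))
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("feature selection never sees the test data", {
  d <- sim_cohort_tbl(n_per_group = 20, n_feat = 50, n_informative = 3, seed = 12)
  sp <- split_cohort(d$meta, 0.75, seed = 13)
  cfg <- model_config(cv_folds = 5, seed = 14)
  rk1 <- rank_features(d$table, d$meta, cfg, samples = sp$train)
  # perturb the held-out samples only
  m <- quant_matrix(d$table)
  m[, sp$test] <- m[, sp$test] * 100 + 7
  rk2 <- rank_features(quant_tbl(m, origin = "microbial"), d$meta, cfg,
                       samples = sp$train)
  expect_identical(rk1$feature_id, rk2$feature_id)
  expect_identical(rk1$influence, rk2$influence)
})

test_that("fixed config and seed give identical rankings, predictions, reports", {
  d <- sim_cohort_tbl(n_per_group = 20, n_feat = 40, n_informative = 4, seed = 15)
  cfg <- model_config(cv_folds = 5, top_k = 10, seed = 16)
  run <- function() {
    sp <- split_cohort(d$meta, 0.75, seed = 17)
    train_and_evaluate(d$table, d$meta,
                       test_tables = list(test = list(table = d$table,
                                                      samples = sp$test)),
                       config = cfg, train_samples = sp$train)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$ranking, f2$ranking)
  expect_identical(f1$evaluations$test$scores, f2$evaluations$test$scores)
  expect_identical(f1$metrics, f2$metrics)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(61)
  y <- rep(0:1, each = 30)
  s <- rnorm(60) + y
  a1 <- pROC::auc(pROC::roc(y, s, levels = c(0, 1), direction = "<", quiet = TRUE))
  a2 <- pROC::auc(pROC::roc(y, exp(s), levels = c(0, 1), direction = "<", quiet = TRUE))
  a3 <- pROC::auc(pROC::roc(y, rank(s), levels = c(0, 1), direction = "<", quiet = TRUE))
  expect_equal(as.numeric(a1), as.numeric(a2))
  expect_equal(as.numeric(a1), as.numeric(a3))
})

test_that("tidy and glance methods summarise models and evaluations", {
  d <- sim_cohort_tbl(n_per_group = 15, n_feat = 20, n_informative = 2, seed = 18)
  cfg <- model_config(cv_folds = 5, top_k = 5, seed = 19)
  rk <- rank_features(d$table, d$meta, cfg)
  mod <- train_screening_model(d$table, d$meta, head(rk$feature_id, 5), cfg)
  ev <- evaluate_model(mod, d$table, d$meta)
  expect_equal(nrow(tidy(mod)), 5)
  expect_equal(glance(mod)$n_features, 5)
  expect_true(all(c("metric", "value") %in% names(tidy(ev))))
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("embedding diagnostics satisfy metric axioms and determinism", {
  set.seed(62)
  m <- matrix(2^rnorm(20 * 3, 15, 1), 20, 3,
              dimnames = list(sprintf("f%02d", 1:20), c("e1", "e2", "e3")))
  tbl <- quant_tbl(m, origin = "microbial")
  meta <- meta_tbl(colnames(m), c("cancer", "cancer", "non_cancer"))
  emb <- embedding_diagnostics(tbl, meta)
  D <- emb$distances
  expect_equal(dim(D), c(3, 3))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  # duplicated sample sits at distance zero from its twin
  m2 <- cbind(m, e4 = m[, "e1"])
  meta2 <- meta_tbl(colnames(m2), c("cancer", "cancer", "non_cancer", "cancer"))
  emb2 <- embedding_diagnostics(quant_tbl(m2, origin = "microbial"), meta2)
  expect_equal(emb2$distances["e1", "e4"], 0)

  # constant features are a degenerate input
  mc <- matrix(5, 4, 3, dimnames = list(sprintf("c%d", 1:4), c("e1", "e2", "e3")))
  expect_error(embedding_diagnostics(quant_tbl(mc, origin = "microbial"), meta),
               class = "linguomics_degenerate_error")

  # determinism for a fixed seed on a bigger set
  set.seed(63)
  mm <- matrix(2^rnorm(30 * 12, 15, 1), 30, 12,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("t%02d", 1:12)))
  mt <- meta_tbl(colnames(mm), rep(c("cancer", "non_cancer"), 6))
  ea <- embedding_diagnostics(quant_tbl(mm, origin = "microbial"), mt,
                              seed = 5, max_iter = 150)
  eb <- embedding_diagnostics(quant_tbl(mm, origin = "microbial"), mt,
                              seed = 5, max_iter = 150)
  expect_identical(ea$embedding, eb$embedding)
})

test_that("staged cancers sit farther from controls than gastritis does", {
  cfg <- generator_config(seed = 64, n_phyla = 2, genera_per_phylum = 2,
                          species_per_genus = 2, proteins_per_species = 15,
                          human_proteins = 10, risk_or = NULL,
                          n_dep_human = 0, n_dep_microbial = 0,
                          n_discriminative = 10, discriminative_lfc = 1.5)
  ref <- generate_reference(cfg)
  meta <- generate_cohort("zjc_like")
  sim <- simulate_intensities(ref, meta, cfg, include_peptides = FALSE)
  disc <- sim$truth$discriminative$feature_id
  sub <- sim$protein[sim$protein$feature_id %in% disc, ]
  emb <- embedding_diagnostics(sub, meta, max_iter = 50)
  gd <- emb$group_distances
  d_stage <- gd$mean_distance[gd$comparison %in%
                                c("control_vs_stage_I_II", "control_vs_stage_III_IV")]
  d_gast <- gd$mean_distance[gd$comparison == "control_vs_gastritis"]
  expect_true(all(d_stage > d_gast))
})
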