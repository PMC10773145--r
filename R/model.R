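#' Gastric cancer screening model
#'
#' A stochastic gradient-boosted classifier over microbial protein
#' abundances. The cohort is split 3:1 stratified by class, the boosted
#' ensemble is fitted on the training data with ten-fold cross-validation,
#' features are ranked by relative influence (normalized reduction-in-loss),
#' and a model refitted on the top-k features is evaluated on held-out and
#' external datasets (accuracy with exact binomial confidence interval,
#' sensitivity, specificity at the 0.5 cutoff, trapezoidal AUC).
#'
#' @name screening_model
NULL

#' Screening model configuration
#'
#' Defaults follow the published model: tree depth 3, 150 trees, learning
#' rate 0.1, minimum node size 10, ten-fold cross-validation, top 50
#' features, 3:1 train:test split, bag fraction 0.5 (the stochastic part of
#' stochastic gradient boosting).
#'
#' @param interaction_depth Tree depth.
#' @param n_trees Number of boosting rounds.
#' @param shrinkage Learning rate.
#' @param min_node_size Minimum observations per terminal node.
#' @param cv_folds Cross-validation folds.
#' @param top_k Number of features kept after ranking.
#' @param train_fraction Training fraction for the cohort split.
#' @param bag_fraction Row subsample fraction per boosting round.
#' @param seed Integer seed.
#' @return A `model_config` list.
#' @export
model_config <- function(interaction_depth = 3, n_trees = 150, shrinkage = 0.1,
                         min_node_size = 10, cv_folds = 10, top_k = 50,
                         train_fraction = 0.75, bag_fraction = 0.5, seed = 1L) {
  cfg <- list(interaction_depth = interaction_depth, n_trees = n_trees,
              shrinkage = shrinkage, min_node_size = min_node_size,
              cv_folds = cv_folds, top_k = top_k,
              train_fraction = train_fraction, bag_fraction = bag_fraction,
              seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "train_fraction")])
  if (any(num <= 0)) abort_arg("all model_config values must be positive")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    abort_arg("train_fraction must lie in (0, 1)")
  }
  structure(cfg, class = "model_config")
}

#' Stratified train/test split of a cohort
#'
#' Splits samples into disjoint train and test sets, stratified by `group`,
#' with `round(train_fraction * n)` training samples per class (clamped so
#' both sides of each class are non-empty). Reproducible for a fixed seed.
#'
#' @param meta Metadata with `sample_id` and `group`.
#' @param train_fraction Training fraction (default 0.75, the 3:1 split).
#' @param seed Integer seed.
#' @return List with `train` and `test` character sample id vectors.
#' @export
split_cohort <- function(meta, train_fraction = 0.75, seed = 1L) {
  meta <- check_meta(meta)
  counts <- table(meta$group)
  if (length(counts) < 2) abort_arg("both classes must be present")
  if (any(counts < 2)) abort_arg("every class needs at least 2 samples")
  with_seed(seed, {
    train <- character(0)
    for (g in sort(names(counts))) {
      ids <- meta$sample_id[meta$group == g]
      n_tr <- min(max(round(train_fraction * length(ids)), 1), length(ids) - 1)
      train <- c(train, sample(ids, n_tr))
    }
    list(train = sort(train), test = sort(setdiff(meta$sample_id, train)))
  })
}

# samples x features matrix for the booster; NA stays NA (xgboost treats it
# as missing)
model_matrix_from_quant <- function(table, samples) {
  m <- quant_matrix(table)
  miss <- setdiff(samples, colnames(m))
  if (length(miss)) {
    abort_schema(paste0("sample(s) missing from quant table: ",
                        paste(head(miss, 5), collapse = ", ")))
  }
  t(m[, samples, drop = FALSE])
}

labels_for <- function(meta, samples) {
  grp <- setNames(meta$group, meta$sample_id)[samples]
  as.integer(grp == "cancer")
}

xgb_params <- function(config) {
  # min_node_size counts observations; the booster's equivalent constraint
  # is in hessian units, which for Bernoulli deviance are at most 1/4 per
  # observation, so divide by 4 to keep the same effective node size
  list(objective = "binary:logistic", eval_metric = "logloss",
       max_depth = config$interaction_depth, eta = config$shrinkage,
       min_child_weight = config$min_node_size / 4,
       subsample = config$bag_fraction, nthread = 1)
}

#' Rank features by boosted-ensemble relative influence
#'
#' Fits the gradient-boosted ensemble on the training data (with `cv_folds`
#' cross-validation to estimate prediction error) and returns all features
#' ordered by decreasing relative influence: the reduction-in-loss (gain)
#' importance normalized to sum 100. Features the ensemble never uses have
#' influence 0; ties break by feature id.
#'
#' @param train_table Quant tibble of microbial proteins.
#' @param meta Metadata with `sample_id`, `group`.
#' @param config A [model_config()].
#' @param samples Training sample ids (default: all columns of
#'   `train_table`).
#' @return Tibble with `feature_id`, `influence`, `rank`; the
#'   cross-validation log-loss track is in `attr(, "cv_error")`.
#' @export
rank_features <- function(train_table, meta, config = model_config(),
                          samples = NULL) {
  samples <- samples %||% quant_samples(train_table)
  meta <- check_meta(meta, samples)
  X <- model_matrix_from_quant(train_table, samples)
  if (any(!is.finite(X[!is.na(X)]))) {
    abort(paste("non-finite intensities in training matrix"),
          class = "linguomics_validation_error")
  }
  y <- labels_for(meta, samples)
  if (min(table(y)) < config$cv_folds) {
    abort_arg("need at least `cv_folds` samples per class")
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  cv_err <- with_seed(config$seed, {
    cv <- xgboost::xgb.cv(params = xgb_params(config), data = dtrain,
                          nrounds = config$n_trees, nfold = config$cv_folds,
                          stratified = TRUE, verbose = 0)
    cv$evaluation_log
  })
  booster <- with_seed(config$seed, {
    xgboost::xgb.train(params = xgb_params(config), data = dtrain,
                       nrounds = config$n_trees, verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = booster)
  used <- tibble(feature_id = imp$Feature, influence = 100 * imp$Gain / sum(imp$Gain))
  unused <- tibble(feature_id = setdiff(colnames(X), used$feature_id), influence = 0)
  out <- bind_rows(used, unused) |>
    arrange(dplyr::desc(.data$influence), .data$feature_id) |>
    mutate(rank = row_number())
  attr(out, "cv_error") <- cv_err
  out
}

#' Train the screening model on a fixed feature list
#'
#' Refits the boosted ensemble on the training samples using only the
#' selected features (chosen before any test data is seen).
#'
#' @param train_table Quant tibble.
#' @param meta Metadata.
#' @param features Character vector of selected feature ids.
#' @param config A [model_config()].
#' @param samples Training sample ids (default all columns).
#' @return Object of class `screening_model`.
#' @export
train_screening_model <- function(train_table, meta, features,
                                  config = model_config(), samples = NULL) {
  samples <- samples %||% quant_samples(train_table)
  meta <- check_meta(meta, samples)
  miss <- setdiff(features, train_table$feature_id)
  if (length(miss)) {
    abort_schema(paste0("selected feature(s) missing from table: ",
                        paste(head(miss, 5), collapse = ", ")))
  }
  sub <- train_table[match(features, train_table$feature_id), , drop = FALSE]
  X <- model_matrix_from_quant(sub, samples)
  y <- labels_for(meta, samples)
  booster <- with_seed(config$seed, {
    xgboost::xgb.train(params = xgb_params(config),
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = config$n_trees, verbose = 0)
  })
  structure(list(features = features, booster = booster, config = config,
                 train_samples = samples),
            class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  cat("<screening_model> ", length(x$features), " features, ",
      x$config$n_trees, " trees, depth ", x$config$interaction_depth,
      ", trained on ", length(x$train_samples), " samples\n", sep = "")
  invisible(x)
}

#' Predict cancer probability for samples
#' @param object A `screening_model`.
#' @param table Quant tibble containing the model's features.
#' @param samples Sample ids (default all columns of `table`).
#' @param ... Unused.
#' @return Named numeric vector of probabilities.
#' @export
predict.screening_model <- function(object, table, samples = NULL, ...) {
  samples <- samples %||% quant_samples(table)
  miss <- setdiff(object$features, table$feature_id)
  if (length(miss)) {
    abort_schema(paste0("model feature(s) missing from table: ",
                        paste(head(miss, 5), collapse = ", ")))
  }
  sub <- table[match(object$features, table$feature_id), , drop = FALSE]
  X <- model_matrix_from_quant(sub, samples)
  setNames(predict(object$booster, xgboost::xgb.DMatrix(X)), samples)
}

# trapezoidal AUC of scores vs binary labels (1 = positive)
trapezoid_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Evaluate the screening model on a dataset
#'
#' Scores the samples and reports accuracy with an exact binomial
#' (Clopper-Pearson) 95% confidence interval, sensitivity and specificity at
#' the `cutoff` probability, trapezoidal AUC, and the confusion matrix.
#'
#' @param model A `screening_model`.
#' @param table Quant tibble.
#' @param meta Metadata with `sample_id`, `group`.
#' @param samples Sample ids to score (default all columns of `table`).
#' @param cutoff Classification probability cutoff (default 0.5).
#' @return Object of class `screening_eval`: a list with `metrics` (tibble),
#'   `confusion` (2x2 table) and `scores` (per-sample tibble).
#' @export
evaluate_model <- function(model, table, meta, samples = NULL, cutoff = 0.5) {
  samples <- samples %||% quant_samples(table)
  meta <- check_meta(meta, samples)
  prob <- predict(model, table, samples)
  y <- labels_for(meta, samples)
  pred <- as.integer(prob >= cutoff)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  n <- length(y)
  acc_test <- stats::binom.test(tp + tn, n)
  metrics <- tibble(
    n = n,
    accuracy = (tp + tn) / n,
    accuracy_ci_low = acc_test$conf.int[1],
    accuracy_ci_high = acc_test$conf.int[2],
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = if (length(unique(y)) == 2) trapezoid_auc(y, prob) else NA_real_
  )
  structure(list(
    metrics = metrics,
    confusion = matrix(c(tn, fn, fp, tp), nrow = 2,
                       dimnames = list(predicted = c("non_cancer", "cancer"),
                                       truth = c("non_cancer", "cancer"))),
    scores = tibble(sample_id = samples, truth = y, probability = unname(prob),
                    predicted = pred),
    cutoff = cutoff
  ), class = "screening_eval")
}

#' @export
print.screening_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<screening_eval> n=%d accuracy=%.1f%% (95%% CI %.1f-%.1f%%) sens=%.1f%% spec=%.1f%% AUC=%.3f\n",
    m$n, 100 * m$accuracy, 100 * m$accuracy_ci_low, 100 * m$accuracy_ci_high,
    100 * m$sensitivity, 100 * m$specificity, m$auc))
  invisible(x)
}

#' Rank, refit and evaluate in one step
#'
#' Ranks features on the training samples, keeps the top `config$top_k`,
#' refits on the training samples only, and evaluates every supplied
#' dataset. Feature selection never sees the test data.
#'
#' @param train_table Quant tibble for training.
#' @param meta Metadata covering all datasets.
#' @param test_tables Named list of `list(table =, samples =)` entries (a
#'   bare quant tibble is also accepted; then all its columns are scored).
#' @param config A [model_config()].
#' @param train_samples Training sample ids (default all columns of
#'   `train_table`).
#' @return List with `model`, `ranking`, `evaluations` (named list of
#'   `screening_eval`) and `metrics` (one tibble row per dataset).
#' @export
train_and_evaluate <- function(train_table, meta, test_tables = list(),
                               config = model_config(), train_samples = NULL) {
  train_samples <- train_samples %||% quant_samples(train_table)
  ranking <- rank_features(train_table, meta, config, samples = train_samples)
  top <- ranking$feature_id[seq_len(min(config$top_k, nrow(ranking)))]
  model <- train_screening_model(train_table, meta, top, config,
                                 samples = train_samples)
  datasets <- c(list(train = list(table = train_table, samples = train_samples)),
                test_tables)
  evaluations <- purrr::imap(datasets, function(d, nm) {
    if (is.data.frame(d)) d <- list(table = d, samples = quant_samples(d))
    evaluate_model(model, d$table, meta, samples = d$samples)
  })
  metrics <- purrr::imap_dfr(evaluations, function(ev, nm) {
    bind_cols(tibble(dataset = nm), ev$metrics)
  })
  list(model = model, ranking = ranking, evaluations = evaluations,
       metrics = metrics)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the feature influence of a screening model
#' @param x A `screening_model`.
#' @param ... Unused.
#' @return Tibble with `feature_id` and model metadata.
#' @export
tidy.screening_model <- function(x, ...) {
  tibble(feature_id = x$features, rank = seq_along(x$features))
}

#' One-row model summary
#' @param x A `screening_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.screening_model <- function(x, ...) {
  tibble(n_features = length(x$features), n_trees = x$config$n_trees,
         interaction_depth = x$config$interaction_depth,
         shrinkage = x$config$shrinkage, n_train = length(x$train_samples))
}

#' Tidy evaluation metrics
#' @param x A `screening_eval`.
#' @param ... Unused.
#' @return Long tibble of metric/value pairs.
#' @export
tidy.screening_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, cols = dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' One-row evaluation summary
#' @param x A `screening_eval`.
#' @param ... Unused.
#' @return One-row tibble of metrics.
#' @export
glance.screening_eval <- function(x, ...) x$metrics
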