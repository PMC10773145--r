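#' Embedding diagnostics for the selected features
#'
#' Visual and metric diagnostics of sample structure in the space of the
#' selected marker proteins: a deterministic 2-D t-SNE embedding, the full
#' pairwise Euclidean distance matrix, and group-averaged distances between
#' healthy controls and the gastritis / stage I-II / stage III-IV strata.
#' Distances and the embedding work on `log2(intensity + 1)` with missing
#' treated as 0 (not identified).
#'
#' @name embedding
NULL

# Exact (O(n^2)) t-SNE, sufficient for cohort-sized inputs. Conditional
# probabilities from a per-point precision found by binary search on the
# perplexity; symmetrized; gradient descent with momentum, adaptive gains
# and early exaggeration; PCA initialization jittered by seeded noise so
# the result is deterministic for a fixed seed.
tsne_exact <- function(X, dims = 2, perplexity = 30, max_iter = 400, seed = 1L) {
  n <- nrow(X)
  if (n < 4) abort_arg("t-SNE needs at least 4 samples")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-Di * beta)
      sumP <- sum(p)
      if (sumP == 0) { p[] <- 1 / length(p); sumP <- 1 }
      H <- log(sumP) + beta * sum(Di * p) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sumP
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  pc <- stats::prcomp(X, rank. = dims)$x[, seq_len(dims), drop = FALSE]
  pc <- scale(pc, scale = FALSE)
  denom <- stats::sd(pc[, 1])
  if (!is.finite(denom) || denom == 0) denom <- 1
  Y <- pc / denom * 1e-4 +
    with_seed(seed, matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  G <- matrix(1, n, dims)   # gains
  dY_prev <- matrix(0, n, dims)
  eta <- 200
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= 100) P * 12 else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    G <- ifelse(sign(grad) != sign(dY_prev), G + 0.2, G * 0.8)
    G <- pmax(G, 0.01)
    dY_prev <- mom * dY_prev - eta * G * grad
    Y <- Y + dY_prev
    Y <- scale(Y, scale = FALSE)
  }
  colnames(Y) <- paste0("tsne", seq_len(dims))
  Y
}

#' Embedding and distance diagnostics on selected features
#'
#' @param table Quant tibble restricted to the selected features.
#' @param meta Metadata with `sample_id`, `group`, and optionally `stage`
#'   (values `I`..`IV`, `gastritis`, `none`).
#' @param samples Sample ids (default all columns of `table`).
#' @param perplexity t-SNE perplexity (default 30, clamped to the sample
#'   size).
#' @param seed Integer seed; the embedding is deterministic given it.
#' @param max_iter t-SNE iterations.
#' @return Object of class `embedding_diagnostics`: list with `embedding`
#'   (tibble of coordinates joined to metadata), `distances` (symmetric
#'   matrix, zero diagonal) and `group_distances` (mean control-to-stratum
#'   Euclidean distances).
#' @export
embedding_diagnostics <- function(table, meta, samples = NULL, perplexity = 30,
                                  seed = 1L, max_iter = 400) {
  samples <- samples %||% quant_samples(table)
  if (length(samples) < 3) abort_arg("need at least 3 samples")
  meta <- check_meta(meta, samples)
  m <- quant_matrix(table)[, samples, drop = FALSE]
  lg <- log2(m + 1)
  # missing = not identified; min-impute per feature so absence sits at the
  # detection floor instead of at log2(1) = 0, which would dominate distances
  lg <- t(apply(lg, 1, function(v) {
    v[is.na(v)] <- if (all(is.na(v))) 0 else min(v, na.rm = TRUE)
    v
  }))
  X <- t(lg)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) {
    abort(paste("all selected features are constant across samples"),
          class = "linguomics_degenerate_error")
  }
  X <- X[, keep, drop = FALSE]
  D <- as.matrix(stats::dist(X))
  emb <- if (nrow(X) >= 4) {
    as_tibble(tsne_exact(X, perplexity = perplexity, seed = seed,
                         max_iter = max_iter))
  } else {
    tibble(tsne1 = rep(NA_real_, nrow(X)), tsne2 = NA_real_)
  }
  emb <- bind_cols(tibble(sample_id = samples), emb)
  emb <- left_join(emb, meta, by = "sample_id")
  stage <- if ("stage" %in% names(meta)) {
    setNames(as.character(meta$stage), meta$sample_id)[samples]
  } else {
    setNames(rep(NA_character_, length(samples)), samples)
  }
  grp <- setNames(meta$group, meta$sample_id)[samples]
  stratum <- dplyr::case_when(
    grp == "non_cancer" & (is.na(stage) | stage %in% c("none", "")) ~ "control",
    grp == "non_cancer" & stage == "gastritis" ~ "gastritis",
    grp == "cancer" & stage %in% c("I", "II") ~ "stage_I_II",
    grp == "cancer" & stage %in% c("III", "IV") ~ "stage_III_IV",
    TRUE ~ "other"
  )
  ctrl <- samples[stratum == "control"]
  gdist <- purrr::map_dfr(c("gastritis", "stage_I_II", "stage_III_IV"), function(s) {
    ids <- samples[stratum == s]
    tibble(comparison = paste0("control_vs_", s),
           n_pairs = length(ctrl) * length(ids),
           mean_distance = if (length(ctrl) && length(ids)) {
             mean(D[ctrl, ids, drop = FALSE])
           } else NA_real_)
  })
  structure(list(embedding = emb, distances = D, group_distances = gdist,
                 seed = seed),
            class = "embedding_diagnostics")
}

#' @export
print.embedding_diagnostics <- function(x, ...) {
  cat("<embedding_diagnostics> ", nrow(x$embedding), " samples\n", sep = "")
  print(x$group_distances, ...)
  invisible(x)
}
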