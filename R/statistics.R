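#' Cohort statistics for tongue-coating proteomes
#'
#' Temporal stability is summarised as Spearman rank correlations between
#' sample pairs, stratified into intra-individual (same subject) and
#' inter-individual (different subjects) pairs. Differential proteins are
#' called by two-sided Wilcoxon rank-sum tests with a fold-change filter;
#' category enrichment uses Fisher's exact test; per-species gastric cancer
#' risk is a univariate logistic regression on standardized log abundance.
#'
#' @name statistics
NULL

check_meta <- function(meta, samples = NULL) {
  if (!all(c("sample_id", "subject_id", "group") %in% names(meta))) {
    abort_schema("metadata needs sample_id, subject_id, group columns")
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, meta$sample_id)
    if (length(miss)) abort_lookup(paste0("sample(s) missing from metadata: ",
                                          paste(head(miss, 5), collapse = ", ")))
  }
  as_tibble(meta)
}

#' Pairwise Spearman stability, intra- vs inter-individual
#'
#' Computes the Spearman correlation over pairwise-complete features for
#' every pair of samples, assigns each pair to the `intra_individual`
#' (same subject) or `inter_individual` stratum, and summarises mean and
#' standard deviation per stratum. Pairs sharing fewer than `min_shared`
#' features are dropped and reported.
#'
#' @param table Quant tibble (one layer: e.g. human proteins, microbial
#'   proteins, phylum aggregate, or COG aggregate).
#' @param meta Sample metadata with `sample_id` and `subject_id`.
#' @param min_shared Minimum pairwise-complete features per pair (default 3).
#' @return Object of class `stability_summary`: tibble with `stratum`,
#'   `mean_r`, `sd_r`, `n_pairs`; the per-pair detail is in
#'   `attr(, "pairs")` and dropped pairs in `attr(, "dropped")`.
#' @export
stability_summary <- function(table, meta, min_shared = 3) {
  m <- quant_matrix(table)
  if (ncol(m) < 2) abort_arg("need at least 2 samples")
  meta <- check_meta(meta, colnames(m))
  subj <- setNames(meta$subject_id, meta$sample_id)
  cmb <- utils::combn(colnames(m), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
    s1 <- cmb[1, k]; s2 <- cmb[2, k]
    ok <- !is.na(m[, s1]) & !is.na(m[, s2])
    tibble(
      sample_a = s1, sample_b = s2,
      stratum = if (subj[[s1]] == subj[[s2]]) "intra_individual" else "inter_individual",
      n_shared = sum(ok),
      r = if (sum(ok) >= min_shared) {
        suppressWarnings(cor(m[ok, s1], m[ok, s2], method = "spearman"))
      } else NA_real_
    )
  })
  dropped <- pairs[pairs$n_shared < min_shared, , drop = FALSE]
  kept <- pairs[pairs$n_shared >= min_shared, , drop = FALSE]
  out <- kept |>
    group_by(.data$stratum) |>
    summarise(mean_r = mean(.data$r), sd_r = sd(.data$r), n_pairs = n(),
              .groups = "drop")
  attr(out, "pairs") <- kept
  attr(out, "dropped") <- dropped
  class(out) <- c("stability_summary", class(out))
  out
}

#' Differential protein analysis (Wilcoxon rank-sum)
#'
#' Per feature, a two-sided Wilcoxon rank-sum test of cancer vs non-cancer
#' intensities (exact when the combined non-missing n is at most 20 and
#' there are no ties, normal approximation with tie and continuity
#' correction otherwise). The fold change is on linear-scale group means:
#' `log2FC = log2(mean cancer / mean non-cancer)`, with both means offset
#' by +1 when either is zero. Significance requires
#' `|log2FC| > lfc_threshold` and (raw or BH-adjusted, per `adjust`)
#' p below `alpha`. Features with fewer than `min_n` non-missing values in
#' either group are skipped and reported.
#'
#' @param table Quant tibble.
#' @param meta Metadata with `sample_id`, `group` (`cancer`/`non_cancer`).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (the headline reading) or `"bh"`.
#' @param min_n Minimum per-group non-missing values (default 3).
#' @return Object of class `dep_results`: tibble with `feature_id`,
#'   `log2fc`, `p`, `p_adj`, `direction`, `significant`, `n_cancer`,
#'   `n_noncancer`; skipped features in `attr(, "skipped")`.
#' @export
differential_proteins <- function(table, meta, lfc_threshold = 1, alpha = 0.05,
                                  adjust = c("none", "bh"), min_n = 3) {
  adjust <- match.arg(adjust)
  m <- quant_matrix(table)
  meta <- check_meta(meta, colnames(m))
  grp <- setNames(meta$group, meta$sample_id)[colnames(m)]
  if (length(unique(grp)) < 2) abort_arg("both groups must be present")
  ca <- m[, grp == "cancer", drop = FALSE]
  nc <- m[, grp == "non_cancer", drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    x <- ca[i, ]; y <- nc[i, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < min_n || length(y) < min_n) {
      return(tibble(feature_id = rownames(m)[i], log2fc = NA_real_, p = NA_real_,
                    n_cancer = length(x), n_noncancer = length(y), skipped = TRUE))
    }
    exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)$p.value
    )
    mx <- mean(x); my <- mean(y)
    if (mx == 0 || my == 0) { mx <- mx + 1; my <- my + 1 }
    tibble(feature_id = rownames(m)[i], log2fc = log2(mx / my), p = p,
           n_cancer = length(x), n_noncancer = length(y), skipped = FALSE)
  })
  skipped <- res[res$skipped, c("feature_id", "n_cancer", "n_noncancer")]
  out <- res[!res$skipped, , drop = FALSE]
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  p_use <- if (adjust == "bh") out$p_adj else out$p
  out$significant <- abs(out$log2fc) > lfc_threshold & p_use < alpha
  out <- out[, c("feature_id", "log2fc", "p", "p_adj", "direction",
                 "significant", "n_cancer", "n_noncancer")]
  attr(out, "skipped") <- skipped
  attr(out, "params") <- list(lfc_threshold = lfc_threshold, alpha = alpha, adjust = adjust)
  class(out) <- c("dep_results", class(out))
  out
}

#' Fisher exact category enrichment
#'
#' For each category, a 2x2 table (in/out foreground by in/out category over
#' the background) is tested two-sided with Fisher's exact test; the
#' reported odds ratio is the sample cross-product ratio. `foreground` must
#' be a subset of `background`.
#'
#' @param foreground,background Character feature id vectors.
#' @param category_map Data frame with `feature_id` and `category` (one row
#'   per feature-category assignment; multiple categories per feature are
#'   allowed).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `category`, `k` (foreground in category), `n`
#'   (foreground size), `K` (background in category), `N` (background
#'   size), `odds_ratio`, `p`, `significant`, sorted by p.
#' @export
fisher_enrichment <- function(foreground, background, category_map, alpha = 0.05) {
  fg <- unique(foreground)
  bg <- unique(background)
  if (length(setdiff(fg, bg))) {
    abort_arg("`foreground` must be a subset of `background`")
  }
  if (!all(c("feature_id", "category") %in% names(category_map))) {
    abort_schema("category_map needs feature_id and category columns")
  }
  cmap <- category_map[category_map$feature_id %in% bg, , drop = FALSE]
  N <- length(bg); n <- length(fg)
  out <- cmap |>
    group_by(category = .data$category) |>
    summarise(
      k = length(intersect(unique(.data$feature_id), fg)),
      K = length(unique(.data$feature_id)),
      .groups = "drop"
    ) |>
    mutate(n = n, N = N)
  res <- purrr::pmap_dfr(out, function(category, k, K, n, N) {
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2)
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    or <- (k * (N - n - K + k)) / ((n - k) * (K - k))
    tibble(category = category, k = k, n = n, K = K, N = N,
           odds_ratio = or, p = p)
  })
  res$significant <- res$p < alpha
  arrange(res, .data$p, .data$category)
}

#' Per-species gastric cancer risk (univariate logistic regression)
#'
#' For each species, outcome (cancer vs non-cancer) is regressed on the
#' z-score of `log2(intensity + 1)` (missing intensity treated as 0, i.e.
#' not identified). The odds ratio is `exp` of the coefficient with a Wald
#' 95% confidence interval and Wald p. Species whose fit fails to converge
#' or shows quasi-separation (|coefficient| or standard error blowing up)
#' are flagged with no estimate.
#'
#' @param abundance Species-level quant tibble (`feature_id` = taxon id,
#'   e.g. from [aggregate_quant()]).
#' @param meta Metadata with `sample_id`, `group`.
#' @param conf_level Confidence level (default 0.95).
#' @param standardize Z-score the log2 abundance predictor (default TRUE;
#'   with FALSE the odds ratio is per unit of `log2(intensity + 1)`, which
#'   for a presence/absence pattern at intensity 1 reduces to the classical
#'   2x2 cross-product ratio).
#' @return Object of class `risk_results`: tibble with `taxon_id`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `converged`.
#' @export
species_risk <- function(abundance, meta, conf_level = 0.95, standardize = TRUE) {
  m <- quant_matrix(abundance)
  meta <- check_meta(meta, colnames(m))
  y <- as.integer(setNames(meta$group, meta$sample_id)[colnames(m)] == "cancer")
  if (length(unique(y)) < 2) abort_arg("both outcome classes must be present")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    x <- log2(m[i, ] %na0% 0 + 1)
    if (sd(x) == 0) {
      return(tibble(taxon_id = rownames(m)[i], odds_ratio = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    converged = FALSE))
    }
    z <- if (standardize) (x - mean(x)) / sd(x) else x
    fit <- suppressWarnings(glm(y ~ z, family = binomial()))
    b <- coef(fit)[["z"]]
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[["z"]])
    ok <- fit$converged && is.finite(b) && is.finite(se) && abs(b) < 10 && se < 10
    if (!ok) {
      return(tibble(taxon_id = rownames(m)[i], odds_ratio = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    converged = FALSE))
    }
    tibble(taxon_id = rownames(m)[i], odds_ratio = exp(b),
           ci_low = exp(b - zq * se), ci_high = exp(b + zq * se),
           p = 2 * stats::pnorm(-abs(b / se)), converged = TRUE)
  })
  class(out) <- c("risk_results", class(out))
  out
}

#' Host-microbe Spearman correlation table
#'
#' Spearman rho and p for every (human feature, COG) pair over the samples
#' shared between the two tables (at least 3 required), sorted by
#' decreasing `|rho|`. The p-value uses the t approximation on the rank
#' correlation.
#'
#' @param human_table Quant tibble of selected human features (e.g. the
#'   keratins KRT2/KRT9).
#' @param cog_table COG-aggregated quant tibble.
#' @return Tibble with `human_feature`, `cog`, `rho`, `p`, `n`.
#' @export
host_microbe_correlation <- function(human_table, cog_table) {
  hm <- quant_matrix(human_table)
  cm <- quant_matrix(cog_table)
  shared <- intersect(colnames(hm), colnames(cm))
  if (length(shared) < 3) abort_arg("need at least 3 shared samples")
  hm <- hm[, shared, drop = FALSE]
  cm <- cm[, shared, drop = FALSE]
  grid <- tidyr::expand_grid(human_feature = rownames(hm), cog = rownames(cm))
  out <- purrr::pmap_dfr(grid, function(human_feature, cog) {
    x <- hm[human_feature, ]; y <- cm[cog, ]
    ok <- !is.na(x) & !is.na(y)
    nn <- sum(ok)
    if (nn < 3) return(tibble(human_feature = human_feature, cog = cog,
                              rho = NA_real_, p = NA_real_, n = nn))
    rho <- suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
    p <- if (is.na(rho) || abs(rho) >= 1) {
      if (is.na(rho)) NA_real_ else 0
    } else {
      tt <- rho * sqrt((nn - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = nn - 2)
    }
    tibble(human_feature = human_feature, cog = cog, rho = rho, p = p, n = nn)
  })
  arrange(out, dplyr::desc(abs(.data$rho)))
}
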