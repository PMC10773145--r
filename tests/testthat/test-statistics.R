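test_that("stability correlations hit the metric extremes and stratify by subject", {
  set.seed(51)
  base <- runif(50, 1, 100)
  m <- cbind(a1 = base, a2 = base, b1 = rev(sort(base))[rank(base)])
  # b1 is the rank-reversed copy of a1
  m <- cbind(m, b2 = max(base) + min(base) - base)
  rownames(m) <- sprintf("f%02d", 1:50)
  tbl <- quant_tbl(m)
  meta <- meta_tbl(colnames(m), "non_cancer", subject = c("A", "A", "B", "B"))
  st <- stability_summary(tbl, meta)
  pairs <- attr(st, "pairs")
  expect_equal(pairs$r[pairs$sample_a == "a1" & pairs$sample_b == "a2"], 1.0)
  expect_equal(pairs$r[pairs$sample_a == "a1" & pairs$sample_b == "b2"], -1.0)
  expect_setequal(st$stratum, c("intra_individual", "inter_individual"))
  expect_equal(sum(st$n_pairs), choose(4, 2))

  # pairs with too few shared features are dropped and reported
  m2 <- m
  m2[3:50, "b1"] <- NA
  m2[1:2, ] <- 1:2
  st2 <- stability_summary(quant_tbl(m2), meta)
  expect_true(nrow(attr(st2, "dropped")) > 0)
})

test_that("generated subject effects give intra > inter microbial stability", {
  cfg <- generator_config(seed = 99, n_phyla = 2, genera_per_phylum = 2,
                          species_per_genus = 2, proteins_per_species = 8,
                          human_proteins = 8, risk_or = NULL,
                          n_discriminative = 0, couple_krt_cog = FALSE,
                          n_dep_human = 0, n_dep_microbial = 0)
  ref <- generate_reference(cfg)
  meta <- generate_cohort("time_series")
  sim <- simulate_intensities(ref, meta, cfg, include_peptides = FALSE)
  st <- stability_summary(sim$protein[sim$protein$origin == "microbial", ], meta)
  expect_gt(st$mean_r[st$stratum == "intra_individual"],
            st$mean_r[st$stratum == "inter_individual"])
})

test_that("rank-sum p-values match exact enumeration and flag planted shifts", {
  m <- rbind(feat = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- sprintf("s%d", 1:6)
  tbl <- quant_tbl(m)
  meta <- meta_tbl(colnames(m), rep(c("cancer", "non_cancer"), each = 3))
  dep <- differential_proteins(tbl, meta, min_n = 3)
  expect_equal(dep$p, 0.1)
  expect_equal(dep$p, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(dep$direction, "down")

  # identical distributions are never significant
  set.seed(52)
  x <- runif(10, 10, 20)
  m2 <- rbind(null_feat = c(x, x))
  colnames(m2) <- sprintf("t%02d", 1:20)
  meta2 <- meta_tbl(colnames(m2), rep(c("cancer", "non_cancer"), each = 10))
  dep2 <- differential_proteins(quant_tbl(m2), meta2)
  expect_false(dep2$significant)

  # planted 4-fold shift at n=20/group is recovered
  set.seed(53)
  base <- 2^rnorm(40, 20, 1)
  m3 <- rbind(shifted = c(base[1:20] * 4, base[21:40]),
              flat = 2^rnorm(40, 20, 1))
  colnames(m3) <- sprintf("u%02d", 1:40)
  meta3 <- meta_tbl(colnames(m3), rep(c("cancer", "non_cancer"), each = 20))
  dep3 <- differential_proteins(quant_tbl(m3), meta3)
  expect_true(dep3$significant[dep3$feature_id == "shifted"])
  expect_equal(dep3$log2fc[dep3$feature_id == "shifted"], 2, tolerance = 0.5)

  # skipped features are reported; single-group input errors
  m4 <- rbind(sparse = c(1, NA, NA, NA, NA, 2, 3, 4))
  colnames(m4) <- sprintf("v%d", 1:8)
  meta4 <- meta_tbl(colnames(m4), rep(c("cancer", "non_cancer"), each = 4))
  dep4 <- differential_proteins(quant_tbl(m4), meta4)
  expect_equal(nrow(dep4), 0)
  expect_equal(attr(dep4, "skipped")$feature_id, "sparse")
  expect_error(differential_proteins(quant_tbl(m4),
                                     meta_tbl(colnames(m4), rep("cancer", 8))),
               class = "linguomics_argument_error")
})

test_that("BH adjustment preserves ordering and exact/approx p agree at n=20", {
  set.seed(54)
  m <- matrix(2^rnorm(50 * 20, 20, 1), 50, 20,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%02d", 1:20)))
  meta <- meta_tbl(colnames(m), rep(c("cancer", "non_cancer"), each = 10))
  dep <- differential_proteins(quant_tbl(m), meta)
  expect_true(all(dep$p_adj >= dep$p - 1e-12))
  expect_true(all(dep$p_adj <= 1))
  # monotone in p (BH introduces ties, so compare sorted sequences)
  expect_true(all(diff(dep$p_adj[order(dep$p)]) >= -1e-12))
  # exact vs normal approximation with continuity correction
  for (i in 1:20) {
    x <- m[i, 1:10]; y <- m[i, 11:20]
    pe <- wilcox.test(x, y, exact = TRUE)$p.value
    pa <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  # equal proportions: OR 1, p 1
  cmap <- tibble::tibble(feature_id = sprintf("f%02d", 1:20),
                         category = rep(c("c1", "c2"), each = 10))
  enr <- fisher_enrichment(c(sprintf("f%02d", 1:5), sprintf("f%02d", 11:15)),
                           sprintf("f%02d", 1:20), cmap)
  expect_equal(enr$odds_ratio, c(1, 1))
  expect_equal(enr$p, c(1, 1))

  # foreground entirely inside one category absent elsewhere: minimal p
  cmap2 <- tibble::tibble(feature_id = sprintf("g%02d", 1:15),
                          category = rep(c("hit", "other"), c(5, 10)))
  enr2 <- fisher_enrichment(sprintf("g%02d", 1:5), sprintf("g%02d", 1:15), cmap2)
  hit <- enr2[enr2$category == "hit", ]
  expect_equal(hit$p, oracle_fisher_p(5, 5, 5, 15))
  expect_equal(hit$p, 1 / choose(15, 5))

  # random margins <= 15 agree with exhaustive summation through the
  # set-construction path
  set.seed(55)
  for (i in 1:40) {
    N <- sample(4:15, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    bg <- sprintf("x%02d", 1:N)
    fg <- bg[1:n]
    cm <- tibble::tibble(feature_id = sample(bg, K), category = "cat")
    k <- length(intersect(fg, cm$feature_id))
    enr3 <- fisher_enrichment(fg, bg, cm)
    expect_equal(enr3$p[enr3$category == "cat"], oracle_fisher_p(k, n, K, N),
                 info = sprintf("N=%d n=%d K=%d k=%d", N, n, K, k))
  }
  expect_error(fisher_enrichment("zz", sprintf("x%02d", 1:5),
                                 tibble::tibble(feature_id = "x01", category = "c")),
               class = "linguomics_argument_error")
})

test_that("species risk recovers the cross-product OR for a binary predictor", {
  # 100 cases (20 exposed), 100 controls (10 exposed); exposure coded by
  # intensity 1 (log2(1+1) = 1) vs missing (0)
  samples <- sprintf("p%03d", 1:200)
  group <- rep(c("cancer", "non_cancer"), each = 100)
  exposed <- c(rep(1, 20), rep(NA, 80), rep(1, 10), rep(NA, 90))
  m <- matrix(exposed, 1, 200, dimnames = list("sp1", samples))
  tbl <- quant_tbl(m, origin = "microbial")
  meta <- meta_tbl(samples, group)
  fit <- species_risk(tbl, meta, standardize = FALSE)
  expect_equal(fit$odds_ratio, (20 * 90) / (80 * 10), tolerance = 1e-4)
  expect_true(fit$ci_low <= fit$odds_ratio && fit$odds_ratio <= fit$ci_high)
})

test_that("null species have OR confidence intervals covering 1", {
  for (seed in 1:5) {
    set.seed(seed)
    samples <- sprintf("q%03d", 1:200)
    m <- matrix(2^rnorm(200, 18, 1.5), 1, 200, dimnames = list("sp_null", samples))
    meta <- meta_tbl(samples, rep(c("cancer", "non_cancer"), each = 100))
    fit <- species_risk(quant_tbl(m), meta)
    expect_true(fit$converged)
    expect_true(fit$ci_low <= 1 && 1 <= fit$ci_high,
                info = paste("seed", seed))
  }
})

test_that("degenerate species are flagged without estimates", {
  samples <- sprintf("r%02d", 1:20)
  m <- rbind(constant = rep(5, 20),
             separating = c(rep(100, 10), rep(NA, 10)))
  colnames(m) <- samples
  meta <- meta_tbl(samples, rep(c("cancer", "non_cancer"), each = 10))
  fit <- species_risk(quant_tbl(m), meta)
  expect_false(any(fit$converged))
  expect_true(all(is.na(fit$odds_ratio)))
})

test_that("host-microbe correlation ranks a planted coupled pair first", {
  # monotone transform: rho exactly 1
  set.seed(56)
  h <- matrix(runif(8, 1, 10), 1, 8,
              dimnames = list("KRT_like", sprintf("s%d", 1:8)))
  cg <- rbind(COGA = 2 * h[1, ], COGB = runif(8))
  colnames(cg) <- colnames(h)
  out <- host_microbe_correlation(quant_tbl(h), quant_tbl(cg))
  expect_equal(out$rho[out$cog == "COGA"], 1.0)
  expect_equal(out$cog[1], "COGA")

  # generator-planted coupling leads the ranking
  cfg <- generator_config(seed = 57, n_phyla = 2, genera_per_phylum = 2,
                          species_per_genus = 2, proteins_per_species = 10,
                          human_proteins = 10, risk_or = NULL,
                          n_discriminative = 0, n_dep_human = 0,
                          n_dep_microbial = 0, missingness = 0)
  ref <- generate_reference(cfg)
  meta <- meta_tbl(sprintf("cs%02d", 1:30), rep(c("cancer", "non_cancer"), 15))
  sim <- simulate_intensities(ref, meta, cfg, include_peptides = FALSE)
  truth <- sim$truth$coupled
  cogagg <- aggregate_quant(sim$protein[sim$protein$origin == "microbial", ],
                            "cog")$table
  hum <- sim$protein[sim$protein$feature_id %in% truth$human, ]
  corr <- host_microbe_correlation(hum, cogagg)
  expect_equal(corr$cog[1], truth$cog)
  expect_error(host_microbe_correlation(hum[, 1:4], cogagg[, c(1, 30:31)]),
               class = "linguomics_argument_error")
})

test_that("independent features show the nominal type-I error rate", {
  set.seed(58)
  h <- matrix(rnorm(100 * 2), 2, 100,
              dimnames = list(c("h1", "h2"), sprintf("n%03d", 1:100)))
  cg <- matrix(rnorm(100 * 50), 50, 100,
               dimnames = list(sprintf("c%02d", 1:50), colnames(h)))
  out <- host_microbe_correlation(quant_tbl(h), quant_tbl(cg))
  expect_equal(mean(out$p < 0.05), 0.05, tolerance = 0.04)
})

test_that("Spearman stability is invariant to monotone transforms", {
  set.seed(59)
  m <- matrix(2^rnorm(30 * 4, 15, 2), 30, 4,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:4)))
  meta <- meta_tbl(colnames(m), "non_cancer", subject = c("A", "A", "B", "B"))
  st1 <- stability_summary(quant_tbl(m), meta)
  st2 <- stability_summary(quant_tbl(m^3), meta)          # strictly increasing
  st3 <- stability_summary(quant_tbl(log2(m + 1)), meta)
  expect_equal(attr(st1, "pairs")$r, attr(st2, "pairs")$r)
  expect_equal(attr(st1, "pairs")$r, attr(st3, "pairs")$r)
})
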