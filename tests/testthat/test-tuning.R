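test_that("fold partitions have the promised shape", {
  occ <- occurrence_tbl(lon = runif(20), lat = runif(20))
  f <- partition_presences(occ, "kfold10", seed = 1)
  expect_identical(as.integer(sort(table(f))), rep(2L, 10))
  expect_identical(partition_presences(occ, "kfold10", seed = 1), f)

  quad <- occurrence_tbl(lon = c(-1, 1, -1, 1), lat = c(-1, -1, 1, 1))
  fq <- partition_presences(quad, "spatial_block")
  expect_identical(sort(unique(fq)), 1:4)
  expect_identical(length(unique(fq)), 4L)

  expect_error(partition_presences(occ[1:5, ], "kfold10"), "at least 10")
})

test_that("AUC matches hand examples and the pair-enumeration oracle", {
  expect_equal(auc_mw(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc_mw(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_equal(auc_mw(c(0.5), c(0.5)), 0.5)
  set.seed(21)
  for (i in 1:30) {
    pos <- sample(seq(0, 1, 0.05), sample(2:12, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.05), sample(2:12, 1), replace = TRUE)
    expect_equal(auc_mw(pos, neg), auc_pairs(pos, neg), tolerance = 1e-14)
  }
  expect_error(auc_mw(numeric(0), 1), "non-empty")
})

test_that("TSS follows sensitivity + specificity - 1", {
  expect_equal(tss(10, 0, 10, 0), 1)
  expect_equal(tss(8, 2, 7, 3), 0.5)
  expect_equal(tss(5, 5, 5, 5), 0)
  expect_error(tss(0, 0, 5, 5), "non-empty")
})

test_that("MTSS threshold scans candidates and takes the lowest maximizer", {
  expect_equal(mtss_threshold(rep(0.9, 3), rep(0.1, 4)), 0.9)
  expect_equal(mtss_threshold(c(0.8, 0.6), c(0.5, 0.3)), 0.6)
  # identical score sets: every candidate ties, lowest returned
  expect_equal(mtss_threshold(c(0.2, 0.7), c(0.2, 0.7)), 0.2)
  # property: TSS at the MTSS threshold is maximal over all candidates
  set.seed(31)
  for (i in 1:15) {
    p <- runif(sample(5:20, 1)); b <- runif(sample(5:30, 1))
    t_star <- mtss_threshold(p, b)
    tss_at <- function(t) tss(sum(p >= t), sum(p < t), sum(b < t), sum(b >= t))
    best <- max(vapply(sort(unique(c(p, b))), tss_at, numeric(1)))
    expect_equal(tss_at(t_star), best, tolerance = 1e-12)
  }
})

test_that("omission rate uses the type-7 training quantile", {
  train <- seq(0.1, 1.0, 0.1)
  expect_equal(quantile(train, 0.1, type = 7, names = FALSE), 0.19)
  expect_equal(omission_rate(train, c(0.15, 0.5)), 0.5)
  expect_equal(omission_rate(train, train), 0.1, tolerance = 1 / length(train))
  expect_equal(omission_rate(train, c(1.5, 2)), 0)
})

test_that("AICc matches the closed formula computed independently", {
  f <- small_fit()
  occ10 <- f$occ[1:30, ]
  a <- aicc_maxent(f$fit, f$occ, f$world$stack)
  # independent recomputation from the raw prediction grid
  raw <- predict(f$fit, f$world$stack, output = "raw")
  rc <- cell_index(raw, f$occ$lon, f$occ$lat)
  sc <- raw$values[rc[, 1] + (rc[, 2] - 1L) * nrow(raw$values)]
  lnL <- sum(log(sc / sum(raw$values, na.rm = TRUE)))
  k <- sum(f$fit$beta != 0); n <- nrow(f$occ)
  expect_equal(a, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-10)

  # k = 0 collapses to -2 lnL of the uniform model
  big <- fit_maxent(f$occ, f$bg, f$world$stack, feature_spec("L"), rm = 5000,
                    on_nonconvergence = "warn")
  expect_identical(sum(big$beta != 0), 0L)
  ncells <- sum(!f$world$stack$union_nodata)
  expect_equal(aicc_maxent(big, f$occ, f$world$stack),
               -2 * nrow(f$occ) * log(1 / ncells), tolerance = 1e-8)

  # undefined when n <= k + 1
  inflated <- f$fit
  inflated$beta[] <- 1e-9
  expect_error(aicc_maxent(inflated, occ10[1:12, ], f$world$stack),
               "AICc undefined")
})

test_that("candidate selection applies both criteria with their tie-breaks", {
  single <- tibble::tibble(feature_classes = "L", rm = 1, aicc = 10,
                           or10 = 0.1, mean_test_auc = 0.8)
  expect_identical(select_candidate(single, "aicc_min")$rm, 1)

  seq_tbl <- tibble::tibble(
    feature_classes = c("L", "LQ", "H"), rm = c(1, 2, 3),
    or10 = c(0.05, 0.05, 0.10), mean_test_auc = c(0.8, 0.9, 0.95),
    aicc = c(NA, NA, NA))
  sel <- select_candidate(seq_tbl, "sequential")
  expect_identical(sel$feature_classes, "LQ")
  expect_identical(sel$mean_test_auc, 0.9)

  ties <- tibble::tibble(
    feature_classes = c("LQHPT", "LQ", "L"), rm = c(1.5, 1.5, 3),
    aicc = c(100, 100, 100), or10 = NA, mean_test_auc = NA)
  expect_identical(select_candidate(ties, "aicc_min")$feature_classes, "LQ")

  # the published tuning outcome shape: AICc prefers the complex low-rm
  # model while sequential selection under block CV prefers linear/high-rm
  cand <- tibble::tibble(
    feature_classes = c("LQHPT", "LQHP", "L", "H", "LQ"),
    rm = c(1.5, 2.0, 4.5, 3.5, 1.0),
    aicc = c(3405.2, 3420.9, 3477.3, 3436.0, 3461.8),
    or10 = c(0.16, 0.15, 0.12, 0.14, 0.17),
    mean_test_auc = c(0.80, 0.79, 0.78, 0.76, 0.75))
  a_sel <- select_candidate(cand, "aicc_min")
  expect_identical(c(a_sel$feature_classes, a_sel$rm), c("LQHPT", "1.5"))
  s_sel <- select_candidate(cand, "sequential")
  expect_identical(c(s_sel$feature_classes, s_sel$rm), c("L", "4.5"))
})

test_that("tune_candidates produces coherent per-candidate metrics", {
  f <- small_fit()
  cand <- tune_candidates(f$occ, f$bg, f$world$stack,
                          feature_classes = c("L", "LQ"), rm_values = 1,
                          scheme = "spatial_block", seed = 2)
  expect_identical(nrow(cand), 2L)
  expect_true(all(c("feature_classes", "rm", "cv_scheme", "train_auc",
                    "mean_test_auc", "auc_diff", "or10", "aicc", "k_params")
                  %in% names(cand)))
  expect_equal(cand$auc_diff, cand$train_auc - cand$mean_test_auc,
               tolerance = 1e-12)
  expect_true(all(cand$or10 >= 0 & cand$or10 <= 1))
  expect_true(all(cand$train_auc > 0.5))   # informative world
  sel <- select_candidate(cand, "aicc_min")
  expect_identical(nrow(sel), 1L)
})
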