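#' Cross-validation partitions for presence records
#'
#' `kfold10` assigns random folds of near-equal size; `spatial_block` splits
#' at the median longitude and median latitude into four quadrant folds (the
#' standard block design recommended when models are transferred to new
#' climates).
#'
#' @param presences Occurrence tibble.
#' @param scheme `"kfold10"` or `"spatial_block"`.
#' @param seed Integer seed (used by `kfold10`).
#' @param k Number of folds for `kfold10` (default 10).
#' @return Integer fold id per presence row.
#' @export
partition_presences <- function(presences, scheme = c("kfold10", "spatial_block"),
                                seed = 1, k = 10) {
  scheme <- match.arg(scheme)
  check_occurrences(presences)
  n <- nrow(presences)
  if (scheme == "kfold10") {
    if (n < k) stop(sprintf("need at least %d presences for %d folds", k, k),
                    call. = FALSE)
    with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    if (n < 4L) stop("need at least 4 presences for spatial blocks", call. = FALSE)
    east <- presences$lon > stats::median(presences$lon)
    north <- presences$lat > stats::median(presences$lat)
    1L + as.integer(east) + 2L * as.integer(north)
  }
}

#' Area under the ROC curve, Mann-Whitney form
#'
#' Probability that a random positive score outranks a random negative
#' score, ties counted 1/2 — computed from midranks, exactly equal to
#' brute-force pair counting.
#'
#' @param pos_scores,neg_scores Numeric score vectors (non-empty).
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores)) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  n1 <- length(pos_scores); n2 <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' True Skill Statistic
#'
#' `sensitivity + specificity - 1` from a confusion matrix.
#'
#' @param tp,fn,tn,fp Confusion counts; `tp + fn > 0` and `tn + fp > 0`.
#' @return TSS in [-1, 1].
#' @export
tss <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0) {
    stop("both the positive and the negative class must be non-empty", call. = FALSE)
  }
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Maximum training sensitivity plus specificity threshold
#'
#' Scans the distinct observed scores as candidate thresholds and returns the
#' one maximizing sensitivity (`presence >= t`) plus specificity
#' (`background < t`); ties resolved to the lowest such threshold.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return The MTSS threshold.
#' @export
mtss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  cand <- sort(unique(c(presence_scores, background_scores)))
  ss <- vapply(cand, function(t) {
    mean(presence_scores >= t) + mean(background_scores < t)
  }, numeric(1))
  cand[which.max(ss >= max(ss) - 1e-12)]
}

#' 10% omission rate
#'
#' The training threshold is the linear-interpolated (type-7) 10% quantile of
#' the training presence scores (the value excluding the lowest 10% of
#' training presences); the omission rate is the fraction of test presences
#' scoring strictly below it.
#'
#' @param train_scores,test_scores Numeric score vectors.
#' @param q Omission fraction (default 0.10).
#' @return Omission rate in [0, 1].
#' @export
omission_rate <- function(train_scores, test_scores, q = 0.10) {
  if (!length(train_scores) || !length(test_scores)) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  t <- stats::quantile(train_scores, q, type = 7, names = FALSE)
  mean(test_scores < t)
}

#' Sample-size-corrected AIC for a presence-background model
#'
#' `ln L = sum_presences ln(raw(x) / sum_cells raw)` over the valid cells of
#' the stack; `AICc = 2k - 2 ln L + 2k(k+1)/(n-k-1)` with `k` the number of
#' non-zero coefficients and `n` the presence count. Undefined (error) when
#' `n <= k + 1`.
#'
#' @param model An [fit_maxent()] model.
#' @param presences Occurrence tibble used to fit.
#' @param stack Prediction stack.
#' @return AICc value.
#' @export
aicc_maxent <- function(model, presences, stack) {
  check_occurrences(presences)
  raw <- predict.sdm_maxent(model, stack, output = "raw")
  total <- sum(raw$values, na.rm = TRUE)
  rc <- cell_index(raw, presences$lon, presences$lat)
  sc <- raw$values[rc[, 1] + (rc[, 2] - 1L) * grid_nrow(raw)]
  if (any(is.na(sc))) {
    stop("presence on nodata or outside the stack; cannot score likelihood",
         call. = FALSE)
  }
  n <- nrow(presences)
  k <- sum(model$beta != 0)
  if (n <= k + 1) {
    stop(sprintf("AICc undefined: n = %d presences <= k + 1 = %d", n, k + 1),
         call. = FALSE)
  }
  lnL <- sum(log(sc / total))
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

fc_complexity <- function(fc) {
  order <- c("L", "LQ", "H", "LQH", "LQHP", "LQHPT")
  pos <- match(fc, order)
  ifelse(is.na(pos), length(order) + nchar(fc), pos)
}

#' Select the optimal candidate model
#'
#' `aicc_min` picks the minimum-AICc candidate; `sequential` picks the
#' minimum mean 10% omission rate, then the maximum mean test AUC among the
#' tied. Remaining ties go to the lower regularization multiplier, then the
#' simpler feature set (L < LQ < H < LQH < LQHP < LQHPT).
#'
#' @param results Tibble of candidates with columns `feature_classes`, `rm`,
#'   and `aicc` or `or10` + `mean_test_auc`.
#' @param criterion `"aicc_min"` or `"sequential"`.
#' @return The selected candidate row (one-row tibble).
#' @export
select_candidate <- function(results, criterion = c("aicc_min", "sequential")) {
  criterion <- match.arg(criterion)
  if (!nrow(results)) stop("no candidate models", call. = FALSE)
  r <- dplyr::mutate(results, .cx = fc_complexity(.data$feature_classes))
  r <- if (criterion == "aicc_min") {
    dplyr::arrange(r, .data$aicc, .data$rm, .data$.cx)
  } else {
    dplyr::arrange(r, .data$or10, dplyr::desc(.data$mean_test_auc),
                   .data$rm, .data$.cx)
  }
  dplyr::select(dplyr::slice(r, 1L), -".cx")
}

#' Evaluate a grid of candidate models by cross-validation
#'
#' For each feature-class/regularization-multiplier combination: fits the
#' full-data model (for AICc and training metrics) and one model per
#' cross-validation fold, scoring test presences and the shared background on
#' cloglog output. Fold metrics are averaged (mean over folds, following the
#' usual mean +/- SD reporting of replicated runs).
#'
#' @param presences,background Occurrence tibbles.
#' @param stack Predictor stack.
#' @param feature_classes Character vector of class tags
#'   (subset of `c("L","LQ","H","LQH","LQHP","LQHPT")`).
#' @param rm_values Numeric vector of regularization multipliers.
#' @param scheme Cross-validation scheme, see [partition_presences()].
#' @param seed Integer seed (fold assignment).
#' @param spec_args Extra arguments to [feature_spec()] (knot counts, clamp).
#' @param maxit,tol Optimizer controls passed to [fit_maxent()].
#' @return Tibble, one row per candidate: `feature_classes`, `rm`,
#'   `cv_scheme`, `train_auc`, `mean_test_auc`, `sd_test_auc`, `auc_diff`,
#'   `or10`, `aicc`, `k_params`.
#' @export
tune_candidates <- function(presences, background, stack,
                            feature_classes = c("L", "LQ", "LQH"),
                            rm_values = c(0.5, 1, 2, 4),
                            scheme = "kfold10", seed = 1,
                            spec_args = list(), maxit = 10000, tol = 1e-6) {
  folds <- partition_presences(presences, scheme, seed = seed)
  grid <- tidyr::expand_grid(feature_classes = feature_classes, rm = rm_values)
  purrr::pmap_dfr(grid, function(feature_classes, rm) {
    spec <- do.call(feature_spec, c(list(classes = feature_classes), spec_args))
    full <- fit_maxent(presences, background, stack, spec = spec, rm = rm,
                       maxit = maxit, tol = tol, on_nonconvergence = "warn")
    sc_p <- predict_points(full, stack, presences$lon, presences$lat)
    sc_b <- predict_points(full, stack, background$lon, background$lat)
    ok_b <- !is.na(sc_b)
    train_auc <- auc_mw(sc_p[!is.na(sc_p)], sc_b[ok_b])
    fold_stats <- purrr::map_dfr(sort(unique(folds)), function(f) {
      tr <- presences[folds != f, , drop = FALSE]
      te <- presences[folds == f, , drop = FALSE]
      fit_f <- fit_maxent(tr, background, stack, spec = spec, rm = rm,
                          maxit = maxit, tol = tol, on_nonconvergence = "warn")
      str_ <- predict_points(fit_f, stack, tr$lon, tr$lat)
      ste <- predict_points(fit_f, stack, te$lon, te$lat)
      sbg <- predict_points(fit_f, stack, background$lon, background$lat)
      str_ <- str_[!is.na(str_)]; ste <- ste[!is.na(ste)]; sbg <- sbg[!is.na(sbg)]
      tibble::tibble(test_auc = auc_mw(ste, sbg),
                     or10 = omission_rate(str_, ste))
    })
    tibble::tibble(
      feature_classes = feature_classes, rm = rm, cv_scheme = scheme,
      train_auc = train_auc,
      mean_test_auc = mean(fold_stats$test_auc),
      sd_test_auc = stats::sd(fold_stats$test_auc),
      auc_diff = train_auc - mean(fold_stats$test_auc),
      or10 = mean(fold_stats$or10),
      aicc = aicc_maxent(full, presences, stack),
      k_params = sum(full$beta != 0)
    )
  })
}
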