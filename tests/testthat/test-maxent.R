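test_that("feature expansion matches the hand-computed transforms", {
  rng <- list(x = c(0, 1), y = c(0, 2))
  xm <- cbind(x = 0.5, y = 1.5)

  lin <- expand_features(xm, feature_spec("L"), rng)
  expect_equal(unname(lin$F[1, ]), c(0.5, 0.75))   # y scaled to [0,1]

  qp <- expand_features(xm, feature_spec(c("Q", "P")), rng)
  expect_equal(unname(qp$F[1, qp$meta$class == "Q"]), c(0.25, 0.5625))
  expect_equal(unname(qp$F[1, qp$meta$class == "P"]), 0.5 * 0.75)

  # forward hinge at knot 0.25 on x = 0.5, range [0,1]: (0.5-0.25)/(1-0.25)
  h <- expand_features(cbind(x = 0.5), feature_spec("H", n_hinge_knots = 3),
                       list(x = c(0, 1)))
  hf <- h$F[1, h$meta$feature == "Hf_x_0.2500"]
  expect_equal(unname(hf), (0.5 - 0.25) / 0.75, tolerance = 1e-12)
  hr <- h$F[1, h$meta$feature == "Hr_x_0.7500"]
  expect_equal(unname(hr), (0.75 - 0.5) / 0.75, tolerance = 1e-12)

  th <- expand_features(cbind(x = 0.6), feature_spec("T", n_threshold_knots = 3),
                        list(x = c(0, 1)))
  expect_equal(unname(th$F[1, ]), c(1, 1, 0))      # knots 0.25, 0.5, 0.75

  # clamping truncates to the training range before expansion
  cl <- expand_features(cbind(x = 1.4), feature_spec("LQ", clamp = TRUE),
                        list(x = c(0, 1)))
  cl1 <- expand_features(cbind(x = 1.0), feature_spec("LQ", clamp = TRUE),
                         list(x = c(0, 1)))
  expect_equal(cl$F, cl1$F)

  expect_error(feature_spec("LZ"), "unknown feature class")
  expect_error(feature_spec("H", n_hinge_knots = 1), "n_hinge_knots")
})

test_that("uninformative presences yield no ranking skill and flatten under shrinkage", {
  w <- make_world(32, 40, seed = 77, params = world_params(mask_frac = 0))
  flat <- w
  flat$true_suitability$values[] <- 0.5        # uniform truth
  occ <- sample_occurrences(flat, 120, bias_strength = 0, seed = 1)
  unif <- sdm_grid(matrix(1, 32, 40), flat$bias_field$origin, flat$bias_field$res)
  bg <- sample_background(unif, 700, seed = 2)
  spreads <- vapply(c(1, 4, 16), function(rm) {
    fit <- fit_maxent(occ, bg, w$stack, feature_spec("LQ"), rm = rm,
                      on_nonconvergence = "warn")
    pred <- predict(fit, w$stack)
    if (rm == 1) {
      sp <- predict_points(fit, w$stack, occ$lon, occ$lat)
      sb <- predict_points(fit, w$stack, bg$lon, bg$lat)
      expect_lt(abs(auc_mw(sp, sb) - 0.5), 0.1)   # no ranking skill
    }
    diff(range(pred$values, na.rm = TRUE))
  }, numeric(1))
  # residual noise structure shrinks away as the penalty grows
  expect_true(all(diff(spreads) < 0))
  expect_lt(spreads[3], 0.05)
})

test_that("a one-variable logistic truth is recovered with the right sign", {
  st <- gradient_stack(30)
  v <- st$layers$x$values
  prob <- plogis(2 * (v - 5))
  set.seed(4)
  idx <- sample(length(v), 150, prob = prob)
  rc <- cbind(((idx - 1) %% 30) + 1, ((idx - 1) %/% 30) + 1)
  cc <- cell_center(st$layers$x, rc[, 1], rc[, 2])
  occ <- occurrence_tbl(cc[, 1], cc[, 2])
  bidx <- sample(length(v), 400)
  bcc <- cell_center(st$layers$x, ((bidx - 1) %% 30) + 1, ((bidx - 1) %/% 30) + 1)
  bg <- occurrence_tbl(bcc[, 1], bcc[, 2])
  fit <- fit_maxent(occ, bg, st, feature_spec("L"), rm = 1,
                    on_nonconvergence = "warn")
  expect_gt(fit$beta[["L_x"]], 0)
})

test_that("regularization shrinks: L1 norm non-increasing in rm", {
  f <- small_fit()
  l1 <- vapply(c(0.5, 1, 2, 4, 8), function(rm) {
    sum(abs(fit_maxent(f$occ, f$bg, f$world$stack, feature_spec("LQ"),
                       rm = rm, on_nonconvergence = "warn")$beta))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("raw output is mean-1 over training background; cloglog is its monotone map", {
  f <- small_fit()
  raw <- predict(f$fit, f$world$stack, output = "raw")
  expect_equal(mean(raw$values[f$fit$background_cells]), 1, tolerance = 1e-6)

  cll <- predict(f$fit, f$world$stack, output = "cloglog")
  ok <- !is.na(raw$values)
  expect_true(all(cll$values[ok] >= 0 & cll$values[ok] <= 1))
  # exact transform identity and rank preservation
  expected <- 1 - exp(-exp(f$fit$entropy_H) * raw$values[ok] / f$fit$n_background)
  expect_equal(cll$values[ok], expected, tolerance = 1e-12)
  expect_identical(rank(cll$values[ok]), rank(raw$values[ok]))
  expect_equal(1 - exp(-0), 0)  # raw 0 maps to cloglog 0 by the same identity

  # AUC is invariant under the monotone transform
  rc <- cell_index(raw, f$occ$lon, f$occ$lat)
  pidx <- rc[, 1] + (rc[, 2] - 1L) * nrow(raw$values)
  rb <- cell_index(raw, f$bg$lon, f$bg$lat)
  bidx <- rb[, 1] + (rb[, 2] - 1L) * nrow(raw$values)
  expect_equal(auc_mw(raw$values[pidx], raw$values[bidx]),
               auc_mw(cll$values[pidx], cll$values[bidx]), tolerance = 1e-12)

  expect_error(predict(f$fit, align_stack(f$world$stack$layers["bio1"])),
               "missing model variable")
})

test_that("non-convergence is reported as an error carrying the objective", {
  f <- small_fit()
  expect_error(
    fit_maxent(f$occ, f$bg, f$world$stack, feature_spec("LQ"), rm = 1,
               maxit = 2),
    "did not converge")
})

test_that("permutation contributions sum to 100 and concentrate on the signal", {
  st <- gradient_stack(30)
  noise <- st$layers$x
  set.seed(8)
  noise$values <- matrix(runif(900, 0, 10), 30, 30)
  st2 <- align_stack(list(x = st$layers$x, junk = noise))
  v <- st$layers$x$values
  set.seed(9)
  idx <- sample(length(v), 150, prob = plogis(2 * (v - 5)))
  cc <- cell_center(st$layers$x, ((idx - 1) %% 30) + 1, ((idx - 1) %/% 30) + 1)
  occ <- occurrence_tbl(cc[, 1], cc[, 2])
  bidx <- sample(length(v), 500)
  bcc <- cell_center(st$layers$x, ((bidx - 1) %% 30) + 1, ((bidx - 1) %/% 30) + 1)
  bg <- occurrence_tbl(bcc[, 1], bcc[, 2])
  fit <- fit_maxent(occ, bg, st2, feature_spec("LQ"), rm = 1,
                    on_nonconvergence = "warn")
  pc <- percent_contribution(fit, st2, seed = 1)
  expect_equal(sum(pc$contribution), 100, tolerance = 1e-9)
  expect_gt(pc$contribution[pc$variable == "x"], 90)
  expect_lt(pc$contribution[pc$variable == "junk"], 10)
})

test_that("jackknife gains behave under nesting, redundancy and single-signal truth", {
  st <- gradient_stack(24)
  dup <- st$layers$x
  set.seed(12)
  noise <- st$layers$x
  noise$values <- matrix(runif(576, 0, 10), 24, 24)
  st3 <- align_stack(list(A = st$layers$x, Adup = dup, B = noise))
  v <- st$layers$x$values
  idx <- sample(length(v), 120, prob = plogis(2 * (v - 5)))
  cc <- cell_center(st$layers$x, ((idx - 1) %% 24) + 1, ((idx - 1) %/% 24) + 1)
  occ <- occurrence_tbl(cc[, 1], cc[, 2])
  bidx <- sample(length(v), 400)
  bcc <- cell_center(st$layers$x, ((bidx - 1) %% 24) + 1, ((bidx - 1) %/% 24) + 1)
  bg <- occurrence_tbl(bcc[, 1], bcc[, 2])

  jk <- jackknife_gain(occ, bg, st3, feature_spec("LQ"), rm = 1)
  full <- attr(jk, "full_gain")
  expect_true(all(jk$gain_without <= full + 1e-4))
  # removing either copy of a duplicated informative variable costs ~nothing
  expect_equal(jk$gain_without[jk$variable == "A"], full, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(jk$gain_without[jk$variable == "Adup"], full, tolerance = 0.02,
               ignore_attr = TRUE)
  # the lone informative variable carries (essentially) the full gain
  expect_gt(jk$gain_only[jk$variable == "A"], 0.8 * full)
  expect_lt(jk$gain_only[jk$variable == "B"],
            0.25 * jk$gain_only[jk$variable == "A"])
})

test_that("tidy/glance and JSON serialization round-trip the model", {
  f <- small_fit()
  td <- tidy(f$fit)
  expect_true(all(td$estimate != 0))
  expect_true(all(c("feature", "class", "estimate") %in% names(td)))
  gl <- glance(f$fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$k_nonzero, sum(f$fit$beta != 0))

  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(f$fit, path)
  back <- read_maxent_json(path)
  p1 <- predict(f$fit, f$world$stack)
  p2 <- predict(back, f$world$stack)
  expect_equal(p2$values, p1$values, tolerance = 1e-12)
})
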