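test_that("cost reclassification applies ordered half-open rules", {
  g <- sdm_grid(matrix(c(50, 100, 99.999, NA), 2, 2), c(0, 2), 1)
  rules <- data.frame(from = c(0, 100), to = c(100, Inf), cost = c(1, 1e6))
  cs <- reclassify_cost(g, rules)
  expect_equal(cs$values[1, 1], 1)
  expect_equal(cs$values[2, 1], 1e6)      # boundary value -> upper rule
  expect_equal(cs$values[1, 2], 1)
  expect_true(is.na(cs$values[2, 2]))

  # urban-style barrier: any positive cover is insurmountable
  urban <- sdm_grid(matrix(c(0, 0.1, 55, 100), 2, 2), c(0, 2), 1)
  ur <- reclassify_cost(urban, data.frame(from = c(0, 1e-9), to = c(1e-9, Inf),
                                          cost = c(1, 1e6)))
  expect_equal(as.vector(ur$values), c(1, 1e6, 1e6, 1e6))

  expect_error(reclassify_cost(g, data.frame(from = 0, to = 60, cost = 1)),
               "uncovered")
  expect_error(reclassify_cost(g, data.frame(from = 0, to = Inf, cost = 0.5)),
               "\\[1, 1e6\\]")
})

test_that("suitability-derived costs interpolate log-linearly above MTSS", {
  mtss <- 0.5
  g <- sdm_grid(matrix(c(1.0, mtss - 1e-9, (mtss + 1) / 2, 0.2), 2, 2),
                c(0, 2), 1)
  cs <- suitability_cost(g, mtss)
  expect_equal(cs$values[1, 1], 1)                 # s = 1 -> cost 1
  expect_equal(cs$values[2, 1], 1e6)               # just below threshold
  expect_equal(cs$values[1, 2], round(sqrt(1000))) # log-midpoint ~ 32
  expect_equal(cs$values[2, 2], 1e6)
  # monotone non-increasing in suitability
  s_seq <- seq(mtss, 1, length.out = 50)
  gg <- sdm_grid(matrix(s_seq, 1), c(0, 1), 0.1)
  costs <- suitability_cost(gg, mtss)$values
  expect_true(all(diff(as.vector(costs)) <= 0))
  expect_error(suitability_cost(sdm_grid(matrix(1.2, 1, 1), c(0, 1), 1), 0.5),
               "\\[0, 1\\]")
})

test_that("max-mosaic keeps the most restrictive cost and respects alignment", {
  a <- sdm_grid(matrix(c(1, 50, NA, 2), 2, 2), c(0, 2), 1)
  b <- sdm_grid(matrix(c(1e6, 1, 7, NA), 2, 2), c(0, 2), 1)
  m <- mosaic_max(list(a, b))
  expect_equal(as.vector(m$values), c(1e6, 50, 7, 2))
  expect_equal(mosaic_max(list(a))$values, a$values)
  # permutation invariance
  m2 <- mosaic_max(list(b, a))
  expect_equal(m2$values, m$values)
  c_bad <- sdm_grid(matrix(1, 2, 2), c(0, 2), 0.5)
  expect_error(mosaic_max(list(a, c_bad)), "not aligned")
})

test_that("cost distance reproduces the hand-worked 1-D Dijkstra example", {
  g <- sdm_grid(matrix(c(1, 1, 1e6, 1), 1, 4), c(0, 1), 1)
  src <- occurrence_tbl(lon = 0.5, lat = 0.5)    # center of cell (1,1)
  acc <- cost_distance(g, src)
  expect_equal(as.vector(acc$values), c(0, 1, 500001.5, 1000002))
})

test_that("uniform cost gives the chamfer (sqrt-2 diagonal) grid distance", {
  g <- sdm_grid(matrix(1, 7, 9), c(0, 7), 1)
  src <- occurrence_tbl(lon = 4.5, lat = 3.5)    # cell (4, 5)
  acc <- cost_distance(g, src)
  for (r in 1:7) for (c in 1:9) {
    dr <- abs(r - 4); dc <- abs(c - 5)
    expect_equal(acc$values[r, c], abs(dr - dc) + sqrt(2) * min(dr, dc),
                 tolerance = 1e-12)
  }
})

test_that("multi-source accumulation is the min over single-source runs", {
  set.seed(41)
  g <- sdm_grid(matrix(sample(c(1, 3, 10), 48, replace = TRUE), 6, 8),
                c(0, 6), 1)
  s1 <- occurrence_tbl(0.5, 5.5); s2 <- occurrence_tbl(7.5, 0.5)
  both <- cost_distance(g, dplyr::bind_rows(s1, s2))
  m1 <- cost_distance(g, s1); m2 <- cost_distance(g, s2)
  expect_equal(both$values, pmin(m1$values, m2$values), tolerance = 1e-12)
  expect_error(cost_distance(g, occurrence_tbl(100, 100)), "nodata or outside")
})

test_that("cost distance equals the Bellman-Ford oracle on random grids", {
  set.seed(53)
  for (i in 1:40) {
    nr <- sample(3:9, 1); nc <- sample(3:9, 1)
    v <- matrix(sample(c(1, 2, 5, 50, 1e6), nr * nc, replace = TRUE,
                       prob = c(0.4, 0.2, 0.2, 0.1, 0.1)), nr, nc)
    if (runif(1) < 0.5) v[sample(length(v), ceiling(0.1 * length(v)))] <- NA
    g <- sdm_grid(v, c(0, nr), 1)
    valid <- which(!is.na(v))
    src <- valid[sample(length(valid), sample(1:3, 1))]
    rr <- ((src - 1) %% nr) + 1; cc <- ((src - 1) %/% nr) + 1
    ctr <- cell_center(g, rr, cc)
    acc <- cost_distance(g, occurrence_tbl(ctr[, 1], ctr[, 2]))
    oracle <- bf_cost_distance(v, src)
    expect_equal(acc$values, oracle, tolerance = 1e-9)
  }
})

test_that("accumulated cost is monotone in cell costs", {
  set.seed(67)
  v <- matrix(sample(c(1, 4, 20), 42, replace = TRUE), 6, 7)
  g <- sdm_grid(v, c(0, 6), 1)
  src <- occurrence_tbl(0.5, 5.5)
  base <- cost_distance(g, src)$values
  for (i in 1:10) {
    v2 <- v
    cell <- sample(length(v2), 1)
    v2[cell] <- v2[cell] + sample(c(1, 10, 100), 1)
    up <- cost_distance(sdm_grid(v2, c(0, 6), 1), src)$values
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("Jenks breaks match examples and the exhaustive-partition oracle", {
  br <- jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)
  expect_equal(as.numeric(br), c(3, 12))

  x <- c(4, 1, 9, 7)
  br4 <- jenks_breaks(x, 4)
  expect_equal(as.numeric(br4), sort(x))
  expect_equal(attr(br4, "ssd"), 0)

  set.seed(71)
  for (i in 1:25) {
    n <- sample(6:20, 1); k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < k) next
    got <- jenks_breaks(x, k)
    ora <- jenks_oracle(x, k)
    expect_equal(attr(got, "ssd"), ora$ssd, tolerance = 1e-9)
  }
  expect_error(jenks_breaks(rep(5, 10), 2), "distinct")
})

test_that("binned Jenks stays close to the exact partition", {
  set.seed(73)
  x <- c(rnorm(3000, 10, 1), rnorm(3000, 100, 5))
  exact <- jenks_breaks(x, 4)
  binned <- jenks_breaks(x, 4, bin_limit = 100)
  bin_w <- diff(range(x)) / 1024
  expect_true(all(abs(as.numeric(exact) - as.numeric(binned)) <= 2 * bin_w + 1e-9))
})

test_that("the dispersal-limit mask keeps the lowest cost class and the sources", {
  # bimodal accumulated costs: a tight near cluster (~10) against a
  # dispersed far cluster (~1e6); the seven-class partition spends its
  # splits on the dominant far cluster, so class 1 is the whole near cluster
  set.seed(79)
  acc_v <- matrix(NA_real_, 10, 10)
  acc_v[, 1:5] <- 10 + runif(50, -0.5, 0.5)
  acc_v[, 6:10] <- 1e6 + rnorm(50, sd = 2e4)
  acc <- sdm_grid(acc_v, c(0, 10), 1)
  lim <- limit_mask(acc, 7)
  expect_true(all(lim$mask$values[, 1:5] == 1))
  expect_true(all(lim$mask$values[, 6:10] == 0))
  expect_true(all(acc$values[lim$mask$values == 1] <= lim$threshold))
  expect_identical(length(lim$class_breaks), 7L)

  # source cells (accumulated 0) are always inside the limit
  v <- matrix(sample(c(1, 10, 1e6), 64, replace = TRUE), 8, 8)
  g <- sdm_grid(v, c(0, 8), 1)
  src <- occurrence_tbl(0.5, 7.5)
  acc2 <- cost_distance(g, src)
  lim2 <- limit_mask(acc2, 4)
  rc <- cell_index(acc2, src$lon, src$lat)
  expect_equal(lim2$mask$values[rc[1, 1], rc[1, 2]], 1)
  # uniform accumulated costs cannot be classified
  flat <- sdm_grid(matrix(0, 3, 3), c(0, 3), 1)
  expect_error(limit_mask(flat, 7), "distinct")
})
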