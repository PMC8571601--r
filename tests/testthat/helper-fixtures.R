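# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small synthetic world plus occurrences, background and a fitted LQ model.
small_fit <- function() {
  fixture("small_fit", function() {
    w <- make_world(48, 64, seed = 42)
    occ <- thin_occurrences(sample_occurrences(w, 200, bias_strength = 1,
                                               seed = 7), 1, seed = 3)
    tg <- sample_target_group(w, 1000, seed = 9)
    bias <- density_raster(tg, w$true_suitability, 5)
    bg <- sample_background(bias, 600, seed = 11)
    fit <- fit_maxent(occ, bg, w$stack, feature_spec("LQ"), rm = 1,
                      on_nonconvergence = "warn")
    list(world = w, occ = occ, bg = bg, fit = fit,
         suit = predict(fit, w$stack))
  })
}

# A tiny hand-made one-layer stack on a regular gradient.
gradient_stack <- function(n = 30) {
  vals <- matrix(rep(seq(0, 10, length.out = n), each = n), n, n, byrow = FALSE)
  g <- sdm_grid(vals, origin = c(0, n / 120), res = 1 / 120)
  align_stack(list(x = g))
}

rand_grid <- function(nr, nc, seed, frac_na = 0, origin = c(0, 10), res = 0.01) {
  set.seed(seed)
  v <- matrix(runif(nr * nc), nr, nc)
  if (frac_na > 0) v[sample(length(v), ceiling(frac_na * length(v)))] <- NA
  sdm_grid(v, origin, res)
}
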