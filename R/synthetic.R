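#' Default settings for the synthetic landscape generator
#'
#' The generator emulates the predictor set used for a cold-adapted montane
#' stream salamander: a smooth elevation field, its slope, an annual-mean
#' temperature layer tied to elevation by an atmospheric lapse rate, wettest-
#' and driest-month precipitation, needleleaf and mixed/other forest cover,
#' and a temperature-seasonality layer that is deliberately independent of
#' the species' truth (a known-uninformative control variable). True
#' suitability is a cloglog-linear function of the layers with coefficients
#' `true_beta`; an independent smooth `bias_field` in (0, 1] emulates uneven
#' survey effort.
#'
#' @param kernel_sigma Gaussian smoothing radius (cells) for random fields.
#' @param bias_sigma Smoothing radius (cells) of the sampling-bias field.
#' @param lapse_rate Temperature lapse rate, degC per km of elevation.
#' @param t_base Sea-level temperature at the southern edge, degC.
#' @param lat_gradient degC change per degree of latitude northward (< 0).
#' @param temp_noise_sd sd of unstructured temperature noise, degC.
#' @param mask_frac Fraction of cells masked as nodata ("sea"), in [0, 0.5).
#' @param true_beta Named coefficients of the generating cloglog-linear model
#'   (physical units); `(Intercept)` required.
#' @return A list of generator settings.
#' @export
world_params <- function(kernel_sigma = 6, bias_sigma = 8,
                         lapse_rate = 6.5, t_base = 13,
                         lat_gradient = -1.0, temp_noise_sd = 0.3,
                         mask_frac = 0.05,
                         true_beta = c(
                           `(Intercept)` = -5.1,
                           bio1 = -0.30, bio13 = 0.012, bio14 = 0.05,
                           slope = 0.4, forest_needle = 0.008,
                           forest_mixed = 0.015, bio4 = 0, elevation = 0)) {
  list(kernel_sigma = kernel_sigma, bias_sigma = bias_sigma,
       lapse_rate = lapse_rate, t_base = t_base,
       lat_gradient = lat_gradient, temp_noise_sd = temp_noise_sd,
       mask_frac = mask_frac, true_beta = true_beta,
       origin = c(127, 39), res = 1 / 120,
       temp_layers = "bio1", precip_layers = c("bio13", "bio14"))
}

#' Generate a synthetic world with known truth
#'
#' Builds spatially autocorrelated predictor layers (Gaussian-kernel-smoothed
#' white noise), a known true suitability surface, and a sampling-bias field,
#' all reproducible from `seed`. See [world_params()] for layer semantics.
#'
#' @param n_rows,n_cols Grid dimensions (>= 16).
#' @param seed Integer seed; same seed gives bit-identical worlds.
#' @param params Generator settings from [world_params()].
#' @return An `sdm_world`: list with `stack` ([align_stack()] of 8 layers),
#'   `true_beta`, `true_suitability` ([sdm_grid]), `bias_field` ([sdm_grid]),
#'   `seed`, `params`.
#' @export
make_world <- function(n_rows, n_cols, seed, params = world_params()) {
  if (n_rows < 16 || n_cols < 16) {
    stop("world dimensions must be at least 16 x 16", call. = FALSE)
  }
  p <- params
  org <- p$origin; res <- p$res
  mk <- function(m) sdm_grid(m, org, res)
  lat <- org[2] - (seq_len(n_rows) - 0.5) * res          # per-row center lat
  lat_m <- matrix(lat, n_rows, n_cols)

  with_seed(seed, {
    field <- function(sigma = p$kernel_sigma) {
      std_field(gaussian_smooth(matrix(rnorm(n_rows * n_cols), n_rows),
                                sigma, normalize_edges = TRUE))
    }
    elev_f <- field()
    elevation <- pmax(600 + 400 * elev_f, 0)

    # slope: finite-difference gradient magnitude of elevation, in degrees
    dx_m <- res * 111320 * cos(lat * pi / 180)           # E-W metres per cell
    dy_m <- res * 110540                                 # N-S metres per cell
    gx <- (elevation[, c(2:n_cols, n_cols)] - elevation[, c(1, 1:(n_cols - 1))]) /
      (2 * matrix(dx_m, n_rows, n_cols))
    gy <- (elevation[c(1, 1:(n_rows - 1)), ] - elevation[c(2:n_rows, n_rows), ]) /
      (2 * dy_m)
    slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi

    bio1 <- p$t_base - p$lapse_rate * elevation / 1000 +
      p$lat_gradient * (lat_m - min(lat)) +
      if (p$temp_noise_sd > 0) matrix(rnorm(n_rows * n_cols, sd = p$temp_noise_sd),
                                      n_rows) else 0
    bio13 <- pmax(300 + 60 * std_field(0.5 * elev_f + field()), 50)
    bio14 <- pmax(35 + 8 * std_field(0.3 * elev_f + field()), 5)
    bio4 <- 1000 + 150 * field()                         # independent of truth
    forest_needle <- 100 * stats::plogis(0.8 * elev_f + field())
    forest_mixed <- 100 * stats::plogis(0.6 * elev_f + field())

    layers <- list(elevation = elevation, slope = slope, bio1 = bio1,
                   bio13 = bio13, bio14 = bio14, bio4 = bio4,
                   forest_needle = forest_needle, forest_mixed = forest_mixed)

    # nodata mask from an independent smooth field (irregular "sea" margin)
    if (p$mask_frac > 0) {
      sea <- field(p$kernel_sigma * 1.5)
      cut <- stats::quantile(sea, p$mask_frac)
      nod <- sea <= cut
      layers <- lapply(layers, function(m) { m[nod] <- NA_real_; m })
    }

    stack <- align_stack(lapply(layers, mk))

    beta <- p$true_beta
    eta <- matrix(beta[["(Intercept)"]], n_rows, n_cols)
    for (v in setdiff(names(beta), "(Intercept)")) {
      if (!v %in% names(layers)) {
        stop("true_beta names a missing layer: ", v, call. = FALSE)
      }
      if (beta[[v]] != 0) eta <- eta + beta[[v]] * layers[[v]]
    }
    truth <- cloglog_inv(eta)
    truth[stack$union_nodata] <- NA_real_

    bias <- std_field(gaussian_smooth(matrix(rnorm(n_rows * n_cols), n_rows),
                                      p$bias_sigma, normalize_edges = TRUE))
    bias <- stats::plogis(1.5 * bias)
    bias <- bias / max(bias)
    bias[stack$union_nodata] <- NA_real_

    structure(list(stack = stack, true_beta = beta,
                   true_suitability = mk(truth), bias_field = mk(bias),
                   seed = seed, params = p),
              class = "sdm_world")
  })
}

#' @export
print.sdm_world <- function(x, ...) {
  cat(sprintf("<sdm_world> seed %d\n", x$seed))
  print(x$stack)
  invisible(x)
}

#' Sample presence records from a synthetic world
#'
#' Presence cells are drawn without replacement with probability proportional
#' to `true_suitability * bias_field^bias_strength`; each point is jittered
#' uniformly within its cell. `bias_strength = 0` samples proportionally to
#' suitability alone.
#'
#' @param world An [make_world()] world.
#' @param n Number of presences (>= 1).
#' @param bias_strength Exponent on the bias field, >= 0.
#' @param seed Integer seed.
#' @return Occurrence tibble (`species`, `lon`, `lat`).
#' @export
sample_occurrences <- function(world, n, bias_strength = 1, seed = 1) {
  stopifnot(n >= 1, bias_strength >= 0)
  s <- world$true_suitability$values
  b <- world$bias_field$values
  w <- as.vector(s * b^bias_strength)
  w[is.na(w)] <- 0
  pos <- sum(w > 0)
  if (n > pos) {
    stop(sprintf("n = %d exceeds the %d cells with positive weight", n, pos),
         call. = FALSE)
  }
  g <- world$true_suitability
  with_seed(seed, {
    idx <- sample.int(length(w), n, replace = FALSE, prob = w)
    row <- ((idx - 1L) %% nrow(s)) + 1L
    col <- ((idx - 1L) %/% nrow(s)) + 1L
    lon <- g$origin[1] + (col - 1L + runif(n)) * g$res
    lat <- g$origin[2] - (row - 1L + runif(n)) * g$res
    occurrence_tbl(lon, lat, "focal")
  })
}

#' Sample multi-species target-group records sharing the survey bias
#'
#' Emulates records of co-surveyed species: cells drawn with replacement
#' proportionally to the survey-effort bias field alone (not the focal
#' species' suitability), with uniformly assigned species labels. Use the
#' same `bias_strength` as in [sample_occurrences()] so the target group
#' shares the focal data's sampling bias — the premise of target-group
#' background correction.
#'
#' @param world An [make_world()] world.
#' @param n Number of records.
#' @param n_species Number of species labels.
#' @param bias_strength Exponent on the bias field, >= 0.
#' @param seed Integer seed.
#' @return Occurrence tibble (`species`, `lon`, `lat`).
#' @export
sample_target_group <- function(world, n, n_species = 8, bias_strength = 1,
                                seed = 1) {
  stopifnot(n >= 1, bias_strength >= 0)
  b <- as.vector(world$bias_field$values)^bias_strength
  b[is.na(b)] <- 0
  g <- world$bias_field
  with_seed(seed, {
    idx <- sample.int(length(b), n, replace = TRUE, prob = b)
    row <- ((idx - 1L) %% grid_nrow(g)) + 1L
    col <- ((idx - 1L) %/% grid_nrow(g)) + 1L
    lon <- g$origin[1] + (col - 1L + runif(n)) * g$res
    lat <- g$origin[2] - (row - 1L + runif(n)) * g$res
    occurrence_tbl(lon, lat, paste0("sp", sample.int(n_species, n, replace = TRUE)))
  })
}

#' Build a future-scenario layer stack
#'
#' Temperature-like layers are shifted additively by `delta_T`;
#' precipitation-like layers are scaled by `precip_scale`; topography and
#' land cover are held constant (bit-identical to the current stack).
#'
#' @param world An [make_world()] world.
#' @param delta_T Additive temperature change, degC.
#' @param precip_scale Multiplicative precipitation change, > 0.
#' @return An [align_stack()] stack with the same layers as `world$stack`.
#' @export
make_scenario <- function(world, delta_T, precip_scale = 1) {
  stopifnot(precip_scale > 0)
  p <- world$params
  layers <- world$stack$layers
  for (v in p$temp_layers) layers[[v]]$values <- layers[[v]]$values + delta_T
  for (v in p$precip_layers) layers[[v]]$values <- layers[[v]]$values * precip_scale
  align_stack(layers)
}

#' True suitability under a scenario stack
#'
#' Evaluates the world's generating model on an arbitrary (aligned) stack,
#' e.g. a [make_scenario()] stack, giving the ground-truth suitability that a
#' fitted model's projection can be compared against.
#'
#' @param world An [make_world()] world.
#' @param stack A stack with the world's layers (default: current).
#' @return An [sdm_grid] of true suitability in [0, 1].
#' @export
true_suitability <- function(world, stack = world$stack) {
  beta <- world$true_beta
  eta <- matrix(beta[["(Intercept)"]], nrow(dim_or(stack)), ncol(dim_or(stack)))
  for (v in setdiff(names(beta), "(Intercept)")) {
    if (beta[[v]] != 0) eta <- eta + beta[[v]] * stack$layers[[v]]$values
  }
  out <- cloglog_inv(eta)
  out[stack$union_nodata] <- NA_real_
  g <- stack$layers[[1]]
  sdm_grid(out, g$origin, g$res, g$crs)
}

dim_or <- function(stack) stack$layers[[1]]$values
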