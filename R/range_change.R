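#' Binary habitat map from suitability, threshold and dispersal limit
#'
#' A cell is suitable when suitability `>= threshold` (closed lower bound)
#' AND it lies inside the dispersal limit; nodata cells are 0.
#'
#' @param suitability An [sdm_grid] of cloglog suitability.
#' @param threshold Threshold in (0, 1): the MTSS for "suitable", 0.8 for
#'   "optimal" habitat.
#' @param limit An [limit_mask()] dispersal limit (or `NULL` to skip the
#'   dispersal crop).
#' @return An [sdm_grid] of 0/1 (nodata preserved as `NA`).
#' @export
binarize <- function(suitability, threshold, limit = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  v <- suitability$values
  out <- as.numeric(!is.na(v) & v >= threshold)
  out <- matrix(out, nrow(v), ncol(v))
  if (!is.null(limit)) {
    if (!same_geometry(suitability, limit$mask)) {
      stop("dispersal limit is not aligned with the suitability grid", call. = FALSE)
    }
    out <- out * ifelse(is.na(limit$mask$values), 0, limit$mask$values)
  }
  out[is.na(v)] <- NA_real_
  sdm_grid(out, suitability$origin, suitability$res, suitability$crs)
}

#' Percent decrease of habitat area
#'
#' `100 * (current - future) / current`, reported to one decimal (the
#' resolution used for range-contraction statements).
#'
#' @param current_km2 Current area (> 0).
#' @param future_km2 Future area (>= 0).
#' @return Percent decrease, rounded to one decimal.
#' @export
pct_decrease <- function(current_km2, future_km2) {
  if (any(current_km2 <= 0)) stop("current area must be positive", call. = FALSE)
  round(100 * (current_km2 - future_km2) / current_km2, 1)
}

#' Mann-Whitney U test (two-sided)
#'
#' `W` is the Mann-Whitney U statistic of `x` versus `y` (number of pairs
#' with `x > y`, ties counted 1/2). The p-value is exact where feasible —
#' full enumeration of group assignments when `n_x + n_y <= 18` (valid under
#' ties), the exact null distribution (`pwilcox`) when tie-free and both
#' samples have at most 50 values — and otherwise uses the normal
#' approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @return List `W`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  N <- n1 + n2
  if (N <= 18) {
    # exact permutation null by enumeration of all assignments (handles ties)
    combos <- utils::combn(N, n1)
    rs <- colSums(matrix(r[combos], nrow = n1))
    Us <- rs - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    method <- "exact enumeration"
  } else if (!ties && max(n1, n2) <= 50) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    method <- "exact distribution"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(W = U, p = p, method = method)
}

#' Elevational shift between two binary range maps
#'
#' Compares the elevations of all suitable cells under the current map
#' against a future map with a two-sided Mann-Whitney U test; `direction` is
#' the sign of (median future elevation - median current elevation),
#' positive = upslope shift.
#'
#' @param current_binary,future_binary Binary [sdm_grid]s ([binarize()]).
#' @param elevation Aligned elevation [sdm_grid].
#' @return List `W`, `p`, `direction`, `median_current`, `median_future`.
#' @export
elevation_shift_test <- function(current_binary, future_binary, elevation) {
  if (!same_geometry(current_binary, elevation) ||
      !same_geometry(future_binary, elevation)) {
    stop("elevation grid is not aligned with the binary maps", call. = FALSE)
  }
  e_cur <- elevation$values[current_binary$values == 1 & !is.na(current_binary$values)]
  e_fut <- elevation$values[future_binary$values == 1 & !is.na(future_binary$values)]
  e_cur <- e_cur[!is.na(e_cur)]; e_fut <- e_fut[!is.na(e_fut)]
  if (!length(e_cur) || !length(e_fut)) {
    stop("one of the binary maps is empty", call. = FALSE)
  }
  mw <- mann_whitney_u(e_fut, e_cur)
  list(W = mw$W, p = mw$p,
       direction = sign(stats::median(e_fut) - stats::median(e_cur)),
       median_current = stats::median(e_cur),
       median_future = stats::median(e_fut))
}

#' Scenario summary table of suitable and optimal habitat
#'
#' For each scenario: binarizes suitability at that scenario's own MTSS
#' threshold (suitable habitat) and at the optimal threshold (default 0.8),
#' crops by that scenario's dispersal limit, sums spherical cell areas, and
#' computes percent decrease versus the `"current"` scenario plus the
#' elevational Mann-Whitney shift test of suitable-cell elevations against
#' current (p-values reported raw, uncorrected).
#'
#' @param scenarios Named list of suitability [sdm_grid]s; must contain
#'   `"current"`.
#' @param limits Named list of [limit_mask()] limits (same names), or `NULL`.
#' @param mtss Named numeric vector of per-scenario MTSS thresholds (a single
#'   unnamed value is recycled).
#' @param elevation Elevation [sdm_grid].
#' @param optimal_threshold Optimal-habitat threshold (default 0.8).
#' @return Tibble with columns `scenario`, `suitable_km2`,
#'   `pct_dec_suitable`, `optimal_km2`, `pct_dec_optimal`, `W`, `p`.
#' @export
summarize_scenarios <- function(scenarios, limits = NULL, mtss, elevation,
                                optimal_threshold = 0.8) {
  if (!"current" %in% names(scenarios)) {
    stop("`scenarios` must contain a \"current\" entry", call. = FALSE)
  }
  ids <- c("current", setdiff(names(scenarios), "current"))
  if (is.null(names(mtss))) mtss <- stats::setNames(rep_len(mtss, length(ids)), ids)
  bin <- lapply(ids, function(id) {
    lim <- if (is.null(limits)) NULL else limits[[id]]
    list(suit = binarize(scenarios[[id]], mtss[[id]], lim),
         opt = binarize(scenarios[[id]], optimal_threshold, lim))
  })
  names(bin) <- ids
  cur_s <- area_km2(bin$current$suit); cur_o <- area_km2(bin$current$opt)
  purrr::map_dfr(ids, function(id) {
    s_km2 <- area_km2(bin[[id]]$suit); o_km2 <- area_km2(bin[[id]]$opt)
    if (id == "current") {
      tibble::tibble(scenario = id, suitable_km2 = s_km2, pct_dec_suitable = 0,
                     optimal_km2 = o_km2, pct_dec_optimal = 0,
                     W = NA_real_, p = NA_real_)
    } else {
      shift <- elevation_shift_test(bin$current$suit, bin[[id]]$suit, elevation)
      tibble::tibble(scenario = id, suitable_km2 = s_km2,
                     pct_dec_suitable = pct_decrease(cur_s, s_km2),
                     optimal_km2 = o_km2,
                     pct_dec_optimal = if (cur_o > 0) pct_decrease(cur_o, o_km2) else NA_real_,
                     W = shift$W, p = shift$p)
    }
  })
}

#' Published area estimates bundled with the package
#'
#' Published per-scenario binary habitat-area estimates for the Korean
#' clawed salamander (*Onychodactylus koreanus*) under CCSM4 climate
#' scenarios: current suitable and optimal areas within dispersal limits and
#' the corresponding areas for 2050/2070 under RCP 2.6/4.5/6.0/8.5, used to
#' recompute percent range contraction.
#'
#' @return Tibble `scenario`, `year`, `suitable_km2`, `optimal_km2`
#'   (`year = NA` for the current row).
#' @export
published_area_table <- function() {
  path <- system.file("extdata", "okoreanus_habitat_areas.csv",
                      package = "sdmshift", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
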