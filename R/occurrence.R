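#' Spatial thinning of occurrence records
#'
#' Enforces a minimum pairwise great-circle (haversine) distance between
#' retained records, the standard pre-processing step that reduces spatial
#' clustering (and hence sampling bias) in presence-only data. Each
#' randomized pass iteratively deletes one record (uniformly at random) from
#' those with the largest number of remaining conflicts until no pair is
#' closer than `min_distance_km`, then greedily re-adds any deleted record
#' that is conflict-free against the survivors (so the result is a maximal
#' independent set of the conflict graph). Among `n_repeats` passes the one
#' retaining the most records is returned; ties go to the earliest pass, so
#' the result is deterministic given `seed`.
#'
#' @param occurrences Occurrence tibble (`lon`, `lat`, optional `species`).
#' @param min_distance_km Minimum pairwise distance, km (> 0).
#' @param seed Integer seed.
#' @param n_repeats Number of randomized passes (>= 1).
#' @return The retained subset of `occurrences` (row order preserved).
#' @export
thin_occurrences <- function(occurrences, min_distance_km, seed = 1,
                             n_repeats = 10) {
  check_occurrences(occurrences)
  stopifnot(min_distance_km > 0, n_repeats >= 1)
  n <- nrow(occurrences)
  if (n == 1L) return(occurrences)
  pts <- cbind(occurrences$lon, occurrences$lat)
  d <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  conflict <- d < min_distance_km
  diag(conflict) <- FALSE
  if (!any(conflict)) return(occurrences)

  run_pass <- function() {
    keep <- rep(TRUE, n)
    deg <- rowSums(conflict)
    while (any(deg[keep] > 0)) {
      cand <- which(keep & deg == max(deg[keep]))
      drop <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      keep[drop] <- FALSE
      nb <- which(conflict[drop, ] & keep)
      deg[nb] <- deg[nb] - 1L
      deg[drop] <- 0L
    }
    # maximality repair: re-add dropped points with no conflict to survivors
    for (i in which(!keep)) {
      if (!any(conflict[i, keep])) keep[i] <- TRUE
    }
    keep
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_repeats)) {
      keep <- run_pass()
      if (is.null(best) || sum(keep) > sum(best)) best <- keep
    }
    occurrences[best, , drop = FALSE]
  })
}

#' Sampling-effort density raster from target-group records
#'
#' Converts target-group occurrence records (all co-surveyed species) into a
#' per-cell density surface: raw per-cell record counts smoothed by a
#' Gaussian kernel of width `kernel_sigma_cells`. The result is the bias
#' raster used to draw background points with the same spatial sampling bias
#' as the presence data.
#'
#' @param target_group Occurrence tibble of target-group records.
#' @param template An [sdm_grid] defining geometry and nodata.
#' @param kernel_sigma_cells Gaussian kernel sd in cells (>= 0; 0 = raw
#'   counts). Default 5.
#' @return An [sdm_grid] of non-negative densities (nodata cells zeroed, grid
#'   nodata preserved as `NA`).
#' @export
density_raster <- function(target_group, template, kernel_sigma_cells = 5) {
  check_occurrences(target_group)
  stopifnot(kernel_sigma_cells >= 0)
  rc <- cell_index(template, target_group$lon, target_group$lat)
  ok <- !is.na(rc[, 1])
  counts <- matrix(0, grid_nrow(template), grid_ncol(template))
  if (any(ok)) {
    idx <- rc[ok, 1] + (rc[ok, 2] - 1L) * grid_nrow(template)
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  dens <- gaussian_smooth(counts, kernel_sigma_cells)
  dens[dens < 0] <- 0
  dens[nodata_mask(template)] <- NA_real_
  sdm_grid(dens, template$origin, template$res, template$crs)
}

#' Sample background points from a bias raster
#'
#' Draws `n` distinct cells without replacement with probability proportional
#' to the bias value and places one point at each drawn cell's center
#' (predictors are constant within a cell, so sub-cell placement is
#' immaterial). Deterministic given `seed`.
#'
#' @param bias An [sdm_grid] of non-negative weights (e.g. from
#'   [density_raster()]).
#' @param n Number of background points.
#' @param seed Integer seed.
#' @return Occurrence tibble (`species = "background"`, `lon`, `lat`).
#' @export
sample_background <- function(bias, n, seed = 1) {
  stopifnot(n >= 1)
  w <- as.vector(bias$values)
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("bias raster has negative weights", call. = FALSE)
  avail <- sum(w > 0)
  if (avail < n) {
    stop(sprintf("requested %d background cells but only %d have positive weight",
                 n, avail), call. = FALSE)
  }
  with_seed(seed, {
    idx <- sample.int(length(w), n, replace = FALSE, prob = w)
    row <- ((idx - 1L) %% grid_nrow(bias)) + 1L
    col <- ((idx - 1L) %/% grid_nrow(bias)) + 1L
    cc <- cell_center(bias, row, col)
    occurrence_tbl(cc[, 1], cc[, 2], "background")
  })
}
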