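#' @importFrom rlang .data
#' @importFrom stats cor median pnorm quantile rnorm runif sd setNames
#' @importFrom utils head
#' @importFrom tibble as_tibble
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps every stochastic operation
# explicitly seeded with no hidden global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Separable Gaussian smoothing of a matrix by band-matrix multiplication.
# Kernel truncated at 4 sigma and normalized to sum 1 (zero padding outside
# the matrix). With normalize_edges = TRUE the result is divided by the
# smoothed all-ones matrix, removing edge attenuation (used for random-field
# generation); with FALSE total mass is conserved for interior sources (used
# for density rasters).
gaussian_smooth <- function(m, sigma, normalize_edges = FALSE) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (d in (-r):r) {
      i <- seq_len(n)
      j <- i + d
      keep <- j >= 1L & j <= n
      B[cbind(i[keep], j[keep])] <- k[d + r + 1L]
    }
    B
  }
  Br <- band(nrow(m)); Bc <- band(ncol(m))
  out <- Br %*% m %*% t(Bc)
  if (normalize_edges) {
    w <- Br %*% matrix(1, nrow(m), ncol(m)) %*% t(Bc)
    out <- out / w
  }
  out
}

# Standardize a matrix to mean 0, sd 1 (population sd over all cells).
std_field <- function(m) {
  mu <- mean(m); s <- stats::sd(as.vector(m))
  if (s == 0) m - mu else (m - mu) / s
}

# Complementary log-log inverse link: eta -> [0, 1).
cloglog_inv <- function(eta) 1 - exp(-exp(eta))

# Build an occurrence tibble (the package-wide occurrence representation:
# one row per record, columns species/lon/lat).
occurrence_tbl <- function(lon, lat, species = "focal") {
  stopifnot(length(lon) == length(lat))
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("occurrence coordinates must be finite", call. = FALSE)
  }
  tibble::tibble(species = rep_len(species, length(lon)), lon = lon, lat = lat)
}

check_occurrences <- function(occ) {
  if (!is.data.frame(occ) || !all(c("lon", "lat") %in% names(occ))) {
    stop("occurrences must be a data frame with `lon` and `lat` columns",
         call. = FALSE)
  }
  if (nrow(occ) < 1L) stop("need at least one occurrence", call. = FALSE)
  if (any(!is.finite(occ$lon)) || any(!is.finite(occ$lat))) {
    stop("occurrence coordinates must be finite", call. = FALSE)
  }
  invisible(occ)
}
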