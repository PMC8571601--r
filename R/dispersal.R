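#' Reclassify a layer into a dispersal-cost surface
#'
#' Maps layer values to traversal costs through ordered half-open rules
#' `[from, to) -> cost` (first matching rule wins). Costs follow the
#' landscape-resistance convention for this analysis: 1 = freely permeable
#' (e.g. closed forest), 1,000,000 = insurmountable barrier coded by
#' magnitude (e.g. urban areas, lakes) rather than nodata, so barriers stay
#' traversable at astronomical cost and never disconnect the graph.
#'
#' @param layer An [sdm_grid].
#' @param rules Data frame with columns `from`, `to`, `cost` (half-open
#'   intervals `[from, to)`, costs in `[1, 1e6]`).
#' @return An [sdm_grid] of costs (class also `sdm_cost`).
#' @export
reclassify_cost <- function(layer, rules) {
  stopifnot(all(c("from", "to", "cost") %in% names(rules)))
  if (any(rules$cost < 1 | rules$cost > 1e6)) {
    stop("costs must lie in [1, 1e6]", call. = FALSE)
  }
  v <- layer$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  todo <- !is.na(v)
  for (i in seq_len(nrow(rules))) {
    hit <- todo & v >= rules$from[i] & v < rules$to[i]
    out[hit] <- rules$cost[i]
    todo <- todo & !hit
  }
  if (any(todo)) {
    stop(sprintf("cost rules leave value %g uncovered", v[which(todo)[1]]),
         call. = FALSE)
  }
  g <- sdm_grid(out, layer$origin, layer$res, layer$crs)
  class(g) <- c("sdm_cost", class(g))
  g
}

#' Cost surface from a suitability map
#'
#' Cells below the suitability threshold (MTSS) are barriers (cost
#' 1,000,000: unsuitable habitat is treated as impermeable to dispersal).
#' From the threshold up, cost decreases geometrically (log-linear in
#' suitability) from `cost_at_threshold` down to 1 at suitability 1, then is
#' rounded to the nearest integer — so cost is non-increasing in
#' suitability.
#'
#' @param suitability An [sdm_grid] with values in [0, 1].
#' @param mtss Suitability threshold in (0, 1).
#' @param cost_at_threshold Cost at `s = mtss` (default 1000).
#' @return An [sdm_grid] cost surface.
#' @export
suitability_cost <- function(suitability, mtss, cost_at_threshold = 1000) {
  stopifnot(mtss > 0, mtss < 1, cost_at_threshold >= 1)
  s <- suitability$values
  if (any(s < 0 | s > 1, na.rm = TRUE)) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  frac <- (s - mtss) / (1 - mtss)
  cost <- round(exp(log(cost_at_threshold) * (1 - frac)))
  cost[s < mtss] <- 1e6
  cost[is.na(s)] <- NA_real_
  g <- sdm_grid(cost, suitability$origin, suitability$res, suitability$crs)
  class(g) <- c("sdm_cost", class(g))
  g
}

#' Cellwise-maximum mosaic of cost surfaces
#'
#' Merges aligned cost surfaces by taking the maximum cost at each cell (the
#' most restrictive layer wins); a cell is nodata only where every input is
#' nodata.
#'
#' @param surfaces List of aligned [sdm_grid] cost surfaces.
#' @return An [sdm_grid] cost surface.
#' @export
mosaic_max <- function(surfaces) {
  if (!length(surfaces)) stop("need at least one cost surface", call. = FALSE)
  ref <- surfaces[[1]]
  for (s in surfaces[-1]) {
    if (!same_geometry(ref, s)) stop("cost surfaces are not aligned", call. = FALSE)
  }
  arr <- vapply(surfaces, function(s) s$values, ref$values)
  dim(arr) <- c(length(ref$values), length(surfaces))
  out <- apply(arr, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  g <- sdm_grid(matrix(out, nrow(ref$values)), ref$origin, ref$res, ref$crs)
  class(g) <- c("sdm_cost", class(g))
  g
}

#' Least-accumulative-cost distance from source points
#'
#' Multi-source shortest path over the 8-connected grid graph with the
#' ArcGIS-style step cost `(cost_a + cost_b) / 2` between adjacent cells,
#' multiplied by `sqrt(2)` for diagonal moves. Source cells get 0; nodata
#' cells are non-traversable and unreachable cells get `Inf`.
#'
#' @param cost An [sdm_grid] of per-cell costs (all valid cells >= 1).
#' @param sources Occurrence tibble of source points.
#' @return An [sdm_grid] of accumulated costs (`Inf` = unreachable,
#'   `NA` = nodata).
#' @export
cost_distance <- function(cost, sources) {
  check_occurrences(sources)
  v <- cost$values
  if (any(v < 1, na.rm = TRUE)) stop("cell costs must be >= 1", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  vid <- matrix(NA_integer_, nr, nc)
  vid[valid] <- seq_len(sum(valid))
  # edges: right, down, down-right, down-left neighbours (each pair once)
  edge_set <- function(dr, dc) {
    r <- seq_len(nr - max(dr, 0) + min(dr, 0) * 0)  # rows with a neighbour
    rows <- seq_len(nr); cols <- seq_len(nc)
    rA <- rows[rows + dr >= 1 & rows + dr <= nr]
    cA <- cols[cols + dc >= 1 & cols + dc <= nc]
    if (!length(rA) || !length(cA)) return(NULL)
    A <- as.matrix(expand.grid(r = rA, c = cA))
    B <- cbind(r = A[, 1] + dr, c = A[, 2] + dc)
    ia <- A[, 1] + (A[, 2] - 1L) * nr
    ib <- B[, 1] + (B[, 2] - 1L) * nr
    keep <- valid[ia] & valid[ib]
    if (!any(keep)) return(NULL)
    ia <- ia[keep]; ib <- ib[keep]
    w <- (v[ia] + v[ib]) / 2 * if (dr != 0 && dc != 0) sqrt(2) else 1
    cbind(from = vid[ia], to = vid[ib], weight = w)
  }
  edges <- do.call(rbind, Filter(Negate(is.null),
                                 list(edge_set(0L, 1L), edge_set(1L, 0L),
                                      edge_set(1L, 1L), edge_set(1L, -1L))))
  rc <- cell_index(cost, sources$lon, sources$lat)
  sidx <- rc[, 1] + (rc[, 2] - 1L) * nr
  sidx <- unique(sidx[!is.na(sidx) & valid[sidx]])
  if (!length(sidx)) stop("all source points fall on nodata or outside the grid",
                          call. = FALSE)
  n_v <- sum(valid)
  g <- igraph::make_empty_graph(n = n_v, directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(edges[, "from"], edges[, "to"]),
                           weight = edges[, "weight"])
  }
  d <- igraph::distances(g, v = vid[sidx], algorithm = "dijkstra")
  acc <- apply(d, 2L, min)
  out <- matrix(NA_real_, nr, nc)
  out[valid] <- acc
  g_out <- sdm_grid(ifelse(is.infinite(out), NA_real_, out),
                    cost$origin, cost$res, cost$crs)
  g_out$values[valid & is.na(g_out$values)] <- Inf
  # sdm_grid() rejects non-finite values, so re-insert Inf after validation
  out[valid] <- acc
  g_out$values <- out
  g_out
}

#' Jenks natural breaks (Fisher exact dynamic program)
#'
#' Partitions sorted values into `n_classes` contiguous classes minimizing
#' the total within-class sum of squared deviations. Exact weighted dynamic
#' program; when more than `bin_limit` finite values are supplied they are
#' first binned into a 1024-bin histogram (documented approximation for
#' large rasters).
#'
#' @param values Numeric vector (>= `n_classes` distinct finite values).
#' @param n_classes Number of classes.
#' @param bin_limit Above this many values, switch to binned DP.
#' @return Ascending upper bounds of the classes (length `n_classes`; the
#'   last equals `max(values)`). Attribute `"ssd"` carries the objective.
#' @export
jenks_breaks <- function(values, n_classes, bin_limit = 1e5) {
  x <- values[is.finite(values)]
  if (length(unique(x)) < n_classes) {
    stop(sprintf("need at least %d distinct finite values", n_classes),
         call. = FALSE)
  }
  if (length(x) > bin_limit) {
    br <- seq(min(x), max(x), length.out = 1025)
    mid <- (br[-1] + br[-1025]) / 2
    w <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), 1024), 1024)
    keep <- w > 0
    v <- mid[keep]; w <- w[keep]
  } else {
    v <- sort(unique(x))
    w <- tabulate(match(x, v), length(v))
  }
  n <- length(v); k <- n_classes
  cw <- cumsum(w); cwx <- cumsum(w * v); cwx2 <- cumsum(w * v^2)
  # ssd of v[i..j] weighted
  seg_cost <- function(i, j) {   # vectorized over i for fixed j
    W <- cw[j] - ifelse(i > 1, cw[i - 1], 0)
    S <- cwx[j] - ifelse(i > 1, cwx[i - 1], 0)
    S2 <- cwx2[j] - ifelse(i > 1, cwx2[i - 1], 0)
    S2 - S^2 / W
  }
  D <- matrix(Inf, k, n); idx <- matrix(0L, k, n)
  D[1, ] <- vapply(seq_len(n), function(j) seg_cost(1, j), numeric(1))
  if (k > 1) for (m in 2:k) {
    for (j in m:n) {
      i <- m:j                       # class m starts at i
      tot <- D[m - 1, i - 1] + seg_cost(i, j)
      best <- which.min(tot)
      D[m, j] <- tot[best]; idx[m, j] <- i[best]
    }
  }
  # backtrack class boundaries
  ub <- numeric(k); j <- n
  for (m in k:1) {
    ub[m] <- v[j]
    if (m > 1) j <- idx[m, j] - 1L
  }
  structure(ub, ssd = D[k, n])
}

#' Dispersal-limit mask from accumulated cost
#'
#' Classifies the finite accumulated-cost values by Jenks natural breaks
#' (default 7 classes) and marks as reachable the cells whose accumulated
#' cost falls in the lowest class (at most the class-1 upper bound).
#' Unreachable (`Inf`) and nodata cells are always `FALSE`; source cells
#' (accumulated 0) are always `TRUE`.
#'
#' @param accumulated [sdm_grid] from [cost_distance()].
#' @param n_classes Number of Jenks classes (default 7).
#' @return An `sdm_dispersal_limit`: list with `mask` ([sdm_grid] of 0/1),
#'   `class_breaks`, `threshold`.
#' @export
limit_mask <- function(accumulated, n_classes = 7) {
  vals <- accumulated$values[is.finite(accumulated$values)]
  if (!length(vals)) stop("no finite accumulated costs", call. = FALSE)
  breaks <- jenks_breaks(vals, n_classes)
  thr <- breaks[1]
  m <- accumulated$values
  mask <- ifelse(is.na(m), NA_real_,
                 as.numeric(is.finite(m) & m <= thr))
  structure(list(
    mask = sdm_grid(mask, accumulated$origin, accumulated$res, accumulated$crs),
    class_breaks = as.numeric(breaks), threshold = thr
  ), class = "sdm_dispersal_limit")
}

#' @export
print.sdm_dispersal_limit <- function(x, ...) {
  cat(sprintf("<sdm_dispersal_limit> threshold %.4g; %d reachable cells\n",
              x$threshold, sum(x$mask$values == 1, na.rm = TRUE)))
  invisible(x)
}
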