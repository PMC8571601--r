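#' Gridded raster layer in geographic coordinates
#'
#' `sdm_grid` is the package's raster container: a numeric matrix of cell
#' values (row 1 = northernmost row, column index increasing eastward) plus a
#' geotransform. Nodata cells are stored as `NA`; all non-`NA` cells must be
#' finite. Coordinates are geographic longitude/latitude (WGS 84 assumed),
#' square cells, cell-center convention.
#'
#' @param values Numeric matrix; `NA` marks nodata.
#' @param origin Length-2 numeric: west edge longitude and north edge latitude
#'   of the grid, in decimal degrees.
#' @param res Cell size in decimal degrees (square cells), `> 0`.
#' @param crs Free-text CRS tag; defaults to `"WGS84"`.
#' @return An object of class `sdm_grid`.
#' @export
sdm_grid <- function(values, origin, res, crs = "WGS84") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0) {
    stop("`res` must be a single positive number (degrees per cell)", call. = FALSE)
  }
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop("`origin` must be (west longitude, north latitude)", call. = FALSE)
  }
  if (any(!is.finite(values[!is.na(values)]))) {
    stop("non-finite cell values outside the nodata mask", call. = FALSE)
  }
  structure(
    list(values = values, origin = as.numeric(origin), res = as.numeric(res),
         crs = crs),
    class = "sdm_grid"
  )
}

#' @export
print.sdm_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<sdm_grid> %d x %d cells, res %.6g deg, origin (%.4f, %.4f) [%s]\n",
              nrow(v), ncol(v), x$res, x$origin[1], x$origin[2], x$crs))
  ok <- !is.na(v)
  cat(sprintf("  valid cells: %d/%d; range [%.4g, %.4g]\n",
              sum(ok), length(v),
              if (any(ok)) min(v[ok]) else NA, if (any(ok)) max(v[ok]) else NA))
  invisible(x)
}

#' @export
dim.sdm_grid <- function(x) dim(x$values)

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)

#' Nodata mask of a grid
#' @param grid An [sdm_grid].
#' @return Logical matrix, `TRUE` where nodata.
#' @export
nodata_mask <- function(grid) is.na(grid$values)

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$res - b$res) < tol
}

#' Cell-center coordinates
#'
#' @param grid An [sdm_grid].
#' @param row,col Cell indices (1-based, row 1 northernmost).
#' @return Two-column matrix of longitude, latitude at cell centers.
#' @export
cell_center <- function(grid, row, col) {
  cbind(lon = grid$origin[1] + (col - 0.5) * grid$res,
        lat = grid$origin[2] - (row - 0.5) * grid$res)
}

#' Point-to-cell lookup
#'
#' Cells are half-open: a point on a cell's west/north edge belongs to that
#' cell. Points outside the grid get `NA` indices.
#'
#' @param grid An [sdm_grid].
#' @param lon,lat Point coordinates in decimal degrees.
#' @return Two-column integer matrix `row`, `col` (`NA` when outside).
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin[1]) / grid$res) + 1L
  row <- floor((grid$origin[2] - lat) / grid$res) + 1L
  bad <- row < 1L | row > grid_nrow(grid) | col < 1L | col > grid_ncol(grid)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII grid format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header then row-major
#' values, first data row = northernmost). Values and nodata cells are
#' preserved exactly; the sentinel is converted to `NA` internally.
#'
#' @param path File path.
#' @return An [sdm_grid].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value", "dx", "dy")) {
      num <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(num)) stop("malformed ASCII grid header field: ", parts[1], call. = FALSE)
      hdr[[key]] <- num
      i <- i + 1L
    } else break
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    stop("non-square pixels (dx/dy header) are not supported", call. = FALSE)
  }
  for (req in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[req]])) stop("ASCII grid header missing field: ", req, call. = FALSE)
  }
  if (hdr$cellsize <= 0) stop("malformed ASCII grid header field: cellsize", call. = FALSE)
  # llcenter variants are shifted by half a cell
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else
      stop("ASCII grid header missing field: xllcorner", call. = FALSE)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else
      stop("ASCII grid header missing field: yllcorner", call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid body has %d values, header promises %d",
                 length(vals), nr * nc), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  sdm_grid(m, origin = c(xll, yll + nr * hdr$cellsize), res = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param grid An [sdm_grid].
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells (default -9999).
#' @param digits Significant digits for values (default 17: round-trip exact).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 17) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.12f", grid$origin[1]),
    sprintf("yllcorner %.12f", grid$origin[2] - nr * grid$res),
    sprintf("cellsize %.12g", grid$res),
    sprintf("NODATA_value %s", format(nodata))
  )
  body <- apply(v, 1L, function(r) {
    r[is.na(r)] <- nodata
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Align named grids into a layer stack
#'
#' A `sdm_stack` is an ordered, named list of geometry-identical grids with a
#' shared union nodata mask (a cell is valid only where every member layer is
#' valid). All multi-layer operations require a stack, so geometry mismatches
#' surface early and by name.
#'
#' @param grids Named list of [sdm_grid] objects (>= 1).
#' @return An object of class `sdm_stack` with elements `layers` (the grids)
#'   and `union_nodata` (logical matrix).
#' @export
align_stack <- function(grids) {
  if (!is.list(grids) || length(grids) < 1L) {
    stop("need at least one grid", call. = FALSE)
  }
  if (is.null(names(grids)) || any(names(grids) == "")) {
    stop("grids must be named", call. = FALSE)
  }
  ref <- grids[[1L]]
  bad <- names(grids)[!vapply(grids, same_geometry, logical(1), b = ref)]
  if (length(bad)) {
    stop("layer geometry mismatch vs '", names(grids)[1], "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  un <- Reduce(`|`, lapply(grids, nodata_mask))
  structure(list(layers = grids, union_nodata = un), class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  shared-valid cells: %d/%d\n",
              sum(!x$union_nodata), length(x$union_nodata)))
  invisible(x)
}

#' @export
dim.sdm_stack <- function(x) dim(x$layers[[1]]$values)

stack_template <- function(stack) {
  g <- stack$layers[[1]]
  sdm_grid(ifelse(stack$union_nodata, NA_real_, 0), g$origin, g$res, g$crs)
}

#' Extract layer values at points
#'
#' @param stack An [align_stack()] stack.
#' @param lon,lat Point coordinates.
#' @return Tibble with one column per layer (NA where outside/nodata).
#' @export
extract_values <- function(stack, lon, lat) {
  g <- stack$layers[[1]]
  rc <- cell_index(g, lon, lat)
  idx <- ifelse(is.na(rc[, 1]), NA_integer_,
                rc[, 1] + (rc[, 2] - 1L) * grid_nrow(g))
  out <- lapply(stack$layers, function(l) l$values[idx])
  tibble::as_tibble(out)
}

#' Spherical cell area
#'
#' Area of one grid cell in km^2 on the authalic sphere
#' (R = 6371.0088 km): `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`.
#' Constant along a row, shrinking toward the poles.
#'
#' @param row Row index (1 = northernmost) or vector of rows.
#' @param grid An [sdm_grid].
#' @return Cell area(s) in km^2.
#' @export
cell_area_km2 <- function(row, grid) {
  if (any(row < 1L | row > grid_nrow(grid))) {
    stop("row index out of range", call. = FALSE)
  }
  R <- 6371.0088
  top <- (grid$origin[2] - (row - 1) * grid$res) * pi / 180
  bot <- (grid$origin[2] - row * grid$res) * pi / 180
  R^2 * (grid$res * pi / 180) * (sin(top) - sin(bot))
}

#' Total area of the TRUE cells of a binary grid
#'
#' @param binary An [sdm_grid] whose values are 0/1 (or logical); `NA` ignored.
#' @return Area in km^2 summed with [cell_area_km2()] row weights.
#' @export
area_km2 <- function(binary) {
  v <- binary$values
  if (!nrow(v)) return(0)
  row_area <- cell_area_km2(seq_len(nrow(v)), binary)
  counts <- rowSums(v == 1, na.rm = TRUE)
  sum(row_area * counts)
}

#' Grid as a tidy tibble
#'
#' @param x An [sdm_grid].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `lon`, `lat`, `value` (valid cells only).
#' @export
as_tibble.sdm_grid <- function(x, ...) {
  v <- x$values
  idx <- which(!is.na(v))
  row <- ((idx - 1L) %% nrow(v)) + 1L
  col <- ((idx - 1L) %/% nrow(v)) + 1L
  cc <- cell_center(x, row, col)
  tibble::tibble(row = row, col = col,
                 lon = cc[, 1], lat = cc[, 2], value = v[idx])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Plot a grid as a filled raster map
#'
#' @param object An [sdm_grid].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_grid <- function(object, ...) {
  df <- as_tibble.sdm_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
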