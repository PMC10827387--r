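#' Gridded raster layer on a geographic (WGS84) lattice
#'
#' `raster_grid` is the package's carrier for every map layer: a numeric
#' matrix (row 1 = northernmost row, column 1 = westernmost column) plus a
#' geotransform. Cells are square in degrees; `NA` marks nodata (land or
#' missing). The coordinate convention, used everywhere in the package, is:
#' cell centers at `west + (j - 1/2) * cell`, `north - (i - 1/2) * cell`, and
#' half-open cell intervals whose west and north edges are inclusive.
#'
#' @param values numeric matrix, row 1 at the north edge.
#' @param west,north longitude of the west edge and latitude of the north
#'   edge of the grid, decimal degrees.
#' @param cell cell size in decimal degrees (> 0).
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, west, north, cell) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || all(is.na(values)))
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("raster_grid needs at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0) {
    stop("cell size must be a single positive number", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values, west = as.numeric(west), north = as.numeric(north),
         cell = as.numeric(cell)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d x %d cells @ %g deg, west %g, north %g\n  %d nodata cells; range [%g, %g]\n",
    nrow(v), ncol(v), x$cell, x$west, x$north, sum(is.na(v)),
    suppressWarnings(min(v, na.rm = TRUE)), suppressWarnings(max(v, na.rm = TRUE))
  ))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_compatible <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$west, a$north, a$cell), c(b$west, b$north, b$cell),
                     tolerance = 1e-9))
}

stop_if_mismatch <- function(a, b, what = "raster") {
  if (!grid_compatible(a, b)) {
    stop(what, " grids are not co-registered (dimension or geotransform mismatch)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-center coordinates of a raster grid
#'
#' @param grid a [raster_grid()].
#' @param cells optional integer vector of linear cell indices
#'   (column-major, as R matrices are indexed); default all cells.
#' @return tibble with `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells = NULL) {
  nr <- nrow(grid$values)
  if (is.null(cells)) cells <- seq_along(grid$values)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  tibble::tibble(
    cell = as.integer(cells), row = row, col = col,
    lon = grid$west + (col - 0.5) * grid$cell,
    lat = grid$north - (row - 0.5) * grid$cell
  )
}

#' Locate points on a raster grid
#'
#' Maps coordinates to row/column indices under the half-open cell
#' convention (west and north edges belong to the cell; east and south edges
#' belong to the neighbour). Points outside the grid get `NA`.
#'
#' @param grid a [raster_grid()].
#' @param lon,lat numeric vectors of coordinates, decimal degrees.
#' @return tibble with `row`, `col`, `cell` (linear index), `inside`.
#' @export
locate_cells <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$west) / grid$cell) + 1
  row <- floor((grid$north - lat) / grid$cell) + 1
  inside <- !is.na(row) & !is.na(col) & row >= 1 & row <= nr & col >= 1 & col <= nc
  row[!inside] <- NA_integer_; col[!inside] <- NA_integer_
  tibble::tibble(
    row = as.integer(row), col = as.integer(col),
    cell = as.integer((col - 1L) * nr + row), inside = inside
  )
}

#' Linear indices of unmasked (non-nodata) cells
#'
#' @param grid a [raster_grid()].
#' @return integer vector of column-major cell indices.
#' @export
unmasked_cells <- function(grid) which(!is.na(grid$values))

#' Predictor stack: co-registered named layers for one scenario
#'
#' @param grids named list of [raster_grid()] layers sharing one
#'   geotransform and nodata mask.
#' @param scenario scenario label, one of `"baseline"`, `"ssp119"`,
#'   `"ssp370"`, `"ssp585"` (other labels allowed for synthetic work).
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(grids, scenario = "baseline") {
  if (length(grids) < 1L || is.null(names(grids)) || any(!nzchar(names(grids)))) {
    stop("predictor_stack needs a non-empty named list of layers", call. = FALSE)
  }
  ref <- grids[[1L]]
  for (nm in names(grids)) {
    stop_if_mismatch(ref, grids[[nm]], paste0("predictor '", nm, "'"))
    bad <- xor(is.na(ref$values), is.na(grids[[nm]]$values))
    if (any(bad)) {
      stop("layer '", nm, "' has a different nodata mask than the first layer",
           call. = FALSE)
    }
  }
  structure(list(scenario = scenario, grids = grids), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> scenario '%s': %s\n", x$scenario,
              paste(names(x$grids), collapse = ", ")))
  invisible(x)
}

stack_names <- function(stack) names(stack$grids)

stack_ref_grid <- function(stack) stack$grids[[1L]]

#' Extract predictor values at point locations
#'
#' Nearest-cell assignment (the value of the containing cell, no
#' interpolation), so training features match per-cell predictions exactly.
#' Points outside the grid or on nodata cells are flagged `keep = FALSE`.
#'
#' @param stack a [predictor_stack()].
#' @param points data frame with `lon` and `lat` columns (decimal degrees).
#' @return tibble: `lon`, `lat`, `keep`, `cell`, then one column per
#'   predictor (NA where `keep` is FALSE).
#' @export
extract_values <- function(stack, points) {
  stopifnot(inherits(stack, "predictor_stack"))
  if (length(stack$grids) == 0L) stop("empty predictor stack", call. = FALSE)
  pts <- normalize_lonlat(points)
  ref <- stack_ref_grid(stack)
  loc <- locate_cells(ref, pts$lon, pts$lat)
  keep <- loc$inside
  keep[loc$inside] <- !is.na(ref$values[loc$cell[loc$inside]])
  out <- tibble::tibble(lon = pts$lon, lat = pts$lat, keep = keep, cell = loc$cell)
  for (nm in stack_names(stack)) {
    v <- rep(NA_real_, nrow(out))
    v[keep] <- stack$grids[[nm]]$values[loc$cell[keep]]
    out[[nm]] <- v
  }
  out
}

normalize_lonlat <- function(points) {
  nms <- tolower(names(points))
  ilon <- match(TRUE, nms %in% c("lon", "longitude", "x"))
  ilat <- match(TRUE, nms %in% c("lat", "latitude", "y"))
  if (is.na(ilon) || is.na(ilat)) {
    stop("points need 'lon' and 'lat' columns", call. = FALSE)
  }
  tibble::tibble(lon = as.numeric(points[[ilon]]), lat = as.numeric(points[[ilat]]))
}

#' Raster heat map of a grid layer
#'
#' @param object a [raster_grid()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- cell_centers(object)
  df$value <- as.vector(object$values)[df$cell]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
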