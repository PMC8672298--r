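#' Grid specification for a raster on a projected coordinate system
#'
#' Describes a regular raster grid by its upper-left corner, square pixel
#' size, and dimensions. Two grids are considered aligned only when all
#' fields agree, which is what every multi-layer operation in the package
#' requires. Map coordinates of a cell refer to the cell *center*; pixel
#' indices are 0-based with row 0 at the top.
#'
#' @param origin_x,origin_y Map coordinates of the upper-left corner of the
#'   grid (not of the first cell center).
#' @param n_rows,n_cols Raster dimensions, positive integers.
#' @param pixel_size Edge length of a square pixel in map units (meters).
#'   The default is the nominal 231.25 m cell of the 250 m-class MODIS
#'   vegetation-index grid.
#' @param crs_label Free-text identifier of the projection. The package
#'   never reprojects; the label travels with the data for provenance.
#' @return An object of class `fc_grid`.
#' @examples
#' g <- grid_spec(0, 0, 64, 64)
#' g$pixel_size
#' @export
grid_spec <- function(origin_x, origin_y, n_rows, n_cols,
                      pixel_size = 231.25, crs_label = "sinusoidal") {
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs_label = as.character(crs_label)),
    class = "fc_grid"
  )
}

#' @export
print.fc_grid <- function(x, ...) {
  cat(sprintf("<fc_grid> %d x %d @ %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

#' Test whether two grids are aligned
#'
#' Aligned means every field of the two [grid_spec()] objects is equal;
#' only aligned layers may be combined cell-by-cell.
#'
#' @param a,b `fc_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(inherits(a, "fc_grid"), inherits(b, "fc_grid"))
  isTRUE(all.equal(unclass(a), unclass(b)))
}

#' Map coordinates of cell centers
#'
#' @param grid An `fc_grid`.
#' @return A list with numeric vectors `x` (length `n_cols`) and `y`
#'   (length `n_rows`); `y` decreases with row index (upper-left origin).
#' @export
cell_centers <- function(grid) {
  list(
    x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_size,
    y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$pixel_size
  )
}

#' Composite calendar of 16-day observation slots
#'
#' The compositing calendar used by the 250 m-class vegetation-index
#' record: 23 composites per calendar year, starting on day-of-year 1 and
#' spaced 16 days apart (start DOYs 1, 17, ..., 353). The final composite
#' of each year absorbs the year's remaining days, including any leap day,
#' so there is never a 24th step.
#'
#' @param years Ordered integer vector of calendar years covered.
#' @param start_doys Start day-of-year of each within-year composite.
#' @param step_days Nominal composite length in days.
#' @return An object of class `fc_calendar`.
#' @examples
#' cal <- composite_calendar(2001:2020)
#' n_steps(cal)   # 20 * 23
#' @export
composite_calendar <- function(years, start_doys = seq(1L, 353L, by = 16L),
                               step_days = 16L) {
  years <- as.integer(years)
  start_doys <- as.integer(start_doys)
  stopifnot(!is.unsorted(years),
            all(diff(start_doys) == step_days),
            !is.unsorted(start_doys, strictly = TRUE))
  structure(
    list(years = years, steps_per_year = length(start_doys),
         start_doys = start_doys, step_days = as.integer(step_days)),
    class = "fc_calendar"
  )
}

#' @export
print.fc_calendar <- function(x, ...) {
  cat(sprintf("<fc_calendar> %d years (%d-%d), %d steps/year every %d days\n",
              length(x$years), min(x$years), max(x$years),
              x$steps_per_year, x$step_days))
  invisible(x)
}

#' Number of time steps spanned by a calendar
#' @param calendar An `fc_calendar`.
#' @return Integer, `length(years) * steps_per_year`.
#' @export
n_steps <- function(calendar) {
  length(calendar$years) * calendar$steps_per_year
}

#' Tabulate a composite calendar
#'
#' @param calendar An `fc_calendar`.
#' @return A tibble with one row per time step: `time` (1-based index),
#'   `year`, `step` (1-based within-year index), and `doy` (start
#'   day-of-year of the composite).
#' @export
calendar_table <- function(calendar) {
  tibble::tibble(
    time = seq_len(n_steps(calendar)),
    year = rep(calendar$years, each = calendar$steps_per_year),
    step = rep(seq_len(calendar$steps_per_year), length(calendar$years)),
    doy  = rep(calendar$start_doys, length(calendar$years))
  )
}

#' Raster cube: a gridded time series
#'
#' A dense time x row x col array on a common [grid_spec()] with a
#' [composite_calendar()]. Missing observations are `NA` in memory; a
#' numeric nodata sentinel is only ever used on disk (see
#' [write_stack()]). When `value_range` is supplied, all non-missing
#' values must fall inside it; NDVI is bounded to \[-1, 1\] by
#' construction.
#'
#' @param values Numeric array `time x row x col` (time first).
#' @param grid An `fc_grid`.
#' @param calendar An `fc_calendar`; its length must equal `dim(values)[1]`.
#' @param value_range Optional length-2 numeric bounds for non-missing
#'   values, e.g. `c(-1, 1)` for NDVI; `NULL` disables the check.
#' @param varname Short variable name used in file naming.
#' @return An object of class `fc_cube`.
#' @export
raster_cube <- function(values, grid, calendar, value_range = c(-1, 1),
                        varname = "ndvi") {
  stopifnot(is.array(values), length(dim(values)) == 3,
            inherits(grid, "fc_grid"), inherits(calendar, "fc_calendar"))
  d <- dim(values)
  if (d[1] != n_steps(calendar))
    stop("calendar error: cube has ", d[1], " time steps but the calendar spans ",
         n_steps(calendar), call. = FALSE)
  if (d[2] != grid$n_rows || d[3] != grid$n_cols)
    stop("alignment error: cube is ", d[2], "x", d[3], " but the grid is ",
         grid$n_rows, "x", grid$n_cols, call. = FALSE)
  if (!is.null(value_range)) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < value_range[1] || max(v) > value_range[2]))
      stop("value error: non-missing values outside declared range [",
           value_range[1], ", ", value_range[2], "]", call. = FALSE)
  }
  structure(
    list(values = values, grid = grid, calendar = calendar,
         value_range = value_range, varname = varname),
    class = "fc_cube"
  )
}

#' @export
print.fc_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fc_cube '%s'> %d steps x %d x %d, %.1f%% missing\n",
              x$varname, d[1], d[2], d[3], 100 * mean(is.na(x$values))))
  invisible(x)
}

# Valid per-observation reliability codes: -1 fill, 0 good, 1 marginal,
# 2 snow/ice, 3 cloudy (the summary reliability scale of the source product).
QUALITY_CODES <- c(-1L, 0L, 1L, 2L, 3L)

#' Quality cube: per-observation reliability codes
#'
#' Same shape as the NDVI cube it accompanies. Codes follow the summary
#' pixel-reliability scale: -1 fill, 0 good, 1 marginal, 2 snow/ice,
#' 3 cloudy. Only codes 0 and 1 are retained by default downstream.
#'
#' @param codes Integer array `time x row x col`; `NA` treated as fill.
#' @inheritParams raster_cube
#' @return An object of class `fc_quality`.
#' @export
quality_cube <- function(codes, grid, calendar) {
  stopifnot(is.array(codes), length(dim(codes)) == 3)
  codes <- array(as.integer(codes), dim(codes))
  bad <- setdiff(unique(codes[!is.na(codes)]), QUALITY_CODES)
  if (length(bad))
    stop("quality codes outside the declared set {-1,0,1,2,3}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- raster_cube(codes, grid, calendar, value_range = NULL,
                     varname = "quality")
  class(out) <- c("fc_quality", class(out))
  out
}

#' Land-cover epochs on the analysis grid
#'
#' Categorical land-cover rasters for several mapping epochs, together
#' with the set of class codes counted as forest (default 311, 312, 313:
#' broadleaved, coniferous, and mixed forest).
#'
#' @param rasters Named list of integer matrices, one per epoch, all on
#'   `grid`; names are the epoch years.
#' @param grid An `fc_grid`.
#' @param forest_codes Integer class codes treated as forest.
#' @return An object of class `fc_landcover`.
#' @export
land_cover_stack <- function(rasters, grid,
                             forest_codes = c(311L, 312L, 313L)) {
  stopifnot(is.list(rasters), length(rasters) >= 1,
            inherits(grid, "fc_grid"))
  if (is.null(names(rasters)) || any(!nzchar(names(rasters))))
    stop("rasters must be a named list; names are epoch years", call. = FALSE)
  for (m in rasters) {
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop("alignment error: land-cover raster does not match the grid",
           call. = FALSE)
  }
  structure(
    list(epochs = as.integer(names(rasters)), rasters = rasters,
         grid = grid, forest_codes = as.integer(forest_codes)),
    class = "fc_landcover"
  )
}
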