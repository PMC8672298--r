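# Raster stacks are stored one single-band ESRI ASCII grid (.asc) per time
# step plus a JSON sidecar (<var>_stack.json) carrying the composite
# calendar, CRS label, and nodata sentinel. ASCII grid is plain text, so
# round-trips are value-identical (%.17g preserves doubles exactly) and
# the files open in any GIS.

FC_NODATA <- -9999

fc_write_asc <- function(values, grid, path, nodata = FC_NODATA) {
  stopifnot(is.matrix(values))
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$origin_x),
    sprintf("yllcorner %.17g", grid$origin_y - grid$n_rows * grid$pixel_size),
    sprintf("cellsize %.17g", grid$pixel_size),
    sprintf("NODATA_value %.17g", nodata)
  )
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

fc_read_asc <- function(path, crs_label = "sinusoidal") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  n_cols <- as.integer(val[["ncols"]]); n_rows <- as.integer(val[["nrows"]])
  cellsize <- val[["cellsize"]]
  grid <- grid_spec(
    origin_x = val[["xllcorner"]],
    origin_y = val[["yllcorner"]] + n_rows * cellsize,
    n_rows = n_rows, n_cols = n_cols, pixel_size = cellsize,
    crs_label = crs_label
  )
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  nodata <- val[["nodata_value"]]
  m[m == nodata] <- NA_real_
  list(values = m, grid = grid, nodata = nodata)
}

stack_filename <- function(varname, year, doy) {
  sprintf("%s_%d_%03d.asc", varname, year, doy)
}

#' Write a raster cube as a stack of single-band ASCII grids
#'
#' One georeferenced single-band file per time step, named
#' `<var>_<year>_<doy>.asc`, with missing values encoded by a nodata
#' sentinel chosen outside the value range, plus a `<var>_stack.json`
#' sidecar recording the calendar, CRS label, nodata value and file list.
#'
#' @param cube An [raster_cube()].
#' @param directory Output directory, created if absent.
#' @param nodata Numeric nodata sentinel written to file; must lie outside
#'   the cube's declared `value_range`.
#' @return Invisibly, the character vector of files written (empty for a
#'   cube with zero time steps).
#' @seealso [read_stack()]
#' @export
write_stack <- function(cube, directory, nodata = FC_NODATA) {
  stopifnot(inherits(cube, "fc_cube"))
  if (!is.null(cube$value_range) &&
      nodata >= cube$value_range[1] && nodata <= cube$value_range[2])
    stop("nodata sentinel must lie outside the declared value range",
         call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ct <- calendar_table(cube$calendar)
  files <- character(0)
  for (i in seq_len(nrow(ct))) {
    f <- file.path(directory, stack_filename(cube$varname, ct$year[i], ct$doy[i]))
    fc_write_asc(cube$values[i, , , drop = TRUE], cube$grid, f, nodata)
    files <- c(files, f)
  }
  sidecar <- list(
    varname = cube$varname,
    crs_label = cube$grid$crs_label,
    nodata = nodata,
    value_range = cube$value_range,
    calendar = list(years = cube$calendar$years,
                    start_doys = cube$calendar$start_doys,
                    step_days = cube$calendar$step_days),
    files = basename(files)
  )
  jsonlite::write_json(sidecar, file.path(directory, paste0(cube$varname, "_stack.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read a stack of single-band rasters into a cube
#'
#' All files must share one grid; the file count must match the calendar
#' length. Values equal to each file's nodata sentinel become missing.
#'
#' @param paths Character vector of `.asc` files in time order.
#' @param calendar The [composite_calendar()] the stack spans.
#' @param value_range,varname Passed to [raster_cube()].
#' @param crs_label CRS identifier to attach (ASCII grid headers do not
#'   carry one).
#' @return An [raster_cube()].
#' @export
read_stack <- function(paths, calendar, value_range = c(-1, 1),
                       varname = "ndvi", crs_label = "sinusoidal") {
  stopifnot(inherits(calendar, "fc_calendar"))
  if (length(paths) != n_steps(calendar))
    stop("calendar error: ", length(paths), " files for a calendar of ",
         n_steps(calendar), " steps", call. = FALSE)
  first <- fc_read_asc(paths[1], crs_label)
  grid <- first$grid
  vals <- array(NA_real_, c(length(paths), grid$n_rows, grid$n_cols))
  vals[1, , ] <- first$values
  for (i in seq_along(paths)[-1]) {
    lay <- fc_read_asc(paths[i], crs_label)
    if (!grids_aligned(lay$grid, grid))
      stop("alignment error: '", basename(paths[i]),
           "' is not on the same grid as '", basename(paths[1]), "'",
           call. = FALSE)
    vals[i, , ] <- lay$values
  }
  raster_cube(vals, grid, calendar, value_range = value_range,
              varname = varname)
}

#' Read a stack written by [write_stack()] using its JSON sidecar
#'
#' @param directory Directory containing the `.asc` files and sidecar.
#' @param varname Variable name (sidecar is `<varname>_stack.json`).
#' @return An [raster_cube()].
#' @export
read_stack_dir <- function(directory, varname) {
  sc <- jsonlite::read_json(file.path(directory, paste0(varname, "_stack.json")),
                            simplifyVector = TRUE)
  cal <- composite_calendar(sc$calendar$years,
                            start_doys = sc$calendar$start_doys,
                            step_days = sc$calendar$step_days)
  vr <- if (length(sc$value_range) != 2) NULL else as.numeric(sc$value_range)
  read_stack(file.path(directory, sc$files), cal, value_range = vr,
             varname = sc$varname, crs_label = sc$crs_label)
}

#' Nearest-neighbor remapping of a categorical raster
#'
#' Each target cell takes the class of the source cell whose center is
#' nearest to the target cell center, so the output class set is always a
#' subset of the input class set (classes are retained, never blended).
#' Distance ties are broken toward the smaller source row, then column
#' index. Target centers falling outside the source extent snap to the
#' nearest edge cell; fully disjoint extents are an error.
#'
#' @param values Matrix of class codes on `src_grid`.
#' @param src_grid,dst_grid [grid_spec()] objects on the same projection.
#' @return Matrix of class codes on `dst_grid`.
#' @export
remap_nearest <- function(values, src_grid, dst_grid) {
  stopifnot(is.matrix(values),
            nrow(values) == src_grid$n_rows, ncol(values) == src_grid$n_cols)
  sx <- c(src_grid$origin_x, src_grid$origin_x + src_grid$n_cols * src_grid$pixel_size)
  sy <- c(src_grid$origin_y - src_grid$n_rows * src_grid$pixel_size, src_grid$origin_y)
  dx <- c(dst_grid$origin_x, dst_grid$origin_x + dst_grid$n_cols * dst_grid$pixel_size)
  dy <- c(dst_grid$origin_y - dst_grid$n_rows * dst_grid$pixel_size, dst_grid$origin_y)
  if (dx[1] >= sx[2] || dx[2] <= sx[1] || dy[1] >= sy[2] || dy[2] <= sy[1])
    stop("disjoint extents: source and target rasters do not overlap",
         call. = FALSE)
  ctr <- cell_centers(dst_grid)
  # fractional source index of each target center; ties go to the smaller index
  nearest_index <- function(u, n) {
    lo <- floor(u)
    idx <- ifelse(u - lo <= (lo + 1) - u, lo, lo + 1)
    pmin(pmax(idx, 0), n - 1) + 1L
  }
  col_idx <- nearest_index((ctr$x - src_grid$origin_x) / src_grid$pixel_size - 0.5,
                           src_grid$n_cols)
  row_idx <- nearest_index((src_grid$origin_y - ctr$y) / src_grid$pixel_size - 0.5,
                           src_grid$n_rows)
  values[cbind(rep(row_idx, times = dst_grid$n_cols),
               rep(col_idx, each = dst_grid$n_rows))] |>
    matrix(nrow = dst_grid$n_rows, ncol = dst_grid$n_cols)
}
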