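# Analysis masks: which pixels are forest throughout the record, and which
# calendar days belong to each pixel's growing season.

# Mid-month day-of-year anchors for the 365-day monthly climatology.
MONTH_ANCHOR_DOYS <- c(15L, 46L, 74L, 105L, 135L, 166L, 196L, 227L, 258L,
                       288L, 319L, 349L)

#' Forest mask from multi-epoch land cover
#'
#' A pixel counts as forest only if its land-cover class belongs to the
#' forest set (broadleaved, coniferous, mixed: codes 311-313) in *every*
#' mapping epoch, which lowers the chance of land-use-change artifacts. A
#' pixel may switch between forest classes (e.g. coniferous to mixed) and
#' still qualify; any excursion outside the forest set disqualifies it.
#' Adding an epoch can therefore only shrink or preserve the mask.
#'
#' @param stack A [land_cover_stack()].
#' @return Logical matrix on the stack's grid.
#' @export
forest_mask <- function(stack) {
  stopifnot(inherits(stack, "fc_landcover"))
  Reduce(`&`, lapply(stack$rasters, function(m) {
    ok <- matrix(m %in% stack$forest_codes, nrow(m), ncol(m))
    ok & !is.na(m)
  }))
}

#' Daily temperature climatology from monthly means
#'
#' Piecewise-linear interpolation of 12 monthly mean temperatures to a
#' 365-day series, with monthly values anchored at mid-month days-of-year
#' (15, 46, ..., 349) and wrap-around interpolation between December and
#' January. The leap day is ignored (365-day climatology). Anchor days
#' reproduce the monthly values exactly.
#'
#' @param monthly Numeric vector of 12 finite monthly mean temperatures
#'   (deg C), January to December.
#' @return Numeric vector of 365 daily values.
#' @export
daily_climatology <- function(monthly) {
  if (length(monthly) != 12L || !all(is.finite(monthly)))
    stop("exactly 12 finite monthly values are required", call. = FALSE)
  # pad with December before January and January after December so the
  # interpolation wraps across the year boundary
  x <- c(MONTH_ANCHOR_DOYS[12] - 365L, MONTH_ANCHOR_DOYS,
         MONTH_ANCHOR_DOYS[1] + 365L)
  y <- c(monthly[12], monthly, monthly[1])
  stats::approx(x, y, xout = 1:365, method = "linear")$y
}

#' Growing-season mask from a daily climatology
#'
#' The growing season of a pixel is the set of calendar days whose
#' interpolated mean-temperature climatology exceeds the threshold
#' (default 5 deg C, a standard threshold for cambial activity and
#' growth). If the climatology crosses the threshold more than twice, all
#' above-threshold days are kept. A composite step counts as in-season iff
#' its start day-of-year is in-season.
#'
#' @param daily 365 daily climatology values (deg C).
#' @param threshold Temperature threshold (deg C), default 5.
#' @param start_doys Composite start days for the per-step mask.
#' @return A list with logical `days` (length 365) and logical `steps`
#'   (one per composite start day).
#' @export
season_mask <- function(daily, threshold = 5,
                        start_doys = seq(1L, 353L, by = 16L)) {
  stopifnot(length(daily) == 365L)
  days <- daily > threshold
  list(days = days, steps = days[start_doys])
}

#' Per-pixel growing-season mask for a whole grid
#'
#' @param climatology Numeric array `12 x n_rows x n_cols` of monthly mean
#'   temperatures.
#' @param threshold Temperature threshold (deg C).
#' @param start_doys Composite start days.
#' @return A list with `steps` (logical array `n_steps_per_year x n_rows x
#'   n_cols`) and `seasonless` (logical matrix: pixels with no in-season
#'   composite step at all).
#' @export
season_mask_grid <- function(climatology, threshold = 5,
                             start_doys = seq(1L, 353L, by = 16L)) {
  stopifnot(is.array(climatology), length(dim(climatology)) == 3,
            dim(climatology)[1] == 12L)
  d <- dim(climatology)
  M <- matrix(climatology, nrow = 12L)       # 12 x pixel
  steps <- vapply(seq_len(ncol(M)), function(j) {
    season_mask(daily_climatology(M[, j]), threshold, start_doys)$steps
  }, logical(length(start_doys)))
  list(
    steps = array(steps, c(length(start_doys), d[2], d[3])),
    seasonless = matrix(colSums(steps) == 0L, d[2], d[3])
  )
}
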