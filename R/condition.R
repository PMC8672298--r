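# The two condition metrics. For each pixel and composite step, the n
# yearly observations (one per year of the record) are transformed into
# (1) Q, the mid-rank of each value scaled to (0,1) and centered on 0.5,
# and (2) PDM, the proportional deviation from the median. Both are
# non-parametric by design: NDVI has a bounded, usually skewed
# distribution, so z-scores would be a poor standardisation.

#' Quantile transform of the yearly values at one pixel-step
#'
#' `Q = R/n - 1/(2n)` with `R` the mid-rank of each value among the `n`
#' yearly observations. The centering term puts the attainable values
#' symmetric around 0.5: the series minimum maps to `1/(2n)`, the maximum
#' to `1 - 1/(2n)`, and for tie-free data the mean over years is exactly
#' 0.5. Ties receive mid-ranks (average rank), which preserves that mean.
#'
#' @param values Numeric vector of the `n >= 2` yearly NDVI values of one
#'   pixel at one composite step. `NA`s are not allowed here; drop missing
#'   years before calling.
#' @return Numeric vector of Q values in (0, 1).
#' @examples
#' quantile_transform(c(0.6, 0.7, 0.8, 0.9))  # 0.125 0.375 0.625 0.875
#' @export
quantile_transform <- function(values) {
  n <- length(values)
  if (n < 2L || anyNA(values))
    stop("Q is undefined for fewer than 2 complete observations", call. = FALSE)
  rank(values, ties.method = "average") / n - 1 / (2 * n)
}

#' Proportional deviation from the median at one pixel-step
#'
#' `PDM = NDVI / median - 1`, the relative deviation of each yearly value
#' from the pixel-step median. Unlike the rank-based Q it carries absolute
#' magnitude, so it is comparable across pixels; it is invariant to
#' rescaling all values by a positive constant. A non-positive median
#' (never expected over forest, where NDVI > 0.5) makes the proportional
#' deviation meaningless, so the result is all-missing with a warning.
#'
#' @param values Numeric vector of the `n >= 2` yearly NDVI values of one
#'   pixel at one composite step.
#' @return Numeric vector of PDM values (`NA` if the median is not
#'   positive).
#' @export
pdm_transform <- function(values) {
  n <- length(values)
  if (n < 2L || anyNA(values))
    stop("PDM is undefined for fewer than 2 complete observations", call. = FALSE)
  med <- stats::median(values)
  if (!is.finite(med) || med <= 0) {
    warning("non-positive median: PDM reported missing for this pixel-step",
            call. = FALSE)
    return(rep(NA_real_, n))
  }
  values / med - 1
}

#' Class breaks for mapping a condition metric
#'
#' Ordered break points defining `length(breaks) + 1` classes with
#' left-closed intervals `[b_k, b_{k+1})` and open-ended extremes. Class
#' indices are 0-based: class 0 is everything below the first break; a
#' value exactly at the last break falls in the highest class.
#'
#' @param breaks Strictly increasing numeric break points.
#' @param metric Label, `"Q"` or `"PDM"`.
#' @return An object of class `fc_breaks`.
#' @seealso [q_breaks()], [pdm_breaks()], [classify()]
#' @export
class_breaks <- function(breaks, metric = c("Q", "PDM")) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(breaks), length(breaks) >= 1,
            !is.unsorted(breaks, strictly = TRUE))
  structure(list(metric = metric, breaks = as.numeric(breaks),
                 n_classes = length(breaks) + 1L),
            class = "fc_breaks")
}

#' Default Q break scheme
#'
#' For an `n`-year record the attainable tie-free Q values are
#' `1/(2n) + k/n`; using exactly those as breaks resolves the map into
#' `n + 1` classes (21 classes for the 20-year record, breaks from 1/40 to
#' 1 - 1/40 in steps of 1/20), so each attainable value starts its own
#' class.
#'
#' @param n_years Number of years in the record (default 20).
#' @return An `fc_breaks` object with `n_years` breaks.
#' @export
q_breaks <- function(n_years = 20L) {
  # same expression as quantile_transform() so attainable Q values coincide
  # with their breaks bit for bit (the boundary rule is load-bearing)
  class_breaks(seq_len(n_years) / n_years - 1 / (2 * n_years), "Q")
}

#' Default PDM break scheme
#'
#' Proportional deviations resolved from below -10% to above +10% in
#' steps of 2.5% (9 breaks, 10 classes). The -10% lower bound matches
#' deviations at which individual-tree die-back has been observed after
#' severe drought.
#'
#' @return An `fc_breaks` object.
#' @export
pdm_breaks <- function() {
  class_breaks(seq(-0.10, 0.10, by = 0.025), "PDM")
}

#' Classify metric values on a break scheme
#'
#' Left-closed intervals: index `k` means `b_k <= value < b_{k+1}`, with
#' class 0 below the first break and the highest class containing the last
#' break itself. Missing values stay missing.
#'
#' @param values Numeric vector, matrix or array of metric values.
#' @param breaks An [class_breaks()] object.
#' @return Integer class indices (0-based) with the shape of `values`.
#' @export
classify <- function(values, breaks) {
  stopifnot(inherits(breaks, "fc_breaks"))
  idx <- findInterval(values, breaks$breaks)    # left-closed by construction
  idx[is.na(values)] <- NA_integer_
  if (!is.null(dim(values))) idx <- array(as.integer(idx), dim(values))
  else idx <- as.integer(idx)
  idx
}

#' Spatial share of each condition class
#'
#' Histogram of class indices over the pixels selected by the analysis
#' mask (forest, in-season, non-missing). Shares sum to one over the
#' counted pixels; an empty selection yields an empty histogram.
#'
#' @param class_values Integer matrix/array of class indices for one date.
#' @param breaks The [class_breaks()] that produced them.
#' @param mask Logical mask of pixels to count (same shape); `NULL` counts
#'   all non-missing pixels.
#' @return A tibble with `class`, `lower`, `upper`, `count`, `share`.
#' @export
spatial_histogram <- function(class_values, breaks, mask = NULL) {
  stopifnot(inherits(breaks, "fc_breaks"))
  v <- as.vector(class_values)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(v))
    v <- v[as.vector(mask)]
  }
  v <- v[!is.na(v)]
  k <- breaks$n_classes
  lower <- c(-Inf, breaks$breaks)
  upper <- c(breaks$breaks, Inf)
  if (!length(v)) {
    return(tibble::tibble(class = integer(0), lower = numeric(0),
                          upper = numeric(0), count = integer(0),
                          share = numeric(0)))
  }
  counts <- tabulate(v + 1L, nbins = k)
  tibble::tibble(class = 0:(k - 1L), lower = lower, upper = upper,
                 count = counts, share = counts / sum(counts))
}

#' Condition cube: Q and PDM per pixel and composite step
#'
#' Computes both metrics for every forest pixel at every composite step,
#' ranking each year's value among all years of the record at that
#' pixel-step. Non-forest pixels are missing throughout; out-of-season
#' steps are *computed* but flagged via the `in_season` array, and all
#' classification/histogram summaries honour that flag. `n_obs` records
#' how many years contributed at each pixel-step (years missing at a
#' pixel-step are dropped before ranking; pixel-steps with fewer than two
#' years stay missing).
#'
#' @param cube A preprocessed NDVI [raster_cube()] whose calendar spans
#'   `n_years` full years.
#' @param forest Logical matrix of forest pixels (`NULL` = all pixels).
#' @param season Per-pixel step mask as returned by [season_mask_grid()]
#'   (`NULL` = always in season).
#' @return An object of class `fc_condition`: list with `q`, `pdm`
#'   (arrays shaped like the cube), `n_obs` (steps/yr x rows x cols),
#'   `in_season` (same shape as `n_obs`), `grid`, `calendar`.
#' @export
condition_cubes <- function(cube, forest = NULL, season = NULL) {
  stopifnot(inherits(cube, "fc_cube"))
  cal <- cube$calendar
  spy <- cal$steps_per_year
  ny <- length(cal$years)
  d <- dim(cube$values)
  if (!is.null(forest))
    stopifnot(is.matrix(forest), all(dim(forest) == d[2:3]))
  V <- array(cube$values, c(spy, ny, d[2] * d[3]))  # step x year x pixel
  V <- aperm(V, c(2, 1, 3))                         # year x step x pixel
  dim(V) <- c(ny, spy * d[2] * d[3])
  if (!is.null(forest)) {
    keep_px <- rep(as.vector(forest), each = spy)
    V[, !keep_px] <- NA_real_
  }
  n_obs <- colSums(!is.na(V))
  Q <- P <- matrix(NA_real_, ny, ncol(V))
  todo <- which(n_obs >= 2L)
  complete <- todo[n_obs[todo] == ny]
  partial <- setdiff(todo, complete)
  n_nonpos_median <- 0L
  if (length(complete)) {
    Vc <- V[, complete, drop = FALSE]
    R <- apply(Vc, 2, rank, ties.method = "average")
    Q[, complete] <- R / ny - 1 / (2 * ny)
    med <- apply(Vc, 2, stats::median)
    P[, complete] <- sweep(Vc, 2, med, "/") - 1
    P[, complete[med <= 0]] <- NA_real_
    n_nonpos_median <- sum(med <= 0)
  }
  for (j in partial) {                       # pixel-steps with missing years
    ok <- !is.na(V[, j])
    n <- sum(ok)
    Q[ok, j] <- rank(V[ok, j], ties.method = "average") / n - 1 / (2 * n)
    med <- stats::median(V[ok, j])
    if (med > 0) P[ok, j] <- V[ok, j] / med - 1
    else n_nonpos_median <- n_nonpos_median + 1L
  }
  back <- function(M) {
    A <- array(M, c(ny, spy, d[2] * d[3]))
    array(aperm(A, c(2, 1, 3)), d)
  }
  in_season <- if (is.null(season)) {
    array(TRUE, c(spy, d[2], d[3]))
  } else season$steps
  structure(
    list(q = back(Q), pdm = back(P),
         n_obs = array(n_obs, c(spy, d[2], d[3])),
         in_season = in_season, n_nonpos_median = n_nonpos_median,
         grid = cube$grid, calendar = cal),
    class = "fc_condition"
  )
}

#' @export
print.fc_condition <- function(x, ...) {
  d <- dim(x$q)
  cat(sprintf("<fc_condition> %d steps x %d x %d (%d years), %.1f%% pixels in metric\n",
              d[1], d[2], d[3], length(x$calendar$years),
              100 * mean(x$n_obs >= 2)))
  invisible(x)
}

#' Extract one date (year, day-of-year) from a condition cube
#'
#' @param condition An `fc_condition`.
#' @param year Calendar year.
#' @param doy Composite start day-of-year.
#' @return A list with matrices `q`, `pdm`, logical `in_season`, and the
#'   time index `time`.
#' @export
condition_slice <- function(condition, year, doy) {
  ct <- calendar_table(condition$calendar)
  i <- which(ct$year == year & ct$doy == doy)
  if (!length(i))
    stop("date outside record: year ", year, ", doy ", doy, call. = FALSE)
  step <- ct$step[i]
  list(q = condition$q[i, , , drop = TRUE],
       pdm = condition$pdm[i, , , drop = TRUE],
       in_season = condition$in_season[step, , , drop = TRUE],
       time = i)
}
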