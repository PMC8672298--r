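# Per-pixel NDVI time-series conditioning. The chain, in the order it is
# applied: quality mask -> linear gap fill -> Gaussian reference smooth ->
# one-pass negative-outlier replacement -> Gaussian smooth -> pixel-specific
# linear detrend. All stages are vectorised over pixels where possible.

#' Preprocessing configuration
#'
#' Parameters of the NDVI conditioning chain. The smoothing filter spans
#' five 16-day composite steps (80 days); outliers are observations whose
#' standardized difference from the Gaussian-filtered series falls below
#' minus two standard deviations (the screen is one-sided: only
#' implausibly *low* values are artifacts of residual cloud/snow
#' contamination).
#'
#' @param keep_quality Integer reliability codes retained by the quality
#'   mask (default good = 0 and marginal = 1).
#' @param filter_window Odd integer >= 3, filter length in composite steps
#'   (default 5, i.e. 80 days at 16 days per step).
#' @param kernel_sigma Gaussian kernel standard deviation in composite
#'   steps (default 1).
#' @param outlier_z Negative z-score threshold below which an observation
#'   is replaced by its smoothed counterpart (default -2).
#' @param step_days Days per composite step (16).
#' @return An object of class `fc_preprocess_config`.
#' @export
preprocess_config <- function(keep_quality = c(0L, 1L), filter_window = 5L,
                              kernel_sigma = 1.0, outlier_z = -2,
                              step_days = 16L) {
  filter_window <- as.integer(filter_window)
  stopifnot(filter_window >= 3L, filter_window %% 2L == 1L,
            kernel_sigma > 0, outlier_z < 0)
  structure(
    list(keep_quality = as.integer(keep_quality),
         filter_window = filter_window,
         filter_span_days = filter_window * as.integer(step_days),
         kernel_sigma = kernel_sigma,
         outlier_z = outlier_z,
         step_days = as.integer(step_days)),
    class = "fc_preprocess_config"
  )
}

# Provenance flag codes carried alongside every conditioned series.
FLAG_OBSERVED <- 0L
FLAG_INTERPOLATED <- 1L
FLAG_OUTLIER_REPLACED <- 2L

#' Normalized difference vegetation index from reflectances
#'
#' NDVI = (NIR - RED) / (NIR + RED), bounded to \[-1, 1\] for
#' non-negative reflectances. Where the denominator is zero the index is
#' undefined and returned as `NA`.
#'
#' @param nir,red Non-negative surface reflectance values (vectors,
#'   matrices or arrays of a common shape).
#' @return NDVI with the shape of the inputs.
#' @examples
#' compute_ndvi(0.5, 0.1)  # 0.667: dense canopy
#' @export
compute_ndvi <- function(nir, red) {
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE))
    stop("reflectances must be non-negative", call. = FALSE)
  s <- nir + red
  out <- (nir - red) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Maximum-value compositing of a daily series
#'
#' Reduces daily observations of one calendar year to per-window maxima
#' over quality-passing values, the standard compositing that suppresses
#' cloud-depressed observations. Windows start at `start_doys` and each
#' extends to the day before the next window (the last window absorbs the
#' rest of the year). A window with no retained observation is missing.
#'
#' @param values Daily values.
#' @param doy Day-of-year of each value.
#' @param quality Optional reliability codes per value.
#' @param keep Codes retained when `quality` is given.
#' @param start_doys Window start days (default the 23-step calendar).
#' @return Numeric vector, one composite per window.
#' @export
composite_max <- function(values, doy, quality = NULL, keep = c(0L, 1L),
                          start_doys = seq(1L, 353L, by = 16L)) {
  stopifnot(length(values) == length(doy),
            is.null(quality) || length(quality) == length(values))
  ok <- !is.na(values)
  if (!is.null(quality)) ok <- ok & quality %in% keep
  win <- findInterval(doy, start_doys)
  out <- rep(NA_real_, length(start_doys))
  keep_idx <- which(ok & win >= 1)
  if (length(keep_idx)) {
    mx <- tapply(values[keep_idx], win[keep_idx], max)
    out[as.integer(names(mx))] <- as.numeric(mx)
  }
  out
}

#' Mask a cube by per-observation quality codes
#'
#' Observations whose reliability code is not in the keep set become
#' missing; all others are unchanged. Never increases the number of
#' non-missing values.
#'
#' @param cube An NDVI [raster_cube()].
#' @param quality A [quality_cube()] of the same shape.
#' @param keep Integer codes to retain (default good and marginal).
#' @return The masked cube.
#' @export
mask_by_quality <- function(cube, quality, keep = c(0L, 1L)) {
  stopifnot(inherits(cube, "fc_cube"), inherits(quality, "fc_quality"))
  if (!identical(dim(cube$values), dim(quality$values)))
    stop("alignment error: cube and quality cube differ in shape",
         call. = FALSE)
  v <- cube$values
  drop <- is.na(quality$values) | !(quality$values %in% keep)
  v[drop] <- NA_real_
  out <- cube
  out$values <- v
  out
}

#' Linear gap filling of a pixel series
#'
#' Interior gaps are linearly interpolated between the nearest flanking
#' observations; leading and trailing gaps are filled by extending the
#' nearest observed value. A series with no observation at all cannot be
#' filled and raises a classed error (`fc_all_missing`) so callers can
#' exclude the pixel explicitly rather than guess.
#'
#' @param values Numeric series with `NA` gaps.
#' @return A list with `values` (gap-free) and integer `flags`
#'   (0 observed, 1 interpolated).
#' @export
fill_gaps <- function(values) {
  obs <- which(!is.na(values))
  if (!length(obs))
    stop(structure(class = c("fc_all_missing", "error", "condition"),
                   list(message = "all-missing series: pixel must be excluded",
                        call = NULL)))
  flags <- ifelse(is.na(values), FLAG_INTERPOLATED, FLAG_OBSERVED)
  if (length(obs) < length(values)) {
    if (length(obs) == 1L) {
      values[] <- values[obs]
    } else {
      values <- stats::approx(obs, values[obs], xout = seq_along(values),
                              method = "linear", rule = 2)$y
    }
  }
  list(values = values, flags = as.integer(flags))
}

# Truncated, renormalized Gaussian weights for offsets -h..h.
gaussian_kernel <- function(window, sigma) {
  h <- (window - 1L) %/% 2L
  w <- exp(-((-h:h) / sigma)^2 / 2)
  w / sum(w)
}

# Dense T x T smoothing operator with truncate-and-renormalize edges.
# Row t holds the weights producing smoothed value t.
smoothing_matrix <- function(n, window, sigma) {
  h <- (window - 1L) %/% 2L
  w <- exp(-((-h:h) / sigma)^2 / 2)
  M <- matrix(0, n, n)
  for (t in seq_len(n)) {
    k <- max(1L, t - h):min(n, t + h)
    wk <- w[k - t + h + 1L]
    M[t, k] <- wk / sum(wk)
  }
  M
}

#' Gaussian smoothing of a gap-free series
#'
#' Discrete convolution with a truncated Gaussian kernel of
#' `filter_window` steps, weights renormalized to sum to one. At the
#' series edges the kernel is truncated to the available steps and
#' renormalized again, so constants are preserved everywhere and no
#' padding value biases early or late steps.
#'
#' @param values Gap-free numeric series.
#' @param config An [preprocess_config()].
#' @return Smoothed series of the same length.
#' @export
gaussian_smooth <- function(values, config = preprocess_config()) {
  if (length(values) < 1L) stop("series must have at least one step", call. = FALSE)
  if (anyNA(values)) stop("gaussian_smooth requires a gap-free series", call. = FALSE)
  drop(smoothing_matrix(length(values), config$filter_window,
                        config$kernel_sigma) %*% values)
}

#' One-pass negative-outlier screening
#'
#' Residual contamination (cloud, snow) shows up as implausibly low
#' values. Differences `d = filled - smoothed` are standardized; steps
#' with `z < outlier_z` (default -2) are replaced by the corresponding
#' smoothed value and flagged. With zero variance in `d` there are no
#' outliers and the series is returned unchanged. Positive spikes are
#' never touched.
#'
#' @param filled Gap-free series.
#' @param smoothed Its Gaussian-filtered counterpart (same length).
#' @param z_threshold Negative threshold on the standardized differences.
#' @return A list with `values`, integer `flags` (2 where replaced), and
#'   the `z` scores.
#' @export
screen_outliers <- function(filled, smoothed, z_threshold = -2) {
  stopifnot(length(filled) == length(smoothed), z_threshold < 0)
  d <- filled - smoothed
  s <- stats::sd(d)
  flags <- integer(length(filled))
  if (is.na(s) || s == 0)
    return(list(values = filled, flags = flags, z = d * 0))
  z <- (d - mean(d)) / s
  out <- z < z_threshold
  filled[out] <- smoothed[out]
  flags[out] <- FLAG_OUTLIER_REPLACED
  list(values = filled, flags = flags, z = z)
}

#' Pixel-specific linear detrending, level-preserving
#'
#' Removes the ordinary-least-squares line over the time index and adds
#' the series mean back, so long-term trends are removed while the mean
#' level is preserved exactly.
#'
#' @param values Numeric series, length >= 3.
#' @return Detrended series with the same mean.
#' @export
detrend_series <- function(values) {
  n <- length(values)
  if (n < 3L) stop("detrending needs at least 3 steps", call. = FALSE)
  t <- seq_len(n) - (n + 1) / 2            # centered time index
  slope <- sum(t * (values - mean(values))) / sum(t * t)
  values - slope * t
}

#' Condition one pixel series through the full chain
#'
#' Applies, in order: quality masking, linear gap filling, Gaussian
#' reference smoothing, one-pass negative-outlier replacement, Gaussian
#' smoothing, and pixel-specific linear detrending. Provenance flags
#' accumulate across stages (interpolated steps keep flag 1 unless also
#' replaced as outliers, which takes precedence as flag 2).
#'
#' @param values Raw composite series for one pixel.
#' @param quality Reliability codes for the series (optional).
#' @param config An [preprocess_config()].
#' @return A list with conditioned `values`, integer `flags`, and
#'   `counts` (gap-filled and outlier-replaced steps).
#' @export
preprocess_pixel <- function(values, quality = NULL,
                             config = preprocess_config()) {
  if (!is.null(quality)) {
    stopifnot(length(quality) == length(values))
    values[is.na(quality) | !(quality %in% config$keep_quality)] <- NA_real_
  }
  filled <- fill_gaps(values)
  reference <- gaussian_smooth(filled$values, config)
  screened <- screen_outliers(filled$values, reference, config$outlier_z)
  smoothed <- gaussian_smooth(screened$values, config)
  detrended <- detrend_series(smoothed)
  flags <- filled$flags
  flags[screened$flags == FLAG_OUTLIER_REPLACED] <- FLAG_OUTLIER_REPLACED
  list(values = detrended, flags = flags,
       counts = c(gap_filled = sum(filled$flags == FLAG_INTERPOLATED),
                  outliers_replaced = sum(screened$flags == FLAG_OUTLIER_REPLACED)))
}

#' Condition every pixel of an NDVI cube
#'
#' Cube-level, vectorised version of [preprocess_pixel()]. Pixels with no
#' retained observation at all are excluded: their series stay all-missing
#' and they are reported in the stage counts rather than guessed.
#'
#' @param cube An NDVI [raster_cube()].
#' @param quality Optional [quality_cube()] aligned with `cube`.
#' @param config An [preprocess_config()].
#' @return A list with `cube` (conditioned values; detrending can move
#'   values slightly outside the raw NDVI bounds, so the declared range is
#'   dropped), `flags` (integer cube of provenance codes), and `counts`
#'   (masked observations, gaps filled, outliers replaced, excluded
#'   pixels).
#' @export
preprocess_cube <- function(cube, quality = NULL,
                            config = preprocess_config()) {
  stopifnot(inherits(cube, "fc_cube"))
  v <- cube$values
  n_obs_before <- sum(!is.na(v))
  if (!is.null(quality)) {
    cube_masked <- mask_by_quality(cube, quality, config$keep_quality)
    v <- cube_masked$values
  }
  n_masked <- n_obs_before - sum(!is.na(v))
  d <- dim(v)
  X <- matrix(v, nrow = d[1])               # time x pixel
  flags <- matrix(FLAG_OBSERVED, nrow = d[1], ncol = ncol(X))
  flags[is.na(X)] <- FLAG_INTERPOLATED
  usable <- colSums(!is.na(X)) > 0L
  n_gaps <- sum(is.na(X[, usable]))          # before outlier flags take precedence
  n_excluded <- sum(!usable)

  fill_one <- function(x) {
    obs <- which(!is.na(x))
    if (length(obs) == length(x)) return(x)
    if (length(obs) == 1L) return(rep(x[obs], length(x)))
    stats::approx(obs, x[obs], xout = seq_along(x), rule = 2)$y
  }
  X[, usable] <- vapply(which(usable), function(j) fill_one(X[, j]),
                        numeric(d[1]))

  M <- smoothing_matrix(d[1], config$filter_window, config$kernel_sigma)
  U <- X[, usable, drop = FALSE]
  reference <- M %*% U
  D <- U - reference
  mu <- colMeans(D)
  sdev <- sqrt(colSums(sweep(D, 2, mu)^2) / (d[1] - 1))
  Z <- sweep(sweep(D, 2, mu), 2, ifelse(sdev > 0, sdev, Inf), "/")
  out_mask <- Z < config$outlier_z
  n_outliers <- sum(out_mask)
  U[out_mask] <- reference[out_mask]
  fl <- flags[, usable, drop = FALSE]
  fl[out_mask] <- FLAG_OUTLIER_REPLACED
  flags[, usable] <- fl

  U <- M %*% U
  t_c <- seq_len(d[1]) - (d[1] + 1) / 2
  slope <- drop(crossprod(t_c, sweep(U, 2, colMeans(U)))) / sum(t_c^2)
  U <- U - outer(t_c, slope)
  X[, usable] <- U
  flags[, !usable] <- FLAG_OBSERVED

  out <- cube
  out$values <- array(X, d)
  out$value_range <- NULL                    # detrending may leave [-1, 1]
  list(
    cube = out,
    flags = quality_like_flags(flags, d),
    counts = c(observations = n_obs_before, masked = n_masked,
               gap_filled = n_gaps,
               outliers_replaced = n_outliers,
               pixels_excluded = n_excluded)
  )
}

quality_like_flags <- function(flags, d) array(as.integer(flags), d)
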