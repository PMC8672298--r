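test_that("NDVI arithmetic handles the defined and degenerate cases", {
  expect_equal(compute_ndvi(0.5, 0.1), 0.4 / 0.6)
  expect_equal(compute_ndvi(0.3, 0.3), 0)
  expect_true(is.na(compute_ndvi(0, 0)))
  expect_error(compute_ndvi(-0.1, 0.2), "non-negative")
  expect_true(all(abs(compute_ndvi(runif(50), runif(50))) <= 1))
})

test_that("maximum-value compositing keeps the max of quality-passing values", {
  # cloudy 0.9 rejected, max of the rest wins
  expect_equal(
    composite_max(c(0.3, 0.9, 0.5), doy = c(2, 7, 12),
                  quality = c(0L, 3L, 1L))[1],
    0.5
  )
  expect_true(is.na(composite_max(c(0.3, 0.9), doy = c(2, 7),
                                  quality = c(3L, 2L))[1]))
  expect_equal(composite_max(0.42, doy = 20)[2], 0.42)
  expect_length(composite_max(0.42, doy = 20), 23L)
})

test_that("quality masking drops exactly the codes outside the keep set", {
  cal <- composite_calendar(2001)
  g <- grid_spec(0, 0, 2, 2)
  v <- array(0.6, c(23, 2, 2))
  codes <- array(0L, c(23, 2, 2))
  codes[1, 1, 1] <- 3L; codes[2, 1, 1] <- 2L; codes[3, 1, 1] <- 1L
  cube <- raster_cube(v, g, cal)
  q <- quality_cube(codes, g, cal)
  masked <- mask_by_quality(cube, q)
  expect_true(is.na(masked$values[1, 1, 1]))       # cloudy
  expect_true(is.na(masked$values[2, 1, 1]))       # snow
  expect_equal(masked$values[3, 1, 1], 0.6)        # marginal retained
  expect_identical(mask_by_quality(cube, q, keep = c(-1L, 0:3))$values, v)
  # never increases the number of observations
  expect_lte(sum(!is.na(masked$values)), sum(!is.na(v)))
})

test_that("gap filling is linear inside and nearest-value at the edges", {
  got <- fill_gaps(c(0.5, NA, 0.7))
  expect_equal(got$values[2], 0.6)
  expect_equal(got$flags, c(0L, 1L, 0L))
  expect_identical(fill_gaps(c(0.1, 0.2))$values, c(0.1, 0.2))
  lead <- fill_gaps(c(NA, NA, 0.4, 0.6))
  expect_equal(lead$values, c(0.4, 0.4, 0.4, 0.6))
  expect_error(fill_gaps(rep(NA_real_, 5)), class = "fc_all_missing")
})

test_that("gap filling matches the piecewise-linear oracle on random series", {
  set.seed(101)
  for (k in 1:20) {
    x <- runif(40, 0.3, 0.9)
    x[sample(40, sample(1:25, 1))] <- NA
    if (all(is.na(x))) next
    expect_equal(fill_gaps(x)$values, oracle_interp(x))
  }
  # a filled series never has gaps
  x <- c(NA, 0.5, NA, NA, 0.8, NA)
  expect_false(anyNA(fill_gaps(x)$values))
})

test_that("Gaussian smoothing equals brute-force convolution and preserves constants", {
  cfg <- preprocess_config()
  expect_equal(gaussian_smooth(rep(0.7, 30), cfg), rep(0.7, 30))
  imp <- gaussian_smooth(c(0, 0, 1, 0, 0), cfg)
  w <- exp(-(-2:2)^2 / 2)
  expect_equal(imp[3], w[3] / sum(w))              # ~0.4026
  set.seed(7)
  for (k in 1:10) {
    x <- runif(sample(3:60, 1), -1, 1)
    expect_equal(gaussian_smooth(x, cfg), oracle_smooth(x))
    # convex-combination property
    expect_gte(min(gaussian_smooth(x, cfg)), min(x))
    expect_lte(max(gaussian_smooth(x, cfg)), max(x))
  }
  wide <- preprocess_config(filter_window = 7, kernel_sigma = 1.5)
  x <- runif(25)
  expect_equal(gaussian_smooth(x, wide), oracle_smooth(x, 7L, 1.5))
})

test_that("outlier screening flags exactly the deep negative spikes", {
  t <- 1:46
  x <- 0.7 + 0.1 * sin(2 * pi * t / 23)
  x[20] <- x[20] - 0.3                             # injected cloud artifact
  sm <- gaussian_smooth(oracle_interp(x))
  got <- screen_outliers(x, sm)
  # independent z recomputation
  d <- x - sm
  z <- (d - mean(d)) / sd(d)
  expect_identical(which(got$flags == 2L), which(z < -2))
  expect_identical(which(got$flags == 2L), 20L)
  expect_equal(got$values[20], sm[20])
  expect_identical(got$values[-20], x[-20])        # replaces only flagged steps
})

test_that("outlier screening ignores constants and positive spikes", {
  x <- rep(0.6, 30)
  expect_identical(screen_outliers(x, x)$values, x)
  t <- 1:46
  y <- 0.7 + 0.05 * sin(2 * pi * t / 23)
  y[10] <- y[10] + 5                               # huge positive spike
  got <- screen_outliers(y, gaussian_smooth(y))
  expect_false(2L %in% got$flags[10])
  expect_equal(got$values[10], y[10])
})

test_that("detrending removes the OLS line and preserves the mean exactly", {
  x <- rep(0.5, 20) + sin(1:20)
  expect_equal(detrend_series(rep(0.4, 10)), rep(0.4, 10))
  line <- 0.2 + 0.01 * (1:30)
  expect_equal(detrend_series(line), rep(mean(line), 30))
  set.seed(5)
  t <- 1:92
  # symmetric about the series center, so the seasonal part has OLS slope 0
  sig <- 0.7 + 0.1 * cos(2 * pi * (t - 46.5) / 23)
  y <- sig + 0.002 * t
  det <- detrend_series(y)
  expect_equal(mean(det), mean(y))                 # level preserving, exact
  # slope re-estimated on the output is 0 (OLS oracle)
  refit <- coef(lm(det ~ t))[2]
  expect_lt(abs(refit), 1e-12)
  # equals the lm-residual construction exactly ...
  expect_equal(det, unname(y - fitted(lm(y ~ t)) + mean(y)), tolerance = 1e-12)
  # ... and recovers the trend-free seasonal signal at the common mean
  expect_equal(det, sig - mean(sig) + mean(y), tolerance = 1e-9)
  expect_error(detrend_series(c(1, 2)), "at least 3")
})

test_that("the full pixel chain reduces to smoothing for clean symmetric input", {
  # even symmetry around the series center makes the OLS slope exactly 0,
  # so masking, filling, screening and detrending are all identities
  t <- 1:46
  x <- 0.7 + 0.1 * cos(2 * pi * (t - 23.5) / 23)
  got <- preprocess_pixel(x, quality = rep(0L, 46))
  expect_equal(got$values, gaussian_smooth(x))
  expect_true(all(got$flags == 0L))
  expect_equal(unname(got$counts), c(0, 0))
})

test_that("the chain records one interpolated and one replaced step for a dirty pixel", {
  t <- 1:69
  x <- 0.7 + 0.1 * sin(2 * pi * t / 23)
  q <- rep(0L, 69)
  q[15] <- 3L                                      # cloud gap
  x[40] <- x[40] - 0.35                            # negative spike survives QA
  got <- preprocess_pixel(x, quality = q)
  expect_identical(which(got$flags == 1L), 15L)
  expect_identical(which(got$flags == 2L), 40L)
  # stage oracles: the chain equals its hand-composed stages
  masked <- replace(x, 15, NA)
  filled <- oracle_interp(masked)
  ref <- oracle_smooth(filled)
  scr <- screen_outliers(filled, ref)$values
  expect_equal(got$values, detrend_series(oracle_smooth(scr)))
})

test_that("an all-rejected pixel is excluded with an explicit signal", {
  expect_error(preprocess_pixel(runif(23), quality = rep(3L, 23)),
               class = "fc_all_missing")
  sc <- tiny_scene()
  codes <- sc$quality$values
  codes[, 1, 1] <- 3L                              # one all-cloud pixel
  q2 <- quality_cube(codes, sc$quality$grid, sc$quality$calendar)
  res <- preprocess_cube(sc$ndvi, q2)
  expect_equal(unname(res$counts["pixels_excluded"]), 1)
  expect_true(all(is.na(res$cube$values[, 1, 1])))
})

test_that("cube-level preprocessing agrees with the per-pixel chain", {
  sc <- tiny_scene(seed = 21L)
  res <- preprocess_cube(sc$ndvi, sc$quality)
  for (px in list(c(1, 1), c(4, 7), c(8, 8))) {
    one <- preprocess_pixel(sc$ndvi$values[, px[1], px[2]],
                            sc$quality$values[, px[1], px[2]])
    expect_equal(res$cube$values[, px[1], px[2]], one$values)
    expect_identical(res$flags[, px[1], px[2]], one$flags)
  }
})

test_that("preprocess_config validates the filter geometry", {
  expect_error(preprocess_config(filter_window = 4))
  expect_error(preprocess_config(filter_window = 1))
  expect_error(preprocess_config(outlier_z = 1))
  cfg <- preprocess_config()
  expect_equal(cfg$filter_span_days, 80L)          # 5 steps of 16 days
})
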