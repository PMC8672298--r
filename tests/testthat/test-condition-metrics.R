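test_that("quantile transform reproduces the centered rank formula", {
  v20 <- sort(runif(20)) * 0.4 + 0.5
  q20 <- quantile_transform(v20)
  expect_equal(min(q20), 1 / 40)                   # lowest observation
  expect_equal(max(q20), 1 - 1 / 40)               # highest observation
  expect_equal(sort(q20), 1 / 40 + (0:19) / 20)    # exactly the attainable set
  expect_equal(quantile_transform(c(0.6, 0.7, 0.8, 0.9)),
               c(0.125, 0.375, 0.625, 0.875))
  # mid-ranks for ties keep the mean at 0.5
  expect_equal(quantile_transform(c(0.5, 0.5, 0.7)), c(1 / 3, 1 / 3, 5 / 6))
  expect_error(quantile_transform(0.5), "fewer than 2")
  expect_error(quantile_transform(c(0.5, NA)), "fewer than 2")
})

test_that("Q is rank-based: invariant under strictly monotone transforms", {
  set.seed(17)
  for (k in 1:20) {
    v <- runif(sample(3:25, 1), 0.2, 0.9)
    expect_equal(quantile_transform(v), quantile_transform(v^3))
    expect_equal(quantile_transform(v), quantile_transform(atan(2 * v)))
    expect_equal(mean(quantile_transform(v)), 0.5)  # rank-sum identity
  }
})

test_that("PDM is the proportional deviation from the median", {
  expect_equal(pdm_transform(c(0.72, 0.80, 0.88))[1], -0.10)
  expect_equal(pdm_transform(c(0.5, 0.55, 0.45))[2], 0.10)
  expect_equal(pdm_transform(c(0.7, 0.8, 0.9))[2], 0)  # the median itself
  # scale-free in the values
  set.seed(2)
  v <- runif(10, 0.4, 0.9)
  expect_equal(pdm_transform(v * 3.7), pdm_transform(v))
  expect_warning(p <- pdm_transform(c(-0.2, -0.1, 0)), "non-positive median")
  expect_true(all(is.na(p)))
})

test_that("PDM is strictly increasing in NDVI for a fixed median", {
  v <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  p <- pdm_transform(v)
  expect_true(all(diff(p) > 0))
})

test_that("default break schemes match the published class counts", {
  qb <- q_breaks(20)
  expect_equal(qb$n_classes, 21L)
  expect_equal(qb$breaks[1], 1 / 40)
  expect_equal(qb$breaks[20], 1 - 1 / 40)
  expect_equal(unique(round(diff(qb$breaks), 10)), 1 / 20)
  pb <- pdm_breaks()
  expect_equal(pb$n_classes, 10L)
  expect_equal(range(pb$breaks), c(-0.10, 0.10))
  expect_equal(unique(round(diff(pb$breaks), 10)), 0.025)
})

test_that("classification is left-closed with open-ended extremes", {
  pb <- pdm_breaks()
  expect_equal(classify(-0.12, pb), 0L)            # below the first break
  expect_equal(classify(0.10, pb), 9L)             # last break: highest class
  expect_equal(classify(-0.10, pb), 1L)            # at the first break
  qb <- q_breaks(20)
  expect_equal(classify(0.025, qb), 1L)            # Q minimum starts class 1
  expect_true(is.na(classify(NA_real_, qb)))
  m <- classify(matrix(c(0.01, 0.5, NA, 0.99), 2, 2), qb)
  expect_identical(dim(m), c(2L, 2L))
  # a 20-year tie-free pixel-step occupies 20 distinct classes
  v <- sort(runif(20))
  expect_length(unique(classify(quantile_transform(v), qb)), 20L)
})

test_that("spatial histograms are normalized over the masked selection", {
  qb <- q_breaks(4)
  cls <- matrix(c(rep(1L, 5), rep(3L, 5)), 2, 5)
  h <- spatial_histogram(cls, qb)
  expect_equal(sum(h$share), 1)
  expect_equal(h$share[h$class == 1], 0.5)
  msk <- matrix(FALSE, 2, 5); msk[1, ] <- TRUE
  h2 <- spatial_histogram(cls, qb, msk)
  expect_equal(sum(h2$count), 5L)                  # masked-out pixels never counted
  h3 <- spatial_histogram(cls, qb, matrix(FALSE, 2, 5))
  expect_equal(nrow(h3), 0L)                       # empty selection
})

test_that("condition cubes rank each pixel-step across years", {
  sc <- tiny_scene(seed = 31L)
  cond <- condition_cubes(sc$ndvi)
  expect_identical(dim(cond$q), dim(sc$ndvi$values))
  expect_identical(dim(cond$pdm), dim(sc$ndvi$values))
  ny <- length(sc$ndvi$calendar$years)
  # a year that is the pixel-step minimum gets Q = 1/(2n)
  v <- sc$ndvi$values[23 * (0:(ny - 1)) + 5, 3, 3]  # step 5 across years
  y_min <- which.min(v)
  expect_equal(cond$q[23 * (y_min - 1) + 5, 3, 3], 1 / (2 * ny))
  # mean over years is exactly 0.5 at every pixel-step (tie-free)
  M <- matrix(cond$q, nrow = dim(cond$q)[1])
  step_means <- rowsum(M, rep(seq_len(23), ny)) / ny
  expect_equal(max(abs(step_means - 0.5)), 0, tolerance = 1e-12)
})

test_that("condition cubes honour forest and season masks", {
  sc <- tiny_scene(seed = 33L)
  fm <- forest_mask(sc$landcover)
  expect_true(any(!fm))                            # scene has non-forest pixels
  sn <- season_mask_grid(sc$climatology)
  cond <- condition_cubes(sc$ndvi, fm, sn)
  nf <- which(!fm, arr.ind = TRUE)[1, ]
  expect_true(all(is.na(cond$q[, nf[1], nf[2]])))
  expect_true(all(is.na(cond$pdm[, nf[1], nf[2]])))
  expect_identical(dim(cond$in_season), c(23L, 8L, 8L))
  # missing years shrink n_obs but Q stays defined from the rest
  v <- sc$ndvi$values
  v[5, 2, 2] <- NA                                  # drop year 1, step 5
  cube2 <- raster_cube(v, sc$ndvi$grid, sc$ndvi$calendar)
  cond2 <- condition_cubes(cube2, fm, sn)
  if (fm[2, 2]) {
    expect_equal(cond2$n_obs[5, 2, 2], length(sc$ndvi$calendar$years) - 1)
    expect_true(is.na(cond2$q[5, 2, 2]))
    expect_false(anyNA(cond2$q[23 * (1:4) + 5, 2, 2]))
  }
})

test_that("condition slices address dates and reject out-of-record dates", {
  sc <- tiny_scene(seed = 35L)
  cond <- condition_cubes(sc$ndvi)
  sl <- condition_slice(cond, 2003, 209)
  expect_identical(dim(sl$q), c(8L, 8L))
  expect_error(condition_slice(cond, 1999, 209), "outside record")
  expect_error(condition_slice(cond, 2003, 210), "outside record")
})
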