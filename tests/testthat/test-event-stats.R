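test_that("covariate rules extract labelled, disjoint groups", {
  share <- matrix(0.8, 4, 4)
  metric <- matrix(runif(16, 0.4, 0.6), 4, 4)
  all_in <- extract_groups(metric, list(
    covariate_rule("pine", share, function(x) x > 0.70)
  ))
  expect_equal(nrow(all_in), 16L)
  tmin <- matrix(seq(-3, 3, length.out = 16), 4, 4)
  two <- extract_groups(metric, list(
    covariate_rule("frost", tmin, function(x) x < -1),
    covariate_rule("no_frost", tmin, function(x) x >= -1)
  ))
  expect_equal(nrow(two), 16L)
  expect_setequal(unique(two$group), c("frost", "no_frost"))
  counts <- table(two$group)
  expect_equal(sum(counts), 16L)                  # partition, no overlap
  expect_warning(
    extract_groups(metric, list(
      covariate_rule("none", share, function(x) x > 2)
    )),
    "selected no pixels"
  )
})

test_that("a disturbed polygon yields lower Q than its surroundings", {
  sc <- tiny_scene(seed = 41L, non_forest_prob = 0, change_prob = 0)
  foot <- matrix(FALSE, 8, 8); foot[2:4, 2:4] <- TRUE
  dist <- inject_disturbance(sc$ndvi, disturbance_spec(foot, 2004, 8:16, 0.2))
  cond <- condition_cubes(dist$cube)
  sl <- condition_slice(cond, 2004, 177)          # mid-disturbance step 12
  gr <- extract_groups(sl$q, list(
    covariate_rule("affected", foot + 0, function(x) x > 0),
    covariate_rule("unaffected", foot + 0, function(x) x == 0)
  ))
  med <- tapply(gr$value, gr$group, mean)
  expect_lt(med["affected"], med["unaffected"])
})

test_that("the exact Wilcoxon p-value matches textbook cases", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(res$p_value, 1 / 20)               # 1 of C(6,3) assignments
  expect_equal(res$statistic, 6)                  # minimal possible rank sum
  expect_true(res$exact)
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)                   # exchangeable groups
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon is label-symmetric", {
  set.seed(9)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  expect_equal(wilcoxon_rank_sum(a, b, "less")$p_value,
               wilcoxon_rank_sum(b, a, "greater")$p_value)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value)
})

test_that("letter display separates and connects groups correctly", {
  set.seed(12)
  same <- tibble::tibble(
    group = rep(c("g1", "g2", "g3"), each = 6),
    value = rep(c(1, 2, 3, 4, 5, 6), 3)
  )
  cmp <- compare_groups(same)
  expect_true(all(tidy(cmp)$letter == "a"))       # identical groups share a letter
  apart <- tibble::tibble(
    group = rep(c("low", "high"), each = 30),
    value = c(rnorm(30, 0), rnorm(30, 10))
  )
  cmp2 <- compare_groups(apart)
  expect_setequal(tidy(cmp2)$letter, c("a", "b"))
})

test_that("a chain A~B, B~C, A!=C yields the a/ab/b pattern", {
  x <- c(1.0, 2.1, 3.2, 4.0, 5.1, 6.3, 7.0, 8.2)
  dat <- tibble::tibble(
    group = rep(c("A", "B", "C"), each = 8),
    value = c(x, x + 2.4, x + 4.8)
  )
  cmp <- compare_groups(dat)
  td <- tidy(cmp)
  expect_equal(td$letter[td$group == "C"], "a")   # letters follow descending median
  expect_equal(td$letter[td$group == "B"], "ab")
  expect_equal(td$letter[td$group == "A"], "b")
  # invariant to group input order
  cmp2 <- compare_groups(dat[order(dat$value), ])
  expect_equal(tidy(cmp2), td)
})

test_that("linear_fit returns OLS estimates and explained variance", {
  x <- c(100, 104, 108, 112, 116, 120)
  perfect <- suppressWarnings(linear_fit(x, 2 * x))  # lm warns on exact fits
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$r_squared, 1)
  flat <- linear_fit(x, rep(0.5, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant predictor")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("a known budburst-like slope is recovered from noisy data", {
  set.seed(77)
  x <- runif(20, 100, 130)                        # mean budburst DOY
  y <- 0.9 - 0.02 * x + rnorm(20, sd = 0.05)      # yearly mean Q
  fit <- linear_fit(x, y)
  se <- summary(lm(y ~ x))$coefficients[2, 2]
  expect_lt(abs(fit$slope - (-0.02)), 3 * se)
})

test_that("frost probability follows the Gaussian error model", {
  expect_equal(frost_probability(-1), pnorm(2))   # ~0.977, 'roughly 97.5%'
  expect_gte(frost_probability(-1), 0.975)
  expect_equal(frost_probability(0), 0.5)
  expect_gt(frost_probability(-10), 1 - 1e-9)
  t <- seq(-2.5, 2.5, by = 0.25)
  expect_true(all(diff(frost_probability(t)) < 0))  # strictly decreasing
  expect_error(frost_probability(0, sigma = 0), "positive")
})

test_that("gust bins are left-closed with open extremes", {
  expect_equal(as.character(bin_by_gust(18)), "<20")
  expect_equal(as.character(bin_by_gust(47)), ">45")
  expect_equal(as.character(bin_by_gust(40)), "40-45")
  expect_equal(as.character(bin_by_gust(20)), "20-25")
  expect_equal(levels(bin_by_gust(0)),
               c("<20", "20-25", "25-30", "30-35", "35-40", "40-45", ">45"))
  expect_error(bin_by_gust(-1), "non-negative")
})
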