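# Statistical procedures used on top of the condition metrics: covariate
# group extraction, Wilcoxon rank-sum comparisons with compact letter
# displays, the phenology regression, frost probability under
# interpolation error, and wind-gust binning.

#' Covariate threshold rule for group extraction
#'
#' Defines one pixel group by a predicate on a covariate raster, e.g.
#' "Scots pine share > 0.70" or "minimum temperature < -1".
#'
#' @param label Group label.
#' @param covariate Numeric matrix on the analysis grid.
#' @param predicate Vectorised function of the covariate returning
#'   logical, e.g. `function(x) x > 0.70`.
#' @return An object of class `fc_rule`.
#' @export
covariate_rule <- function(label, covariate, predicate) {
  stopifnot(is.character(label), length(label) == 1,
            is.matrix(covariate), is.function(predicate))
  structure(list(label = label, covariate = covariate,
                 predicate = predicate), class = "fc_rule")
}

#' Extract metric values by covariate rules
#'
#' For each rule, collects the metric values at qualifying pixels into a
#' labelled long tibble. Missing metric values are dropped and counted; a
#' rule that selects no pixel yields an empty group with a warning.
#'
#' @param metric Numeric matrix of metric values for one date (e.g. a Q
#'   slice), aligned with every rule's covariate.
#' @param rules A list of [covariate_rule()] objects.
#' @return A tibble with columns `group` and `value`; attribute
#'   `n_dropped` counts missing values removed per group.
#' @export
extract_groups <- function(metric, rules) {
  stopifnot(is.matrix(metric), length(rules) >= 1)
  out <- purrr::map(rules, function(r) {
    stopifnot(inherits(r, "fc_rule"))
    if (!all(dim(r$covariate) == dim(metric)))
      stop("alignment error: covariate and metric rasters differ in shape",
           call. = FALSE)
    sel <- r$predicate(r$covariate)
    sel[is.na(sel)] <- FALSE
    v <- metric[sel]
    dropped <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (!length(v))
      warning("rule '", r$label, "' selected no pixels with data",
              call. = FALSE)
    tibble::tibble(group = r$label, value = v, .dropped = dropped)
  })
  res <- dplyr::bind_rows(out)
  dropped <- vapply(out, function(d) d$.dropped[1] %||% 0L, numeric(1))
  names(dropped) <- vapply(rules, `[[`, "", "label")
  res <- dplyr::select(res, "group", "value")
  attr(res, "n_dropped") <- dropped
  res
}

#' Wilcoxon rank-sum test between two groups
#'
#' Rank-sum statistic with mid-ranks for ties. The p-value is exact (full
#' enumeration of label assignments) when the combined sample size is at
#' most 20 and there are no ties, and otherwise uses the normal
#' approximation with continuity and tie correction.
#'
#' @param a,b Numeric value vectors (both non-empty).
#' @param alternative `"two.sided"`, `"less"` (a shifted left of b) or
#'   `"greater"`.
#' @return A one-row tibble: `statistic` (rank sum of `a`), `u`
#'   (Mann-Whitney U of `a`), `p_value`, `exact`, `n_a`, `n_b`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")$p_value  # 0.05
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= 20L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = use_exact,
                       correct = TRUE)
  )
  tibble::tibble(
    statistic = sum(r[seq_along(a)]),
    u = unname(ht$statistic),
    p_value = ht$p.value,
    alternative = alternative,
    exact = use_exact,
    n_a = length(a), n_b = length(b)
  )
}

# Compact letter display by insert-and-absorb on a significance matrix.
# `sig` is a symmetric logical matrix (TRUE = the pair differs); groups are
# assumed ordered the way letters should be assigned.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!isTRUE(sig[i, j])) next
    hit <- which(vapply(sets, function(s) i %in% s && j %in% s, logical(1)))
    for (h in hit) {
      s <- sets[[h]]
      sets[[h]] <- setdiff(s, i)
      sets <- c(sets, list(setdiff(s, j)))
    }
    # absorb: drop sets contained in another set, and duplicates
    keep <- rep(TRUE, length(sets))
    for (p in seq_along(sets)) for (q in seq_along(sets)) {
      if (p != q && keep[p] && keep[q] &&
          all(sets[[p]] %in% sets[[q]]) &&
          (length(sets[[p]]) < length(sets[[q]]) || p > q))
        keep[p] <- FALSE
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- character(k)
  for (s in seq_along(sets)) {
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  }
  letters_out
}

#' Multi-group comparison with pairwise Wilcoxon tests and letters
#'
#' Runs all pairwise two-sided Wilcoxon rank-sum tests and summarises them
#' as a compact letter display: groups connected by any non-significant
#' pair share a letter, so identical groups always share one and clearly
#' separated groups get distinct letters. Letters are assigned in order of
#' descending group median. P-values are unadjusted by default (an
#' optional Holm adjustment is available).
#'
#' @param data A data frame with the value and group columns (long form,
#'   as returned by [extract_groups()]).
#' @param value,group Column names (tidy-eval) of the values and labels.
#' @param alpha Significance level for the letter display.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return An object of class `fc_group_comparison`: per-group summary
#'   (`groups`), pairwise p-value matrix (`p_matrix`), `alpha`, `adjust`.
#' @export
compare_groups <- function(data, value = value, group = group,
                           alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  df <- tibble::tibble(
    value = rlang::eval_tidy(value, data),
    group = as.character(rlang::eval_tidy(group, data))
  )
  df <- df[!is.na(df$value), ]
  labs <- unique(df$group)
  if (length(labs) < 2) stop("need at least two groups", call. = FALSE)
  split_vals <- split(df$value, df$group)[labs]
  if (any(!lengths(split_vals)))
    stop("empty group: ", paste(labs[!lengths(split_vals)], collapse = ", "),
         call. = FALSE)
  # order groups by descending median; letters follow this order
  med <- vapply(split_vals, stats::median, numeric(1))
  ord <- order(-med)
  labs <- labs[ord]; split_vals <- split_vals[ord]; med <- med[ord]
  k <- length(labs)
  pm <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pm[i, j] <- pm[j, i] <-
      wilcoxon_rank_sum(split_vals[[i]], split_vals[[j]])$p_value
  }
  p_used <- pm
  if (adjust == "holm") {
    up <- upper.tri(pm)
    p_used[up] <- stats::p.adjust(pm[up], method = "holm")
    p_used[lower.tri(pm)] <- t(p_used)[lower.tri(pm)]
  }
  lett <- cld_insert_absorb(!is.na(p_used) & p_used < alpha)
  structure(
    list(groups = tibble::tibble(group = labs, n = lengths(split_vals),
                                 median = med, letter = lett),
         p_matrix = pm, p_used = p_used, alpha = alpha, adjust = adjust),
    class = "fc_group_comparison"
  )
}

#' @export
print.fc_group_comparison <- function(x, ...) {
  cat(sprintf("<fc_group_comparison> %d groups, alpha = %g, adjust = %s\n",
              nrow(x$groups), x$alpha, x$adjust))
  print(x$groups)
  invisible(x)
}

#' Ordinary least-squares fit of a condition metric on a covariate
#'
#' The regression used to relate yearly mean condition metrics to ground
#' observations (e.g. mean budburst day-of-year): OLS slope, intercept,
#' explained variance and the slope's p-value.
#'
#' @param x Predictor (e.g. yearly mean budburst DOY); must not be
#'   constant.
#' @param y Response (e.g. yearly mean Q); at least 3 complete pairs.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  if (stats::sd(y) == 0) {           # flat response: nothing to explain
    return(tibble::tibble(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = 1, n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = unname(s$coefficients[2, 4]),
    n = length(x)
  )
}

#' Frost probability under Gaussian interpolation error
#'
#' Interpolated minimum temperatures carry error; against station
#' observations the difference has a standard deviation of about 0.5 deg
#' C. Treating that error as Gaussian, the probability that the true
#' temperature was at or below `frost_temp` given an interpolated value
#' `t_interp` is `pnorm((frost_temp - t_interp) / sigma)`. At the -1 deg C
#' decision threshold this is `pnorm(2)`, roughly 97.5%.
#'
#' @param t_interp Interpolated minimum temperature(s), deg C.
#' @param sigma Standard deviation of the interpolation error (> 0).
#' @param frost_temp Frost definition temperature (default 0 deg C).
#' @return Probability in (0, 1), same shape as `t_interp`; strictly
#'   decreasing in `t_interp`.
#' @export
frost_probability <- function(t_interp, sigma = 0.5, frost_temp = 0) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  stats::pnorm((frost_temp - t_interp) / sigma)
}

# Wind-gust category definitions: subtle impact below 20 m/s, then 5 m/s
# steps up to "stronger than 45 m/s". Interior bins are left-closed.
GUST_BREAKS <- c(0, 20, 25, 30, 35, 40, 45, Inf)
GUST_LABELS <- c("<20", "20-25", "25-30", "30-35", "35-40", "40-45", ">45")

#' Bin maximum wind-gust speed into storm-impact categories
#'
#' @param gust Non-negative gust speeds (m/s).
#' @return Factor with levels `<20`, `20-25`, ..., `40-45`, `>45`;
#'   interior bins are left-closed (a gust of exactly 40 falls in 40-45).
#' @export
bin_by_gust <- function(gust) {
  if (any(gust < 0, na.rm = TRUE))
    stop("gust speeds must be non-negative", call. = FALSE)
  cut(gust, breaks = GUST_BREAKS, labels = GUST_LABELS, right = FALSE,
      include.lowest = TRUE)
}
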