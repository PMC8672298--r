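# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a multi-group comparison
#'
#' @param x An `fc_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble with one row per group: `group`, `n`, `median`,
#'   `letter`.
#' @export
tidy.fc_group_comparison <- function(x, ...) x$groups

#' One-row summary of a multi-group comparison
#'
#' @param x An `fc_group_comparison`.
#' @param ... Unused.
#' @return A tibble: `n_groups`, `n_total`, `alpha`, `adjust`, `n_pairs`,
#'   `n_significant`.
#' @export
glance.fc_group_comparison <- function(x, ...) {
  up <- upper.tri(x$p_used)
  tibble::tibble(
    n_groups = nrow(x$groups),
    n_total = sum(x$groups$n),
    alpha = x$alpha,
    adjust = x$adjust,
    n_pairs = sum(up),
    n_significant = sum(x$p_used[up] < x$alpha, na.rm = TRUE)
  )
}

#' Tidy a condition cube into a long table
#'
#' @param x An `fc_condition` from [condition_cubes()].
#' @param ... Unused.
#' @return A tibble with one row per pixel-time step: `year`, `doy`,
#'   `row`, `col`, `q`, `pdm`, `in_season`. Non-forest pixels carry `NA`
#'   metrics.
#' @export
tidy.fc_condition <- function(x, ...) {
  d <- dim(x$q)
  ct <- calendar_table(x$calendar)
  tibble::tibble(
    year = rep(ct$year, times = d[2] * d[3]),
    doy = rep(ct$doy, times = d[2] * d[3]),
    row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    col = rep(seq_len(d[3]), each = d[1] * d[2]),
    q = as.vector(x$q),
    pdm = as.vector(x$pdm),
    in_season = as.vector(x$in_season[rep(seq_len(x$calendar$steps_per_year),
                                          length(x$calendar$years)), , ,
                                      drop = FALSE])
  )
}

#' Plot a group comparison as boxplots with letter labels
#'
#' @param object An `fc_group_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_group_comparison <- function(object, ...) {
  g <- object$groups
  g$group <- factor(g$group, levels = g$group)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$median)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "group median",
                  subtitle = sprintf(
                    "groups sharing a letter do not differ (alpha = %g)",
                    object$alpha)) +
    ggplot2::theme_minimal()
}

# Color ramp of the condition maps: red (low) over orange and gray to blue
# (high); used by the map and histogram plots.
fc_palette <- function(n) {
  grDevices::colorRampPalette(
    c("#67001f", "#d6604d", "#f4a582", "#bababa", "#92c5de", "#2166ac",
      "#053061"))(n)
}

#' Map one date of a condition cube
#'
#' Greenness condition map for a single composite date: red shades mark
#' relatively low greenness, blue shades high; out-of-season pixels are
#' light gray.
#'
#' @param object An `fc_condition`.
#' @param year,doy Date to map.
#' @param metric `"q"` or `"pdm"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_condition <- function(object, year = NULL, doy = NULL,
                                  metric = c("q", "pdm"), ...) {
  metric <- match.arg(metric)
  ct <- calendar_table(object$calendar)
  if (is.null(year)) year <- ct$year[1]
  if (is.null(doy)) doy <- ct$doy[1]
  sl <- condition_slice(object, year, doy)
  m <- sl[[metric]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m),
    in_season = as.vector(sl$in_season)
  )
  df$value[!df$in_season] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = fc_palette(21),
                                  na.value = "grey85",
                                  name = toupper(metric)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, %d DOY %d", toupper(metric), year, doy),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a spatial-share histogram
#'
#' Stacked-bar style view of the relative spatial share of each condition
#' class, the summary shown beside every condition map.
#'
#' @param histogram A tibble from [spatial_histogram()] (optionally with a
#'   `metric` column from the pipeline output).
#' @return A ggplot.
#' @export
plot_spatial_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$class), y = .data$share,
                               fill = factor(.data$class))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = fc_palette(max(histogram$class) + 1L)) +
    ggplot2::labs(x = "condition class (low to high)",
                  y = "spatial share") +
    ggplot2::theme_minimal()
}
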