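# Batch orchestration of the full chain: read a scene from disk, condition
# the NDVI series, build the forest and growing-season masks, compute the
# condition metrics, classify, summarise, and write every product with a
# run manifest. Deterministic given identical inputs and config.

#' Write a scene to disk in the layout the pipeline reads
#'
#' NDVI and quality stacks via [write_stack()], land-cover epochs as
#' `landcover_<epoch>.asc`, the monthly climatology as
#' `climatology_<month>.asc`, and a `scene.json` manifest.
#'
#' @param scene An `fc_scene` from [generate_scene()].
#' @param directory Output directory.
#' @return Invisibly, `directory`.
#' @export
write_scene <- function(scene, directory) {
  stopifnot(inherits(scene, "fc_scene"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$ndvi, directory)
  write_stack(scene$quality, directory)
  grid <- scene$ndvi$grid
  for (e in seq_along(scene$landcover$epochs)) {
    fc_write_asc(scene$landcover$rasters[[e]], grid,
                 file.path(directory, sprintf("landcover_%d.asc",
                                              scene$landcover$epochs[e])))
  }
  for (m in 1:12) {
    fc_write_asc(scene$climatology[m, , , drop = TRUE], grid,
                 file.path(directory, sprintf("climatology_%02d.asc", m)))
  }
  jsonlite::write_json(
    list(epochs = scene$landcover$epochs,
         forest_codes = scene$landcover$forest_codes,
         crs_label = grid$crs_label),
    file.path(directory, "scene.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(directory)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param directory Scene directory.
#' @return A list with `ndvi`, `quality`, `landcover`, `climatology`.
#' @export
read_scene <- function(directory) {
  meta <- jsonlite::read_json(file.path(directory, "scene.json"),
                              simplifyVector = TRUE)
  ndvi <- read_stack_dir(directory, "ndvi")
  quality_raw <- read_stack_dir(directory, "quality")
  quality <- quality_cube(array(as.integer(quality_raw$values),
                                dim(quality_raw$values)),
                          quality_raw$grid, quality_raw$calendar)
  lc <- lapply(meta$epochs, function(e) {
    m <- fc_read_asc(file.path(directory, sprintf("landcover_%d.asc", e)),
                     meta$crs_label)$values
    matrix(as.integer(m), nrow(m), ncol(m))
  })
  names(lc) <- meta$epochs
  clim <- vapply(1:12, function(m) {
    fc_read_asc(file.path(directory, sprintf("climatology_%02d.asc", m)),
                meta$crs_label)$values
  }, matrix(0, ndvi$grid$n_rows, ndvi$grid$n_cols))
  list(
    ndvi = ndvi, quality = quality,
    landcover = land_cover_stack(lc, ndvi$grid,
                                 forest_codes = meta$forest_codes),
    climatology = aperm(clim, c(3, 1, 2))
  )
}

#' Pipeline configuration
#'
#' @param scene_dir Directory holding the input scene (layout of
#'   [write_scene()]).
#' @param output_dir Directory for products and the manifest.
#' @param preprocess An [preprocess_config()].
#' @param season_threshold Growing-season temperature threshold (deg C).
#' @param pdm_break_scheme An [class_breaks()] for PDM (default
#'   [pdm_breaks()]); the Q scheme always follows the number of record
#'   years via [q_breaks()].
#' @return An object of class `fc_pipeline_config`.
#' @export
pipeline_config <- function(scene_dir, output_dir,
                            preprocess = preprocess_config(),
                            season_threshold = 5,
                            pdm_break_scheme = pdm_breaks()) {
  structure(list(scene_dir = scene_dir, output_dir = output_dir,
                 preprocess = preprocess,
                 season_threshold = season_threshold,
                 pdm_break_scheme = pdm_break_scheme),
            class = "fc_pipeline_config")
}

#' Run the full condition-monitoring chain
#'
#' Reads the scene, conditions every pixel series, derives the forest and
#' growing-season masks, computes Q and PDM, classifies both on their
#' break schemes, writes per-step Q/PDM/class stacks, per-step spatial
#' histograms (CSV), and a JSON run manifest with a config hash, package
#' version and per-stage counts. Re-running with identical inputs and
#' config reproduces every numeric output bit for bit.
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, a list with `condition` (the [condition_cubes()]
#'   result), `classes` (Q and PDM class cubes), `histograms` (long
#'   tibble), `forest`, `season`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fc_pipeline_config"))
  scene <- read_scene(config$scene_dir)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  prep <- preprocess_cube(scene$ndvi, scene$quality, config$preprocess)
  forest <- forest_mask(scene$landcover)
  season <- season_mask_grid(scene$climatology, config$season_threshold)
  cond <- condition_cubes(prep$cube, forest, season)

  cal <- cond$calendar
  qb <- q_breaks(length(cal$years))
  pb <- config$pdm_break_scheme
  q_class <- classify(cond$q, qb)
  pdm_class <- classify(cond$pdm, pb)

  # per-step exports
  grid <- cond$grid
  q_cube <- raster_cube(cond$q, grid, cal, value_range = NULL, varname = "q")
  pdm_cube <- raster_cube(cond$pdm, grid, cal, value_range = NULL,
                          varname = "pdm")
  qc_cube <- raster_cube(q_class + 0, grid, cal, value_range = NULL,
                         varname = "q_class")
  pc_cube <- raster_cube(pdm_class + 0, grid, cal, value_range = NULL,
                         varname = "pdm_class")
  write_stack(q_cube, out_dir)
  write_stack(pdm_cube, out_dir)
  write_stack(qc_cube, out_dir)
  write_stack(pc_cube, out_dir)

  ct <- calendar_table(cal)
  hist_rows <- purrr::map(seq_len(nrow(ct)), function(i) {
    msk <- forest & cond$in_season[ct$step[i], , , drop = TRUE]
    hq <- spatial_histogram(q_class[i, , , drop = TRUE], qb, msk)
    hp <- spatial_histogram(pdm_class[i, , , drop = TRUE], pb, msk)
    dplyr::bind_rows(
      dplyr::mutate(hq, metric = "Q", .before = 1),
      dplyr::mutate(hp, metric = "PDM", .before = 1)
    ) |>
      dplyr::mutate(year = ct$year[i], doy = ct$doy[i], .before = 1)
  })
  histograms <- dplyr::bind_rows(hist_rows)
  readr::write_csv(histograms, file.path(out_dir, "histograms.csv"))

  counts <- prep$counts
  manifest <- list(
    package_version = as.character(utils::packageVersion("forestcondition")),
    config_hash = rlang::hash(list(
      preprocess = unclass(config$preprocess),
      season_threshold = config$season_threshold,
      pdm_breaks = config$pdm_break_scheme$breaks
    )),
    n_pixels = grid$n_rows * grid$n_cols,
    n_forest_pixels = sum(forest),
    n_seasonless_pixels = sum(season$seasonless),
    observations_total = unname(counts["observations"]),
    observations_masked = unname(counts["masked"]),
    observations_retained = unname(counts["observations"] - counts["masked"]),
    gaps_filled = unname(counts["gap_filled"]),
    outliers_replaced = unname(counts["outliers_replaced"]),
    pixels_excluded = unname(counts["pixels_excluded"]),
    nonpositive_pdm_medians = cond$n_nonpos_median
  )
  if (manifest$n_seasonless_pixels > 0)
    warning(manifest$n_seasonless_pixels, " pixel(s) have no growing season",
            call. = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(condition = cond,
                 classes = list(q = q_class, pdm = pdm_class),
                 histograms = histograms, forest = forest, season = season,
                 manifest = manifest))
}

#' Compare the products of two dates
#'
#' Aligned map pairs and histogram pairs for two dates of the record, the
#' side-by-side view used to contrast, e.g., a drought year with a
#' reference year. Swapping the arguments swaps the outputs.
#'
#' @param result A [run_pipeline()] result (or any list with `condition`,
#'   `classes`, `forest`).
#' @param date_a,date_b Lists `list(year =, doy =)`.
#' @return A list with `a` and `b`, each holding `year`, `doy`, `maps`
#'   (`q`, `pdm`, `in_season` matrices) and `histograms` (per-metric
#'   shares over forest, in-season pixels).
#' @export
compare_dates <- function(result, date_a, date_b) {
  one <- function(dt) {
    sl <- condition_slice(result$condition, dt$year, dt$doy)
    cal <- result$condition$calendar
    qb <- q_breaks(length(cal$years))
    pb <- pdm_breaks()
    msk <- result$forest & sl$in_season
    hq <- spatial_histogram(classify(sl$q, qb), qb, msk)
    hp <- spatial_histogram(classify(sl$pdm, pb), pb, msk)
    list(year = dt$year, doy = dt$doy,
         maps = list(q = sl$q, pdm = sl$pdm, in_season = sl$in_season),
         histograms = dplyr::bind_rows(
           dplyr::mutate(hq, metric = "Q", .before = 1),
           dplyr::mutate(hp, metric = "PDM", .before = 1)
         ))
  }
  list(a = one(date_a), b = one(date_b))
}
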