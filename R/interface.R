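# Reproducible end-to-end runs tying the modules together. Each run_*()
# function takes a config (named list or path to YAML/JSON), fills in
# defaults, executes the pipeline, writes its outputs plus a machine-
# readable copy of the resolved config (seed included) into the output
# directory, and returns the main result invisibly. The command-line entry
# point in inst/cli/dca.R is a thin wrapper over these functions.

.resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

.prep_out_dir <- function(config, mode) {
  out <- config$out_dir %||% stop("config needs an out_dir", call. = FALSE)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  config$input_mode <- mode
  write_resolved_config(config, file.path(out, "resolved_config.json"))
  out
}

.read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format .", ext,
                     " (use PNG or TIFF)", call. = FALSE))
  if (length(dim(img)) == 3 && dim(img)[3] > 3) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  img
}

.grid_from_config <- function(config) {
  g <- config$grid %||% list()
  do.call(grid_spec, g)
}

.trajectory_outputs <- function(traj, config, out) {
  tab <- merge(traj$distances, traj$summary[c("time_min", "mean_D", "sd_D")],
               by = "time_min", sort = TRUE)
  tab <- tab[order(tab$time_min, tab$location),
             c("time_min", "location", "D", "mean_D", "sd_D")]
  utils::write.csv(tab, file.path(out, "trajectory.csv"),
                   row.names = FALSE, quote = FALSE)
  degree <- config$trend_degree %||% 2
  trend <- NULL
  if (nrow(traj$summary) >= degree + 1) {
    trend <- list(
      mean_D = fit_trend(traj$summary$time_min, traj$summary$mean_D, degree),
      sd_D = if (all(is.finite(traj$summary$sd_D))) {
        fit_trend(traj$summary$time_min, traj$summary$sd_D, degree)
      }
    )
    jsonlite::write_json(
      lapply(trend[!vapply(trend, is.null, TRUE)], function(f) {
        f[c("coefficients", "rss", "degree")]
      }),
      file.path(out, "trend.json"), auto_unbox = TRUE, digits = NA)
  } else {
    message("too few time points for a degree-", degree,
            " trend fit; skipping")
  }
  p <- plot_trajectory(traj)
  ggplot2::ggsave(file.path(out, "trajectory.png"), p,
                  width = 7, height = 4, dpi = 150)
  invisible(list(trajectory = traj, table = tab, trend = trend))
}

#' Analyze a directory of vessel images
#'
#' Full image pipeline: read the frames listed in the time map, sample the
#' grid cells of every frame, build the final mixed-state reference, and
#' compute the mixedness trajectory with a polynomial trend fit. Time
#' stamps come exclusively from an explicit filename-to-minutes map (never
#' from file metadata) so runs are deterministic.
#'
#' Config fields: `images_dir`; `time_map` (path to a JSON/YAML object
#' mapping filename to minutes); `grid` (arguments for [grid_spec()]);
#' `space` (default `"lab"`); `reference` (list with `mode`, optional
#' `which` and `final_time`); `trend_degree` (default 2); `out_dir`.
#' Outputs written: `trajectory.csv` (`time_min, location, D, mean_D,
#' sd_D`), `trend.json`, `trajectory.png`, `resolved_config.json`.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Invisibly, a list with the [mixedness_trajectory()] object, the
#'   output table and the trend fits.
#' @export
run_analyze_images <- function(config) {
  config <- .resolve_config(config, list(space = "lab", trend_degree = 2,
                                         reference = list(
                                           mode = "mean_over_locations")))
  for (f in c("images_dir", "time_map", "out_dir")) {
    if (is.null(config[[f]])) stop("config needs ", f, call. = FALSE)
  }
  tm <- read_run_config(config$time_map)
  if (length(tm) == 0) stop("empty time map", call. = FALSE)
  paths <- file.path(config$images_dir, names(tm))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing frame(s): ",
         paste(names(tm)[missing], collapse = ", "), call. = FALSE)
  }
  spec <- .grid_from_config(config)
  readings <- do.call(rbind, lapply(seq_along(tm), function(k) {
    grid_sample(.read_frame(paths[k]), spec,
                time_min = as.numeric(tm[[k]]), space = config$space)
  }))
  message("sampled ", length(tm), " frame(s) x ",
          spec$n_rows * spec$n_cols, " cell(s) in ", config$space,
          " space")
  ref <- do.call(final_reference,
                 c(list(readings = readings), config$reference))
  message("reference: ", attr(ref, "reference_mode"), " at t = ",
          attr(ref, "final_time"), " min")
  traj <- mixedness_trajectory(readings, ref,
                               hue_mode = config$hue_mode %||% "naive")
  out <- .prep_out_dir(config, "images")
  .trajectory_outputs(traj, config, out)
}

#' Analyze a table of sampled color readings
#'
#' Pipeline for non-transparent vessels: readings taken at discrete tank
#' locations (wells read by camera or colorimeter) are ingested from the
#' standard CSV reading table and pushed through the same reference /
#' trajectory / trend chain as the image pipeline. Lab colorimeter rows are
#' used directly.
#'
#' Config fields: `readings_csv`; optional `locations` (allowed location
#' codes; unknown codes abort with the offending list); `reference`,
#' `trend_degree`, `out_dir` as in [run_analyze_images()]. Duplicated
#' `(time, location)` rows are an error.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Invisibly, a list with the trajectory object, table and trend
#'   fits.
#' @export
run_analyze_readings <- function(config) {
  config <- .resolve_config(config, list(trend_degree = 2,
                                         reference = list(
                                           mode = "mean_over_locations")))
  for (f in c("readings_csv", "out_dir")) {
    if (is.null(config[[f]])) stop("config needs ", f, call. = FALSE)
  }
  readings <- read_color_table(config$readings_csv)
  if (nrow(readings) == 0) stop("empty reading table", call. = FALSE)
  if (anyDuplicated(readings[c("time_min", "location")])) {
    dup <- readings[duplicated(readings[c("time_min", "location")]),
                    c("time_min", "location")]
    stop("duplicated (time, location) row(s): ",
         paste(sprintf("(%g, %s)", dup$time_min, dup$location),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$locations)) {
    unknown <- setdiff(unique(readings$location), config$locations)
    if (length(unknown)) {
      stop("unknown location code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  ref <- do.call(final_reference,
                 c(list(readings = readings), config$reference))
  traj <- mixedness_trajectory(readings, ref,
                               hue_mode = config$hue_mode %||% "naive")
  out <- .prep_out_dir(config, "readings")
  .trajectory_outputs(traj, config, out)
}

#' Validate a pH indicator in one or more color spaces
#'
#' Loads a pH-ordered calibration/trajectory table (CSV with columns `pH,
#' space, c1, c2, c3`, pH strictly increasing), takes the last row (highest
#' pH, the intended final state) as the reference, and runs the
#' monotone-decrease validity check in each requested color space,
#' converting through RGB as needed. Typically Lab and HSB pass over a
#' well-chosen pH range while RGB does not.
#'
#' Config fields: `table_csv`; `spaces` (default `c("lab", "hsb", "rgb")`);
#' `tolerance` (default 0); `hue_mode` (default `"naive"`); `out_dir`.
#' Writes `validity.json` with per-space results.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Invisibly, a named list of per-space `indicator_validity`
#'   results.
#' @export
run_validate_indicator <- function(config) {
  config <- .resolve_config(config, list(spaces = c("lab", "hsb", "rgb"),
                                         tolerance = 0,
                                         hue_mode = "naive"))
  for (f in c("table_csv", "out_dir")) {
    if (is.null(config[[f]])) stop("config needs ", f, call. = FALSE)
  }
  df <- utils::read.csv(config$table_csv, stringsAsFactors = FALSE)
  need <- c("pH", "space", "c1", "c2", "c3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("indicator table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) < 1) stop("empty indicator table", call. = FALSE)
  if (is.unsorted(df$pH, strictly = TRUE)) {
    stop("pH column must be strictly increasing", call. = FALSE)
  }
  from <- unique(tolower(df$space))
  if (length(from) != 1) stop("indicator table mixes color spaces",
                              call. = FALSE)
  results <- lapply(stats::setNames(nm = config$spaces), function(sp) {
    rows <- lapply(seq_len(nrow(df)), function(k) {
      convert_color(as.numeric(df[k, c("c1", "c2", "c3")]),
                    from = from, to = sp)
    })
    validate_indicator(rows, rows[[length(rows)]],
                       tolerance = config$tolerance, space = sp,
                       hue_mode = config$hue_mode)
  })
  out <- .prep_out_dir(config, "validate")
  jsonlite::write_json(
    lapply(results, function(r) {
      list(valid = r$valid, distances = r$distances,
           first_violation = if (is.na(r$first_violation)) NULL else
             r$first_violation,
           tolerance = r$tolerance, hue_mode = r$hue_mode)
    }),
    file.path(out, "validity.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(results)
}

#' Fit piecewise power-law rheology from a rheometry CSV
#'
#' Fits each pH group of the input curve by ln-ln ordinary least squares,
#' optionally piecewise at user-supplied breakpoints, and writes the fitted
#' parameters as a parameter table (`pH, shear_range, n_minus_1, K, n`).
#'
#' Config fields: `rheometry_csv`; `breakpoints` (either a vector applied
#' to every pH group, or a named list keyed by pH value); `out_dir`.
#' Writes `power_law_fit.csv`.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Invisibly, the list of fitted [power_law_segment] objects.
#' @export
run_fit_rheology <- function(config) {
  config <- .resolve_config(config, list(breakpoints = numeric()))
  for (f in c("rheometry_csv", "out_dir")) {
    if (is.null(config[[f]])) stop("config needs ", f, call. = FALSE)
  }
  curve <- read_rheometry(config$rheometry_csv)
  groups <- split(curve, curve$pH, drop = TRUE)
  segs <- list()
  for (g in groups) {
    ph <- g$pH[1]
    bp <- config$breakpoints
    if (is.list(bp) && !is.null(names(bp))) {
      bp <- bp[[as.character(ph)]] %||% numeric()
    }
    segs <- c(segs, fit_power_law(g$shear_rate_per_s, g$viscosity_Pa_s,
                                  breakpoints = bp, pH = ph))
  }
  out <- .prep_out_dir(config, "rheometry")
  write_power_law_table(segs, file.path(out, "power_law_fit.csv"))
  message("fitted ", length(segs), " segment(s) over ", length(groups),
          " pH group(s)")
  invisible(segs)
}

#' Simulate a synthetic mixing experiment to disk
#'
#' Thin wrapper over [render_sequence()]: builds the scene from the config,
#' writes PNG frames, the noise-free ground-truth reading table and the
#' filename-to-minutes map into `out_dir`, alongside the resolved config.
#' Re-running with the same config and seed reproduces the directory
#' byte-for-byte.
#'
#' Config fields: any argument of [scene_config()] under `scene`; `times`
#' (minutes); `out_dir`.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Invisibly, the `synthetic_scene` object.
#' @export
run_simulate <- function(config) {
  config <- .resolve_config(config, list(
    scene = list(),
    times = c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 11.5, 13)))
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  sc <- do.call(scene_config, config$scene)
  config$scene <- unclass(sc)
  out <- .prep_out_dir(config, "simulate")
  scene <- render_sequence(sc, times = as.numeric(config$times), dir = out)
  if (scene$n_clipped > 0) {
    message(scene$n_clipped, " noisy channel value(s) clipped to gamut")
  }
  invisible(scene)
}
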