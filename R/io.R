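# Plain-text interchange formats: color reading tables, rheometry curves,
# fitted parameter tables, run configs. All CSV I/O is locale-independent
# (decimal points, fixed column order).

#' Read a color reading table
#'
#' The standard tabular input: one color observation per row with columns
#' `time_min, location, space, c1, c2, c3`. `space` declares the color space
#' of the triple (`lab`, `hsb` or `rgb`); for Lab rows `c1, c2, c3` are
#' `L, a, b`, for HSB rows `h, s, v`, for RGB rows `r, g, b` in \[0, 1\].
#'
#' @param path path to a CSV file.
#' @return A data frame with the six columns above, `time_min` numeric and
#'   `location` character.
#' @export
read_color_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "location", "space", "c1", "c2", "c3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("color table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  df$time_min <- as.numeric(df$time_min)
  df$location <- as.character(df$location)
  df$space <- tolower(as.character(df$space))
  bad <- !df$space %in% c("lab", "hsb", "rgb")
  if (any(bad)) {
    stop("unknown color space in rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$time_min)) || any(df$time_min < 0)) {
    stop("time_min must be finite and >= 0", call. = FALSE)
  }
  if (any(!nzchar(df$location))) stop("empty location code", call. = FALSE)
  for (ch in c("c1", "c2", "c3")) df[[ch]] <- as.numeric(df[[ch]])
  if (any(!is.finite(as.matrix(df[c("c1", "c2", "c3")])))) {
    stop("non-finite color component in table", call. = FALSE)
  }
  df
}

#' Write a color reading table
#'
#' @param df a data frame with columns `time_min, location, space, c1, c2,
#'   c3` (as produced by the synthetic generator or [grid_sample()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_color_table <- function(df, path) {
  need <- c("time_min", "location", "space", "c1", "c2", "c3")
  stopifnot(all(need %in% names(df)))
  utils::write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rheometry curve table
#'
#' Columns: `shear_rate_per_s` (1/s), `viscosity_Pa_s` (Pa s) and an
#' optional `pH` annotation. Within each pH group shear rates must be
#' positive and strictly increasing, viscosities positive.
#'
#' @param path path to a CSV file.
#' @return A data frame with the columns above (pH filled with `NA` when
#'   absent).
#' @export
read_rheometry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("shear_rate_per_s", "viscosity_Pa_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("rheometry table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"pH" %in% names(df)) df$pH <- NA_real_
  df <- df[c(need, "pH")]
  df$shear_rate_per_s <- as.numeric(df$shear_rate_per_s)
  df$viscosity_Pa_s <- as.numeric(df$viscosity_Pa_s)
  if (any(df$shear_rate_per_s <= 0) || any(df$viscosity_Pa_s <= 0)) {
    stop("shear rates and viscosities must be positive", call. = FALSE)
  }
  for (g in split(df, df$pH, drop = TRUE)) {
    if (is.unsorted(g$shear_rate_per_s, strictly = TRUE)) {
      stop("shear rates must be strictly increasing within each pH group",
           call. = FALSE)
    }
  }
  df
}

#' Write fitted power-law parameters as a parameter table
#'
#' One row per segment with columns `pH, shear_range, n_minus_1, K, n`
#' (shear range printed as `"<min>-<max>"` in 1/s).
#'
#' @param segments a list of [power_law_segment] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_power_law_table <- function(segments, path) {
  df <- power_law_table(segments)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' File format is chosen by extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json, got .", ext, call. = FALSE)
  }
}

#' Write the resolved configuration of a run
#'
#' Every pipeline run writes a machine-readable copy of the configuration it
#' actually used (defaults filled in, seed included) so the run can be
#' reproduced exactly.
#'
#' @param config a named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
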