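# Mixedness quantification: per-location color distances D_ij to a final
# mixed-state reference, their mean (global deviation from mixedness) and
# standard deviation (spatial heterogeneity) over time.

#' Sampling-grid specification for vessel images
#'
#' Describes how a frontal image of a transparent vessel is divided into a
#' grid of sampling sections. Each cell is sampled at its center point by
#' averaging a small square pixel window. The default 4x4 grid uses row
#' codes `U, A, B, L` (top to bottom) and column numbers 1--4, giving cell
#' labels `U1 ... L4` in row-major order.
#'
#' @param n_rows,n_cols grid shape, both >= 1.
#' @param row_labels,col_labels ordered label parts; `length(row_labels)`
#'   must equal `n_rows`, likewise for columns.
#' @param sample_window half-width w (pixels) of the averaging window: the
#'   window is `(2w + 1)^2` pixels. Default 2 (a 5x5 window), a small
#'   average that suppresses sensor noise while approximating a point read.
#' @param image_region optional rectangle `c(x0, y0, x1, y1)` in pixel
#'   coordinates (1-based, inclusive) delimiting the vessel inside the
#'   image; default: the whole image.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(n_rows = 4, n_cols = 4,
                      row_labels = c("U", "A", "B", "L"),
                      col_labels = as.character(1:4),
                      sample_window = 2, image_region = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1 || n_cols < 1) stop("grid must be at least 1x1",
                                     call. = FALSE)
  if (identical(row_labels, c("U", "A", "B", "L")) && n_rows != 4) {
    row_labels <- paste0("R", seq_len(n_rows))
  }
  if (length(col_labels) == 4 && n_cols != 4) {
    col_labels <- as.character(seq_len(n_cols))
  }
  if (length(row_labels) != n_rows || length(col_labels) != n_cols) {
    stop("label vectors must match the grid shape", call. = FALSE)
  }
  if (sample_window < 0) stop("sample_window must be >= 0", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 row_labels = as.character(row_labels),
                 col_labels = as.character(col_labels),
                 sample_window = as.integer(sample_window),
                 image_region = image_region),
            class = "grid_spec")
}

#' Cell labels of a grid in row-major order
#'
#' @param spec a [grid_spec].
#' @return Character vector of `n_rows * n_cols` labels, e.g. `"U1" ...
#'   "L4"`.
#' @export
grid_labels <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  as.vector(t(outer(spec$row_labels, spec$col_labels, paste0)))
}

#' Sample grid-cell colors from a vessel image
#'
#' For each grid cell, averages the RGB pixels in the `(2w + 1)^2` window
#' centered on the cell's center point and converts the average to the
#' requested color space. Windows that would cross the image (or region)
#' boundary are clipped, with a warning.
#'
#' @param image an `height x width x 3` numeric array with channels in
#'   \[0, 1\] (as returned by [png::readPNG()]).
#' @param spec a [grid_spec]; its `image_region` defaults to the full
#'   image.
#' @param time_min time stamp (minutes) attached to every reading.
#' @param space output color space: `"lab"` (default), `"hsb"` or `"rgb"`.
#' @return A color reading data frame (`time_min, location, space, c1, c2,
#'   c3`) with one row per cell, labels in row-major order.
#' @export
grid_sample <- function(image, spec = grid_spec(), time_min = 0,
                        space = c("lab", "hsb", "rgb")) {
  space <- match.arg(space)
  stopifnot(inherits(spec, "grid_spec"))
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    stop("image must be an height x width x 3 array", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  reg <- spec$image_region %||% c(1, 1, w, h)
  if (reg[1] < 1 || reg[2] < 1 || reg[3] > w || reg[4] > h ||
      reg[1] > reg[3] || reg[2] > reg[4]) {
    stop("image_region must be a non-empty rectangle within the image",
         call. = FALSE)
  }
  rw <- reg[3] - reg[1] + 1; rh <- reg[4] - reg[2] + 1
  win <- spec$sample_window
  labels <- grid_labels(spec)
  rgb <- matrix(NA_real_, nrow = length(labels), ncol = 3)
  clipped <- 0L
  k <- 0L
  for (i in seq_len(spec$n_rows)) {
    cy <- reg[2] - 1 + round((i - 0.5) / spec$n_rows * rh + 0.5)
    cy <- min(max(cy, 1), h)
    for (j in seq_len(spec$n_cols)) {
      k <- k + 1L
      cx <- reg[1] - 1 + round((j - 0.5) / spec$n_cols * rw + 0.5)
      cx <- min(max(cx, 1), w)
      ys <- (cy - win):(cy + win)
      xs <- (cx - win):(cx + win)
      if (any(ys < 1 | ys > h | xs < 1 | xs > w)) {
        clipped <- clipped + 1L
        ys <- ys[ys >= 1 & ys <= h]
        xs <- xs[xs >= 1 & xs <= w]
      }
      rgb[k, ] <- c(mean(image[ys, xs, 1]), mean(image[ys, xs, 2]),
                    mean(image[ys, xs, 3]))
    }
  }
  if (clipped > 0) {
    warning(clipped, " sampling window(s) clipped at the image boundary",
            call. = FALSE)
  }
  vals <- switch(space,
                 rgb = rgb,
                 lab = .rgb_mat_to_lab(rgb),
                 hsb = t(apply(rgb, 1, function(p) {
                   unclass(rgb_to_hsb(color_rgb(p[1], p[2], p[3])))
                 })))
  data.frame(time_min = time_min, location = labels, space = space,
             c1 = vals[, 1], c2 = vals[, 2], c3 = vals[, 3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct the final mixed-state reference color
#'
#' The reference approximating the fully mixed condition, taken from the
#' readings at the final time point. Two conventions are supported and the
#' one used is recorded on the result: a single designated location
#' (`mode = "single_location"`, e.g. the visually well-mixed cell), or the
#' component-wise mean over all locations at the final time
#' (`mode = "mean_over_locations"`).
#'
#' @param readings a color reading data frame (single color space).
#' @param mode `"single_location"` or `"mean_over_locations"`.
#' @param which location code, required for `"single_location"`.
#' @param final_time time point to use; default the maximum `time_min`
#'   present.
#' @return A color object in the readings' space, with attributes
#'   `reference_mode` and `final_time`.
#' @export
final_reference <- function(readings,
                            mode = c("single_location",
                                     "mean_over_locations"),
                            which = NULL, final_time = NULL) {
  mode <- match.arg(mode)
  .check_readings(readings)
  space <- unique(readings$space)
  final_time <- final_time %||% max(readings$time_min)
  fin <- readings[readings$time_min == final_time, , drop = FALSE]
  if (nrow(fin) == 0) {
    stop("no readings at the final time point (t = ", final_time, " min)",
         call. = FALSE)
  }
  if (mode == "single_location") {
    if (is.null(which)) {
      stop("mode 'single_location' needs a location code in `which`",
           call. = FALSE)
    }
    row <- fin[fin$location == which, , drop = FALSE]
    if (nrow(row) == 0) {
      stop("no final-time reading at location ", which, call. = FALSE)
    }
    vals <- as.numeric(row[1, c("c1", "c2", "c3")])
  } else {
    vals <- colMeans(fin[, c("c1", "c2", "c3")])
  }
  ref <- do.call(paste0("color_", space), as.list(unname(vals)))
  attr(ref, "reference_mode") <- mode
  attr(ref, "final_time") <- final_time
  ref
}

.check_readings <- function(readings) {
  need <- c("time_min", "location", "space", "c1", "c2", "c3")
  miss <- setdiff(need, names(readings))
  if (length(miss)) {
    stop("readings are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(readings) == 0) stop("empty reading table", call. = FALSE)
  if (length(unique(readings$space)) != 1) {
    stop("readings mix color spaces; convert to a single space first",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-location color distances to the reference at one time point
#'
#' Applies the color-space distance to every reading of one frame,
#' producing the distance field `D_ij` for time `i` over locations `j`.
#'
#' @param readings color readings sharing a single `time_min` and space.
#' @param reference the final mixed-state reference color (same space).
#' @param hue_mode hue handling when the space is `"hsb"`.
#' @return A data frame `time_min, location, D`.
#' @export
distance_field <- function(readings, reference, hue_mode = "naive") {
  .check_readings(readings)
  if (length(unique(readings$time_min)) != 1) {
    stop("distance_field expects readings from a single time point",
         call. = FALSE)
  }
  space <- unique(readings$space)
  if (inherits(reference, "dca_color") &&
      !inherits(reference, paste0("color_", space))) {
    stop("reference is in ", sub("color_", "", class(reference)[1]),
         " but readings are in ", space, call. = FALSE)
  }
  ref <- .as_triple(reference, space, "reference")
  D <- vapply(seq_len(nrow(readings)), function(k) {
    color_distance(as.numeric(readings[k, c("c1", "c2", "c3")]), ref,
                   space, hue_mode)
  }, numeric(1))
  data.frame(time_min = readings$time_min, location = readings$location,
             D = D)
}

#' Mixedness trajectory of an experiment
#'
#' Computes, for every time point, the per-location distances `D_ij` to the
#' final mixed-state reference, their arithmetic mean (`mean_D`, the global
#' deviation from the mixed state) and their sample standard deviation
#' (`sd_D`, n - 1 denominator; the degree of spatial heterogeneity).
#' Locations missing at a time point are dropped from that time's mean/SD
#' with a warning (no imputation); with a single location `sd_D` is `NA`
#' with a warning.
#'
#' @param readings a color reading data frame covering >= 1 time point.
#' @param reference the reference color (same space), e.g. from
#'   [final_reference()].
#' @param hue_mode hue handling when the space is `"hsb"`.
#' @return An object of class `"mixing_trajectory"`: a list with
#'   `distances` (data frame `time_min, location, D`), `summary` (data
#'   frame `time_min, mean_D, sd_D, n_locations`), `reference`, `space`.
#' @export
mixedness_trajectory <- function(readings, reference, hue_mode = "naive") {
  .check_readings(readings)
  space <- unique(readings$space)
  if (anyDuplicated(readings[c("time_min", "location")])) {
    stop("duplicated (time, location) reading(s)", call. = FALSE)
  }
  times <- sort(unique(readings$time_min))
  locsets <- lapply(times, function(t) {
    sort(readings$location[readings$time_min == t])
  })
  all_locs <- sort(unique(readings$location))
  if (any(vapply(locsets, function(s) length(s) < length(all_locs), TRUE))) {
    warning("location set differs across time points; ",
            "missing locations are dropped per time point", call. = FALSE)
  }
  dist <- do.call(rbind, lapply(times, function(t) {
    distance_field(readings[readings$time_min == t, , drop = FALSE],
                   reference, hue_mode)
  }))
  summ <- do.call(rbind, lapply(times, function(t) {
    d <- dist$D[dist$time_min == t]
    if (length(d) == 1L) {
      warning("single location at t = ", t,
              " min: sd_D undefined, reported as NA", call. = FALSE)
    }
    data.frame(time_min = t, mean_D = mean(d),
               sd_D = if (length(d) > 1L) stats::sd(d) else NA_real_,
               n_locations = length(d))
  }))
  structure(list(distances = dist, summary = summ, reference = reference,
                 space = space, hue_mode = hue_mode),
            class = "mixing_trajectory")
}

#' @export
print.mixing_trajectory <- function(x, ...) {
  cat(sprintf("<mixing trajectory> %d time point(s), %d location(s), %s space\n",
              nrow(x$summary), length(unique(x$distances$location)),
              x$space))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit a polynomial trend to a time series
#'
#' Ordinary least-squares polynomial (default degree 2, the customary trend
#' model for mean-distance and SD-distance curves) fitted to `(time,
#' value)` pairs.
#'
#' @param time,value numeric vectors of equal length.
#' @param degree polynomial degree >= 0 (default 2); needs at least
#'   `degree + 1` points.
#' @return A list with `coefficients` (constant term first), `fitted`,
#'   `residuals`, `rss` and `degree`.
#' @export
fit_trend <- function(time, value, degree = 2) {
  time <- as.numeric(time); value <- as.numeric(value)
  stopifnot(length(time) == length(value))
  degree <- as.integer(degree)
  if (degree < 0) stop("degree must be >= 0", call. = FALSE)
  if (length(time) < degree + 1L) {
    stop("need at least degree + 1 = ", degree + 1L, " points, got ",
         length(time), call. = FALSE)
  }
  fit <- if (degree == 0) {
    stats::lm(value ~ 1)
  } else {
    stats::lm(value ~ stats::poly(time, degree, raw = TRUE))
  }
  co <- unname(stats::coef(fit))
  list(coefficients = co, fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::residuals(fit)),
       rss = sum(stats::residuals(fit)^2), degree = degree)
}

#' Replicate variability of a color determination
#'
#' Summarizes repeat color readings of one physical sample (e.g. the same
#' suspension dispensed in different wells, capturing illumination
#' heterogeneity): per-channel mean and sample SD, and the mean and SD of
#' the replicate distances to a reference color.
#'
#' @param replicates a list of Lab colors/triples, or a matrix/data frame
#'   with one replicate per row; at least 2 replicates.
#' @param reference the reference color the distances are measured to.
#' @return A list with `n`, `channel_mean`, `channel_sd` (named `L, a, b`),
#'   `d_mean`, `d_sd`.
#' @export
replicate_variability <- function(replicates, reference) {
  rows <- .as_color_rows(replicates, "lab")
  if (nrow(rows) < 2L) stop("need at least 2 replicates", call. = FALSE)
  ref <- .as_triple(reference, "lab", "reference")
  d <- apply(rows, 1, function(p) lab_distance(p, ref))
  list(n = nrow(rows),
       channel_mean = stats::setNames(colMeans(rows), c("L", "a", "b")),
       channel_sd = stats::setNames(apply(rows, 2, stats::sd),
                                    c("L", "a", "b")),
       d_mean = mean(d), d_sd = stats::sd(d))
}
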