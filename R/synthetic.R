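# Synthetic experiment generator: pH fields relaxing toward a set point,
# pH -> color rendering through a calibration table, image sequences with
# per-well illumination noise, and power-law rheometry curves. Provides
# exact ground truth for every analysis operation; no fluid dynamics is
# implied.

#' Configuration of a synthetic mixing scene
#'
#' Defines a grid of cells whose pH relaxes first-order toward a common set
#' point, emulating a pH excursion experiment in a stirred vessel. Three
#' initial patterns are available:
#' \describe{
#'   \item{`uniform`}{every cell starts at `ph_init` with time constant
#'     `tau` — an ideally stirred excursion.}
#'   \item{`top_bottom_layers`}{the top half of the grid starts at
#'     `ph_init` and relaxes with `2 * tau`; the bottom half starts halfway
#'     to `ph_final` and relaxes with `tau` — the classic top-bottom
#'     segregation of a concentrically agitated tank, where the upper
#'     region mixes last.}
#'   \item{`stagnant_spot`}{all cells start at `ph_init` with time constant
#'     `tau`, except one stagnant cell pinned near strongly alkaline pH
#'     (`ph_spot`) with time constant `tau_spot_factor * tau` — a
#'     high-viscosity alkaline pocket created by a poorly placed base
#'     injection, which barely mixes on the experiment's time scale.}
#' }
#'
#' @param n_rows,n_cols grid shape (default 4x4, sixteen cells).
#' @param pattern one of `"top_bottom_layers"`, `"uniform"`,
#'   `"stagnant_spot"`.
#' @param ph_init,ph_final initial and set-point pH, both within
#'   \[1.6, 11.6\]. Defaults 3.3 -> 10.6: an acid-to-base excursion across
#'   the indicator's valid range.
#' @param tau base relaxation time constant in minutes (default 1.5,
#'   i.e. near-homogeneity within a 13-minute experiment).
#' @param noise_sd SD of the per-cell, per-channel Gaussian illumination
#'   noise added in RGB (channels in \[0, 1\]; default 0.005, about one
#'   8-bit step — small relative to pH-driven color changes, as observed
#'   for well-to-well lighting variation).
#' @param cell_px rendered cell size in pixels (default 16).
#' @param seed integer seed recorded in the config and used by every
#'   stochastic output.
#' @param spot `(row, col)` of the stagnant cell (default `c(1, 1)`).
#' @param ph_spot pH of the stagnant cell (default 11.0).
#' @param tau_spot_factor multiplier on `tau` for the stagnant cell
#'   (default 50).
#' @return An object of class `"scene_config"`.
#' @export
scene_config <- function(n_rows = 4, n_cols = 4,
                         pattern = c("top_bottom_layers", "uniform",
                                     "stagnant_spot"),
                         ph_init = 3.3, ph_final = 10.6, tau = 1.5,
                         noise_sd = 0.005, cell_px = 16, seed = 1L,
                         spot = c(1, 1), ph_spot = 11.0,
                         tau_spot_factor = 50) {
  pattern <- match.arg(pattern)
  for (p in c(ph_init, ph_final, ph_spot)) {
    if (p < 1.6 || p > 11.6) {
      stop("pH values must lie within [1.6, 11.6], got ", p, call. = FALSE)
    }
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pattern = pattern, ph_init = ph_init, ph_final = ph_final,
                 tau = tau, noise_sd = noise_sd,
                 cell_px = as.integer(cell_px), seed = as.integer(seed),
                 spot = as.integer(spot), ph_spot = ph_spot,
                 tau_spot_factor = tau_spot_factor),
            class = "scene_config")
}

# initial pH and time-constant maps implied by the pattern
.scene_maps <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols
  ph0 <- matrix(config$ph_init, nr, nc)
  tau <- matrix(config$tau, nr, nc)
  if (config$pattern == "top_bottom_layers") {
    top <- seq_len(ceiling(nr / 2))
    ph0[-top, ] <- (config$ph_init + config$ph_final) / 2
    tau[top, ] <- 2 * config$tau
  } else if (config$pattern == "stagnant_spot") {
    ph0[config$spot[1], config$spot[2]] <- config$ph_spot
    tau[config$spot[1], config$spot[2]] <-
      config$tau_spot_factor * config$tau
  }
  list(ph0 = ph0, tau = tau)
}

#' Synthetic pH field at a given time
#'
#' Each cell relaxes first-order toward the set point:
#' \deqn{pH(cell, t) = pH_{final} + (pH_0(cell) - pH_{final})
#'   e^{-t/\tau(cell)}.}
#' Deterministic given the configuration.
#'
#' @param config a [scene_config].
#' @param t time in minutes, `t >= 0`.
#' @return An `n_rows x n_cols` numeric matrix of pH values.
#' @export
ph_field <- function(config, t) {
  stopifnot(inherits(config, "scene_config"))
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  m <- .scene_maps(config)
  config$ph_final + (m$ph0 - config$ph_final) * exp(-t / m$tau)
}

#' Map pH to the expected indicator color
#'
#' Component-wise piecewise-linear interpolation of the Lab anchors of a
#' calibration table; exact at the anchors. pH values outside the anchor
#' range are rejected (no extrapolation).
#'
#' @param pH pH value(s) within the table's anchor range.
#' @param table a [calibration_table] (default [default_calibration()]).
#' @return For scalar `pH`, a [color_lab]; for a vector, a matrix with
#'   columns `L, a, b` and one row per pH.
#' @export
ph_to_color <- function(pH, table = default_calibration()) {
  stopifnot(inherits(table, "calibration_table"))
  pH <- as.numeric(pH)
  rng <- range(table$pH)
  if (any(pH < rng[1] | pH > rng[2])) {
    stop("pH outside the calibration range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  vals <- vapply(c("L", "a", "b"), function(ch) {
    stats::approx(table$pH, table[[ch]], xout = pH, method = "linear")$y
  }, numeric(length(pH)))
  if (length(pH) == 1L) {
    vals <- as.numeric(vals)
    return(color_lab(vals[1], vals[2], vals[3]))
  }
  colnames(vals) <- c("L", "a", "b")
  vals
}

#' Render a synthetic image sequence with ground truth
#'
#' For each requested time the scene's pH field is mapped to Lab through
#' the calibration table, converted to RGB, painted as uniform cell blocks
#' of `cell_px` pixels, and perturbed by seeded Gaussian illumination noise
#' (one draw per cell, channel and frame, emulating well-to-well lighting
#' heterogeneity) before clipping to the \[0, 1\] gamut. The noise-free
#' per-cell Lab ground truth is returned alongside.
#'
#' @param config a [scene_config]; `config$seed` makes the output
#'   bit-reproducible.
#' @param times time points in minutes (default: 13 frames spanning 0 to 13
#'   minutes, densest early when the color changes fastest).
#' @param table a [calibration_table].
#' @param dir optional directory: when given, frames are written as
#'   `frame_t<minutes>.png`, the ground truth as `truth.csv` and a
#'   filename-to-minutes map as `time_map.json`.
#' @return A list of class `"synthetic_scene"`: `frames` (list of
#'   `H x W x 3` arrays named by time), `truth` (reading data frame of
#'   noise-free Lab values), `times`, `n_clipped` (count of noise-clipped
#'   channel values), `config`, and `files` when `dir` was given.
#' @export
render_sequence <- function(config = scene_config(),
                            times = c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10,
                                      11.5, 13),
                            table = default_calibration(), dir = NULL) {
  stopifnot(inherits(config, "scene_config"),
            inherits(table, "calibration_table"))
  times <- sort(as.numeric(times))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  nr <- config$n_rows; nc <- config$n_cols; px <- config$cell_px
  labels <- grid_labels(grid_spec(nr, nc))
  set.seed(config$seed)
  frames <- vector("list", length(times))
  names(frames) <- format(times, trim = TRUE)
  truth <- vector("list", length(times))
  n_clipped <- 0L
  for (fi in seq_along(times)) {
    ph <- ph_field(config, times[fi])
    lab <- ph_to_color(as.vector(t(ph)), table)  # row-major cell order
    if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1)
    rgb <- .lab_mat_to_rgb(lab, warn_clip = FALSE)
    noise <- matrix(stats::rnorm(length(rgb), sd = config$noise_sd),
                    nrow = nrow(rgb))
    noisy <- rgb + noise
    n_clipped <- n_clipped + sum(noisy < 0 | noisy > 1)
    noisy <- pmin(pmax(noisy, 0), 1)
    img <- array(0, dim = c(nr * px, nc * px, 3))
    k <- 0L
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        k <- k + 1L
        img[(i - 1) * px + seq_len(px), (j - 1) * px + seq_len(px), 1] <-
          noisy[k, 1]
        img[(i - 1) * px + seq_len(px), (j - 1) * px + seq_len(px), 2] <-
          noisy[k, 2]
        img[(i - 1) * px + seq_len(px), (j - 1) * px + seq_len(px), 3] <-
          noisy[k, 3]
      }
    }
    frames[[fi]] <- img
    truth[[fi]] <- data.frame(time_min = times[fi], location = labels,
                              space = "lab", c1 = lab[, 1], c2 = lab[, 2],
                              c3 = lab[, 3])
  }
  truth <- do.call(rbind, truth)
  out <- structure(list(frames = frames, truth = truth, times = times,
                        n_clipped = n_clipped, config = config),
                   class = "synthetic_scene")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- sprintf("frame_t%s.png", format(times, trim = TRUE))
    for (fi in seq_along(times)) {
      png::writePNG(frames[[fi]], file.path(dir, files[fi]))
    }
    write_color_table(truth, file.path(dir, "truth.csv"))
    jsonlite::write_json(stats::setNames(as.list(times), files),
                         file.path(dir, "time_map.json"),
                         auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}

#' Generate a synthetic rheometry curve from power-law segments
#'
#' Log-spaced shear rates within each segment's range, viscosities from the
#' power law times multiplicative log-normal noise
#' (`exp(rnorm(0, noise_sd))`). With `noise_sd = 0` the points lie exactly
#' on the model, so a subsequent fit must recover the parameters.
#'
#' @param segments a [power_law_segment] or a list of them (for a piecewise
#'   curve; segments assumed ordered and non-overlapping).
#' @param n_points points per segment (>= 2, default 50).
#' @param noise_sd SD of the Gaussian noise on `ln eta` (default 0).
#' @param seed optional seed for the noise.
#' @return A rheometry data frame with columns `shear_rate_per_s,
#'   viscosity_Pa_s, pH`.
#' @export
make_rheometry <- function(segments, n_points = 50, noise_sd = 0,
                           seed = NULL) {
  if (inherits(segments, "power_law_segment")) segments <- list(segments)
  stopifnot(all(vapply(segments, inherits, TRUE, "power_law_segment")),
            n_points >= 2)
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(segments, function(seg) {
    g <- exp(seq(log(seg$shear_min), log(seg$shear_max),
                 length.out = n_points))
    eta <- seg$K * g^(seg$n - 1)
    if (noise_sd > 0) {
      eta <- eta * exp(stats::rnorm(length(eta), sd = noise_sd))
    }
    data.frame(shear_rate_per_s = g, viscosity_Pa_s = eta, pH = seg$pH)
  }))
  # drop duplicated shear rates at shared segment boundaries
  out[!duplicated(out[c("pH", "shear_rate_per_s")]), , drop = FALSE]
}
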