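.check_finite <- function(x, fields) {
  bad <- !is.finite(x)
  if (any(bad)) {
    stop("non-finite color component(s): ",
         paste(fields[bad], collapse = ", "), call. = FALSE)
  }
}

#' CIELab color
#'
#' A single color in the CIELab space: `L` in \[0, 100\] (0 = black,
#' 100 = white); `a` runs green (negative) to red (positive) and `b` blue
#' (negative) to yellow (positive), both unbounded.
#'
#' @param L,a,b CIELab coordinates; `L` must lie in \[0, 100\], all finite.
#' @return A named numeric triple of class `c("color_lab", "dca_color")`.
#' @examples
#' color_lab(56.3, -4.1, 18.3)
#' @export
color_lab <- function(L, a, b) {
  x <- c(L = as.numeric(L), a = as.numeric(a), b = as.numeric(b))
  .check_finite(x, c("L", "a", "b"))
  if (x[["L"]] < 0 || x[["L"]] > 100) {
    stop("L must lie in [0, 100], got ", x[["L"]], call. = FALSE)
  }
  structure(x, class = c("color_lab", "dca_color"))
}

#' RGB color
#'
#' A single RGB color with channels in \[0, 1\]; 8-bit values 0--255 are a
#' serialization concern only (divide by 255 on input).
#'
#' @param r,g,b channel intensities in \[0, 1\].
#' @return A named numeric triple of class `c("color_rgb", "dca_color")`.
#' @examples
#' color_rgb(0.5, 0.25, 0.75)
#' @export
color_rgb <- function(r, g, b) {
  x <- c(r = as.numeric(r), g = as.numeric(g), b = as.numeric(b))
  .check_finite(x, c("r", "g", "b"))
  if (any(x < 0 | x > 1)) {
    off <- names(x)[x < 0 | x > 1]
    stop("RGB channel(s) out of [0, 1]: ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  structure(x, class = c("color_rgb", "dca_color"))
}

#' HSB (hue-saturation-brightness) color
#'
#' Hue is an angle in degrees, stored modulo 360; saturation and brightness
#' are percentages in \[0, 100\]. HSB is the hexcone parameterization also
#' known as HSV.
#'
#' @param h hue angle in degrees.
#' @param s,v saturation and brightness in \[0, 100\].
#' @return A named numeric triple of class `c("color_hsb", "dca_color")`.
#' @examples
#' color_hsb(270, 67, 75)
#' @export
color_hsb <- function(h, s, v) {
  x <- c(h = as.numeric(h), s = as.numeric(s), v = as.numeric(v))
  .check_finite(x, c("h", "s", "v"))
  x[["h"]] <- x[["h"]] %% 360
  if (x[["s"]] < 0 || x[["s"]] > 100) {
    stop("saturation must lie in [0, 100], got ", x[["s"]], call. = FALSE)
  }
  if (x[["v"]] < 0 || x[["v"]] > 100) {
    stop("brightness must lie in [0, 100], got ", x[["v"]], call. = FALSE)
  }
  structure(x, class = c("color_hsb", "dca_color"))
}

#' @export
print.dca_color <- function(x, ...) {
  space <- sub("^color_", "", class(x)[1])
  cat(sprintf("<%s> %s\n", space,
              paste(sprintf("%s = %.2f", names(x), unclass(x)),
                    collapse = ", ")))
  invisible(x)
}

# Accept a classed color, a bare numeric triple, or a row of a table.
.as_triple <- function(x, space, arg = deparse(substitute(x))) {
  if (inherits(x, "dca_color")) {
    want <- paste0("color_", space)
    if (!inherits(x, want)) {
      stop(arg, " is a ", class(x)[1], ", expected ", want, call. = FALSE)
    }
    return(unclass(x))
  }
  x <- as.numeric(x)
  if (length(x) != 3L) {
    stop(arg, " must be a color triple (length 3)", call. = FALSE)
  }
  fields <- switch(space,
                   lab = c("L", "a", "b"),
                   rgb = c("r", "g", "b"),
                   hsb = c("h", "s", "v"))
  .check_finite(x, fields)
  names(x) <- fields
  x
}

#' Euclidean color distance in the CIELab space
#'
#' The straight-line distance between two colors in the three-dimensional
#' CIELab space,
#' \deqn{D = \sqrt{(L_1-L_2)^2 + (a_1-a_2)^2 + (b_1-b_2)^2},}
#' the quantity used throughout Dynamic Color Analysis to measure how far a
#' sampling location is from the final mixed state (often written
#' \eqn{\Delta E_{ab}} in color science).
#'
#' @param c1,c2 `color_lab` objects or bare numeric `(L, a, b)` triples.
#' @return A single non-negative number.
#' @examples
#' lab_distance(color_lab(59.2, 0.4, 4.9), color_lab(56.3, -4.1, 18.3))
#' @export
lab_distance <- function(c1, c2) {
  p <- .as_triple(c1, "lab", "c1")
  q <- .as_triple(c2, "lab", "c2")
  sqrt(sum((p - q)^2))
}

#' Euclidean color distance in the HSB space
#'
#' Applies the same straight-line distance to `(h, s, v)` coordinates. In
#' `"naive"` mode hue is treated as a plain number (so 359 and 1 degrees are
#' 358 apart); `"circular"` mode replaces the hue difference by the shortest
#' angular difference (2 degrees in that example). The mode used is attached
#' as the `"hue_mode"` attribute of the result.
#'
#' @param c1,c2 `color_hsb` objects or bare `(h, s, v)` triples.
#' @param hue_mode `"naive"` (default) or `"circular"`.
#' @return A non-negative number with attribute `hue_mode`.
#' @export
hsb_distance <- function(c1, c2, hue_mode = c("naive", "circular")) {
  hue_mode <- match.arg(hue_mode)
  p <- .as_triple(c1, "hsb", "c1")
  q <- .as_triple(c2, "hsb", "c2")
  dh <- p[["h"]] - q[["h"]]
  if (hue_mode == "circular") {
    dh <- ((dh + 180) %% 360) - 180
  }
  d <- sqrt(dh^2 + (p[["s"]] - q[["s"]])^2 + (p[["v"]] - q[["v"]])^2)
  structure(d, hue_mode = hue_mode)
}

#' Euclidean color distance in the RGB space
#'
#' Straight-line distance on `(r, g, b)` channels in \[0, 1\]. Provided so
#' that the indicator-validity check can be run in RGB; RGB distances are
#' generally a poor mixedness indicator (they need not decrease
#' monotonically along a pH trajectory even when Lab and HSB distances do).
#'
#' @param c1,c2 `color_rgb` objects or bare `(r, g, b)` triples.
#' @return A single non-negative number.
#' @export
rgb_distance <- function(c1, c2) {
  p <- .as_triple(c1, "rgb", "c1")
  q <- .as_triple(c2, "rgb", "c2")
  sqrt(sum((p - q)^2))
}

#' Distance between two colors in a named space
#'
#' Dispatcher used by the mixedness pipeline: calls [lab_distance()],
#' [hsb_distance()] or [rgb_distance()] according to `space`.
#'
#' @param c1,c2 color triples in the space named by `space`.
#' @param space `"lab"`, `"hsb"` or `"rgb"`.
#' @param hue_mode passed to [hsb_distance()] when `space = "hsb"`.
#' @return A single non-negative number.
#' @export
color_distance <- function(c1, c2, space = c("lab", "hsb", "rgb"),
                           hue_mode = "naive") {
  space <- match.arg(space)
  switch(space,
         lab = lab_distance(c1, c2),
         hsb = as.numeric(hsb_distance(c1, c2, hue_mode)),
         rgb = rgb_distance(c1, c2))
}

# ---- conversions -----------------------------------------------------------
# The sRGB <-> CIELab chain (sRGB companding, D65 white, 2 degree observer)
# is delegated to grDevices::convertColor; matrix helpers below keep the
# per-color constructors out of inner loops.

.rgb_mat_to_lab <- function(m) {
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}

.lab_mat_to_rgb <- function(m, warn_clip = TRUE) {
  out <- grDevices::convertColor(m, from = "Lab", to = "sRGB", clip = NA)
  bad <- !is.finite(out)
  if (any(bad)) {
    if (warn_clip) {
      warning(sum(rowSums(bad) > 0),
              " color(s) outside the sRGB gamut were clipped", call. = FALSE)
    }
    out <- grDevices::convertColor(m, from = "Lab", to = "sRGB", clip = TRUE)
  }
  pmin(pmax(out, 0), 1)
}

#' Convert an RGB color to CIELab
#'
#' Standard chain: sRGB companding, then XYZ with the D65 white point and
#' the 2 degree standard observer, then Lab. White `(1, 1, 1)` maps to
#' `L = 100, a = b = 0` and black to the origin.
#'
#' @param c a `color_rgb` or bare `(r, g, b)` triple in \[0, 1\].
#' @return A [color_lab] object.
#' @export
rgb_to_lab <- function(c) {
  p <- .as_triple(c, "rgb", "c")
  if (any(p < 0 | p > 1)) {
    stop("RGB channel(s) out of [0, 1]: ",
         paste(names(p)[p < 0 | p > 1], collapse = ", "), call. = FALSE)
  }
  m <- .rgb_mat_to_lab(matrix(p, nrow = 1))
  color_lab(m[1, 1], m[1, 2], m[1, 3])
}

#' Convert a CIELab color to RGB
#'
#' Inverse of [rgb_to_lab()] (same D65 / 2 degree / sRGB chain). Lab colors
#' outside the sRGB gamut are clipped channel-wise with a warning.
#'
#' @param c a `color_lab` or bare `(L, a, b)` triple.
#' @return A [color_rgb] object.
#' @export
lab_to_rgb <- function(c) {
  p <- .as_triple(c, "lab", "c")
  m <- .lab_mat_to_rgb(matrix(p, nrow = 1))
  color_rgb(m[1, 1], m[1, 2], m[1, 3])
}

#' Convert an RGB color to HSB
#'
#' Standard hexcone conversion; hue in degrees, saturation and brightness
#' as percentages. Grays (r = g = b) have saturation 0 and hue 0 by
#' convention.
#'
#' @param c a `color_rgb` or bare `(r, g, b)` triple in \[0, 1\].
#' @return A [color_hsb] object.
#' @export
rgb_to_hsb <- function(c) {
  p <- .as_triple(c, "rgb", "c")
  if (any(p < 0 | p > 1)) {
    stop("RGB channel(s) out of [0, 1]: ",
         paste(names(p)[p < 0 | p > 1], collapse = ", "), call. = FALSE)
  }
  hsv <- grDevices::rgb2hsv(p[["r"]], p[["g"]], p[["b"]], maxColorValue = 1)
  color_hsb(hsv[1] * 360, hsv[2] * 100, hsv[3] * 100)
}

#' Convert an HSB color to RGB
#'
#' Exact inverse hexcone transform (continuous channels, no 8-bit
#' quantization).
#'
#' @param c a `color_hsb` or bare `(h, s, v)` triple.
#' @return A [color_rgb] object.
#' @export
hsb_to_rgb <- function(c) {
  p <- .as_triple(c, "hsb", "c")
  h <- (p[["h"]] %% 360) / 60
  s <- p[["s"]] / 100
  v <- p[["v"]] / 100
  i <- floor(h) %% 6
  f <- h - floor(h)
  x1 <- v * (1 - s)
  x2 <- v * (1 - s * f)
  x3 <- v * (1 - s * (1 - f))
  rgb <- switch(as.character(i),
                "0" = c(v, x3, x1),
                "1" = c(x2, v, x1),
                "2" = c(x1, v, x3),
                "3" = c(x1, x2, v),
                "4" = c(x3, x1, v),
                "5" = c(v, x1, x2))
  color_rgb(rgb[1], rgb[2], rgb[3])
}

#' Convert a color triple between any two supported spaces
#'
#' Routes through RGB as the hub space when needed (e.g. Lab to HSB).
#'
#' @param c a color triple in the space named by `from`.
#' @param from,to `"lab"`, `"hsb"` or `"rgb"`.
#' @return A color object in the `to` space.
#' @export
convert_color <- function(c, from = c("lab", "hsb", "rgb"),
                          to = c("lab", "hsb", "rgb")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) {
    p <- .as_triple(c, from, "c")
    return(do.call(paste0("color_", from), unname(as.list(p))))
  }
  rgb <- switch(from,
                rgb = { p <- .as_triple(c, "rgb", "c"); color_rgb(p[1], p[2], p[3]) },
                lab = lab_to_rgb(c),
                hsb = hsb_to_rgb(c))
  switch(to,
         rgb = rgb,
         lab = rgb_to_lab(rgb),
         hsb = rgb_to_hsb(rgb))
}

# ---- indicator validity ----------------------------------------------------

#' Check a distance sequence for monotone decrease
#'
#' Core of the indicator-validity criterion: a color indicator is usable for
#' mixedness tracking only if the distance to the final-state reference
#' decreases consistently along the approach to homogeneity. The sequence is
#' valid when every step satisfies `d[k+1] <= d[k] + tolerance`.
#'
#' @param d numeric vector of distances, ordered from the start of the
#'   trajectory toward the reference state.
#' @param tolerance non-negative slack allowed on each step (default 0:
#'   strict non-increase).
#' @return A list with `valid` (logical), `distances` (the input) and
#'   `first_violation` (index of the first entry that rises above its
#'   predecessor by more than `tolerance`; `NA` when valid).
#' @export
validate_distance_sequence <- function(d, tolerance = 0) {
  d <- as.numeric(d)
  if (length(d) < 1L) stop("empty distance sequence", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distance value", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  viol <- which(diff(d) > tolerance)
  list(valid = length(viol) == 0L,
       distances = d,
       first_violation = if (length(viol)) viol[1] + 1L else NA_integer_)
}

#' Validate a color indicator along a trajectory
#'
#' Computes the distance of every trajectory color to the reference (final
#' mixed-state) color and checks that the sequence decreases monotonically,
#' up to `tolerance`. For a pH indicator this is run on calibration colors
#' ordered from the starting pH toward the set point; validity means
#' color distance is a faithful proxy for approach to homogeneity over that
#' pH range.
#'
#' @param trajectory a list of color objects/triples, or a numeric matrix or
#'   data frame with one color per row, ordered from the start toward the
#'   reference state.
#' @param reference the reference color (same space).
#' @param tolerance non-negative monotonicity slack (default 0).
#' @param space color space of the trajectory: `"lab"` (default), `"hsb"` or
#'   `"rgb"`.
#' @param hue_mode hue handling for `space = "hsb"`.
#' @return A list of class `"indicator_validity"`: `valid`, `distances`,
#'   `first_violation`, plus the `space`, `hue_mode` and `tolerance` used.
#' @examples
#' cal <- default_calibration()
#' traj <- cal[cal$pH <= 10.6, c("L", "a", "b")]
#' validate_indicator(traj, reference = unlist(traj[nrow(traj), ]))
#' @export
validate_indicator <- function(trajectory, reference, tolerance = 0,
                               space = c("lab", "hsb", "rgb"),
                               hue_mode = "naive") {
  space <- match.arg(space)
  rows <- .as_color_rows(trajectory, space)
  if (nrow(rows) < 1L) stop("empty trajectory", call. = FALSE)
  ref <- .as_triple(reference, space, "reference")
  d <- apply(rows, 1, function(p) color_distance(p, ref, space, hue_mode))
  res <- validate_distance_sequence(d, tolerance)
  structure(c(res, list(space = space, hue_mode = hue_mode,
                        tolerance = tolerance)),
            class = "indicator_validity")
}

#' @export
print.indicator_validity <- function(x, ...) {
  cat(sprintf("Indicator validity in %s space: %s\n", x$space,
              if (x$valid) "VALID" else "INVALID"))
  cat("  distances:", paste(sprintf("%.2f", x$distances), collapse = ", "),
      "\n")
  if (!x$valid) {
    cat(sprintf("  first violation at step %d (%.2f follows %.2f)\n",
                x$first_violation, x$distances[x$first_violation],
                x$distances[x$first_violation - 1L]))
  }
  invisible(x)
}

# rows of colors from list / matrix / data.frame
.as_color_rows <- function(x, space) {
  if (is.list(x) && !is.data.frame(x)) {
    rows <- t(vapply(x, function(ci) .as_triple(ci, space), numeric(3)))
  } else {
    rows <- as.matrix(as.data.frame(x))
    if (ncol(rows) != 3L) stop("colors must have 3 components", call. = FALSE)
    storage.mode(rows) <- "double"
  }
  rows
}

# ---- calibration table -----------------------------------------------------

#' Build a pH-to-color calibration table
#'
#' An ordered set of `(pH, Lab color)` anchors mapping pH to the expected
#' indicator color. Anchors must be strictly increasing in pH and at least
#' two are required.
#'
#' @param pH numeric vector of anchor pH values (strictly increasing).
#' @param L,a,b CIELab coordinates of the anchor colors.
#' @return A data frame of class `"calibration_table"` with columns
#'   `pH, L, a, b`.
#' @seealso [default_calibration()], [ph_to_color()]
#' @export
calibration_table <- function(pH, L, a, b) {
  pH <- as.numeric(pH)
  if (length(pH) < 2L) stop("need at least 2 calibration anchors",
                            call. = FALSE)
  if (any(diff(pH) <= 0)) {
    stop("anchor pH values must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(L) == length(pH), length(a) == length(pH),
            length(b) == length(pH))
  for (i in seq_along(pH)) color_lab(L[i], a[i], b[i])  # validates ranges
  structure(data.frame(pH = pH, L = as.numeric(L), a = as.numeric(a),
                       b = as.numeric(b)),
            class = c("calibration_table", "data.frame"))
}

#' Default synthetic pH-to-color calibration
#'
#' Six anchors spanning pH 1.6 to 11.6 that emulate the hue progression of
#' an anthocyanin indicator (pink, magenta, violet, blue, blue-green,
#' green). The Lab values are synthetic stand-ins chosen so that (i) every
#' anchor and every interpolated color lies inside the sRGB gamut, (ii) the
#' distances of the first five anchors to the pH 10.6 anchor decrease
#' strictly — so a pH excursion within 1.6--10.6 passes the
#' indicator-validity check — and (iii) the trajectory continued to the
#' pH 11.6 anchor violates monotonicity, reproducing the known failure of
#' the indicator when the range is stretched to strongly alkaline pH.
#'
#' @return A [calibration_table] with 6 anchors.
#' @export
default_calibration <- function() {
  calibration_table(
    pH = c(1.6, 3.3, 5.6, 8.0, 10.6, 11.6),
    L  = c(65, 55, 47, 42, 48, 55),
    a  = c(45, 48, 28, 8, -22, -38),
    b  = c(8, -12, -28, -38, -8, 25)
  )
}
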