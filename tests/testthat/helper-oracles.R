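# Independent oracles, kept deliberately separate from the package code
# paths they check.

# sRGB -> CIELab chain coded directly from the published constants
# (sRGB companding, sRGB->XYZ matrix, D65 white, 2 degree observer).
oracle_rgb_to_lab <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  wn <- c(0.95047, 1, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / wn)
  c(116 * fx[2] - 16, 500 * (fx[1] - fx[2]), 200 * (fx[2] - fx[3]))
}

# hexcone max/min formula for RGB -> HSB, h in degrees, s/v in percent
oracle_rgb_to_hsb <- function(rgb) {
  mx <- max(rgb); mn <- min(rgb); d <- mx - mn
  h <- if (d == 0) 0
  else if (mx == rgb[1]) 60 * (((rgb[2] - rgb[3]) / d) %% 6)
  else if (mx == rgb[2]) 60 * ((rgb[3] - rgb[1]) / d + 2)
  else 60 * ((rgb[1] - rgb[2]) / d + 4)
  s <- if (mx == 0) 0 else d / mx
  c(h, s * 100, mx * 100)
}

# all-pairs scan: a sequence is non-increasing iff no later entry exceeds
# an earlier one (tolerance 0)
oracle_nonincreasing <- function(d) {
  for (i in seq_along(d)) {
    for (j in seq_along(d)) {
      if (j > i && d[j] > d[i]) return(FALSE)
    }
  }
  TRUE
}

# closed-form simple linear regression (normal equations)
oracle_simple_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - sl * mean(x), slope = sl)
}

# polynomial least squares via explicit normal equations
oracle_poly_fit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# build a color reading data frame from a matrix of Lab rows
make_readings <- function(lab, time_min = 0, locations = NULL,
                          space = "lab") {
  locations <- locations %||% paste0("P", seq_len(nrow(lab)))
  data.frame(time_min = time_min, location = locations, space = space,
             c1 = lab[, 1], c2 = lab[, 2], c3 = lab[, 3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
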