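# ggplot2 figures for trajectories and rheology curves.

#' Plot a mixedness trajectory
#'
#' Mean distance to the final mixed state and the standard deviation of the
#' distance field versus time, as two panels, with the per-location
#' distances shown faintly behind the mean.
#'
#' @param traj a `mixing_trajectory` from [mixedness_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  stopifnot(inherits(traj, "mixing_trajectory"))
  s <- traj$summary
  long <- rbind(
    data.frame(time_min = s$time_min, value = s$mean_D,
               panel = "mean D (global deviation)"),
    data.frame(time_min = s$time_min, value = s$sd_D,
               panel = "SD of D (heterogeneity)"))
  per_loc <- data.frame(time_min = traj$distances$time_min,
                        value = traj$distances$D,
                        location = traj$distances$location,
                        panel = "mean D (global deviation)")
  ggplot2::ggplot(long, ggplot2::aes(x = time_min, y = value)) +
    ggplot2::geom_line(data = per_loc,
                       ggplot2::aes(group = location),
                       color = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (min)",
                  y = sprintf("color distance (%s)", traj$space)) +
    ggplot2::theme_minimal()
}

#' Plot a rheometry curve with fitted power-law segments
#'
#' Apparent viscosity versus shear rate on log-log axes; fitted segments,
#' when given, are drawn over their validity ranges.
#'
#' @param curve a rheometry data frame (`shear_rate_per_s,
#'   viscosity_Pa_s`, optional `pH`).
#' @param segments optional list of [power_law_segment] objects.
#' @return A ggplot object.
#' @export
plot_rheology <- function(curve, segments = NULL) {
  stopifnot(all(c("shear_rate_per_s", "viscosity_Pa_s") %in% names(curve)))
  curve$pH_lab <- if ("pH" %in% names(curve)) factor(curve$pH) else
    factor("data")
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = shear_rate_per_s,
                                    y = viscosity_Pa_s,
                                    color = pH_lab)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "shear rate (1/s)", y = "apparent viscosity (Pa s)",
                  color = "pH") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    lines <- do.call(rbind, lapply(segments, function(seg) {
      g <- exp(seq(log(seg$shear_min), log(seg$shear_max),
                   length.out = 50))
      data.frame(shear_rate_per_s = g,
                 viscosity_Pa_s = seg$K * g^(seg$n - 1),
                 pH_lab = factor(if (is.finite(seg$pH)) seg$pH else "fit"))
    }))
    p <- p + ggplot2::geom_line(data = lines, linetype = "dashed")
  }
  p
}
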