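uniform_image <- function(rgb, h = 64, w = 64) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

test_that("grid sampling of a uniform image returns 16 equal readings", {
  img <- uniform_image(c(0.3, 0.6, 0.2))
  r <- grid_sample(img, grid_spec(), time_min = 2, space = "rgb")
  expect_identical(nrow(r), 16L)
  expect_identical(r$location,
                   as.vector(t(outer(c("U", "A", "B", "L"), 1:4, paste0))))
  expect_identical(r$location[1], "U1")
  expect_identical(r$location[16], "L4")
  expect_true(all(abs(r$c1 - 0.3) < 1e-12))
  expect_true(all(abs(r$c2 - 0.6) < 1e-12))
  expect_true(all(abs(r$c3 - 0.2) < 1e-12))
  expect_true(all(r$time_min == 2))
})

test_that("grid sampling matches a direct pixel-averaging oracle", {
  # two-tone image: left half dark, right half light
  img <- array(0.2, dim = c(40, 40, 3))
  img[, 21:40, ] <- 0.8
  spec <- grid_spec(2, 2, row_labels = c("T", "B"),
                    col_labels = c("1", "2"), sample_window = 3)
  r <- grid_sample(img, spec, space = "rgb")
  # oracle: recompute the window means from raw pixels at the cell centers
  centers_y <- round((c(1, 2) - 0.5) / 2 * 40 + 0.5)
  centers_x <- round((c(1, 2) - 0.5) / 2 * 40 + 0.5)
  k <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      k <- k + 1
      ys <- (centers_y[i] - 3):(centers_y[i] + 3)
      xs <- (centers_x[j] - 3):(centers_x[j] + 3)
      expect_equal(r$c1[k], mean(img[ys, xs, 1]))
    }
  }
  # windows crossing the region boundary are clipped with a warning
  tiny <- grid_spec(1, 1, row_labels = "C", col_labels = "1",
                    sample_window = 30)
  expect_warning(grid_sample(img, tiny, space = "rgb"), "clipped")
})

test_that("final reference supports both conventions", {
  lab <- rbind(c(50, 1, 1), c(60, 2, 2), c(55, 3, 6))
  r <- make_readings(lab, time_min = 13, locations = c("B1", "B2", "B3"))
  # designated single location
  ref1 <- final_reference(r, "single_location", which = "B2")
  expect_equal(as.numeric(unclass(ref1)), c(60, 2, 2))
  expect_identical(attr(ref1, "reference_mode"), "single_location")
  # mean over locations: component-wise arithmetic mean
  ref2 <- final_reference(r, "mean_over_locations")
  expect_equal(as.numeric(unclass(ref2)), unname(colMeans(lab)))
  # identical colors collapse to that color
  same <- make_readings(rbind(c(30, 0, 5), c(30, 0, 5), c(30, 0, 5)),
                        time_min = 13)
  expect_equal(as.numeric(unclass(final_reference(same, "mean_over_locations"))),
               c(30, 0, 5))
  expect_error(final_reference(r, "single_location", which = "Z9"),
               "no final-time reading")
  expect_error(final_reference(r, "single_location", which = "B1",
                               final_time = 99), "final time")
})

test_that("distance field equals element-wise distances", {
  lab <- rbind(c(24.63, -0.61, 2.78), c(30, 5, 5), c(22, -2, 1))
  r <- make_readings(lab, time_min = 40, locations = c("12M", "5U", "3L"))
  ref <- color_lab(22.992, -1.398, 1.05)
  df <- distance_field(r, ref)
  expect_equal(df$D[1], 2.5094, tolerance = 1e-4)
  for (k in 1:3) expect_equal(df$D[k], lab_distance(lab[k, ], ref))
  # all readings at the reference give a zero field
  at_ref <- make_readings(matrix(rep(unclass(ref), 3), 3, byrow = TRUE),
                          time_min = 40)
  expect_true(all(distance_field(at_ref, ref)$D == 0))
  # space mismatch between reference and readings is rejected
  r_hsb <- r; r_hsb$space <- "hsb"
  expect_error(distance_field(r_hsb, ref), "readings are in hsb")
})

test_that("trajectory mean and SD match direct computation", {
  # the five printed port distances at t = 40 min, realized as Lab colors
  d <- c(2.5094, 17.022, 1.7953, 8.1427, 1.3766)
  lab <- cbind(d, 0, 0)
  ref <- color_lab(0, 0, 0)
  r <- make_readings(lab, time_min = 40,
                     locations = c("12M", "7U", "1U", "5U", "3L"))
  traj <- mixedness_trajectory(r, ref)
  expect_equal(traj$summary$mean_D, 6.1692, tolerance = 1e-6)
  expect_equal(traj$summary$sd_D, 6.655301, tolerance = 1e-6)
  expect_identical(traj$summary$n_locations, 5L)
  # one-frame trajectory agrees with distance_field + mean/sd
  df <- distance_field(r, ref)
  expect_equal(traj$distances$D, df$D)
  expect_equal(traj$summary$mean_D, mean(df$D))
  expect_equal(traj$summary$sd_D, sd(df$D))
})

test_that("mean and SD are invariant to location order and translation", {
  set.seed(17)
  lab <- cbind(runif(6, 20, 80), runif(6, -30, 30), runif(6, -30, 30))
  ref <- c(50, 0, 0)
  r1 <- make_readings(lab, time_min = 1)
  r2 <- r1[sample(6), ]
  t1 <- mixedness_trajectory(r1, color_lab(ref[1], ref[2], ref[3]))
  t2 <- mixedness_trajectory(r2, color_lab(ref[1], ref[2], ref[3]))
  expect_equal(t1$summary$mean_D, t2$summary$mean_D)
  expect_equal(t1$summary$sd_D, t2$summary$sd_D)
  # adding the same offset to readings and reference changes nothing
  off <- c(5, -3, 2)
  shifted <- sweep(lab, 2, off, `+`)
  t3 <- mixedness_trajectory(make_readings(shifted, time_min = 1),
                             color_lab(ref[1] + 5, ref[2] - 3, ref[3] + 2))
  expect_equal(t3$summary$mean_D, t1$summary$mean_D)
  expect_equal(t3$summary$sd_D, t1$summary$sd_D)
})

test_that("degenerate trajectories warn or error as specified", {
  one <- make_readings(rbind(c(50, 0, 0)), time_min = 0)
  expect_warning(t1 <- mixedness_trajectory(one, color_lab(40, 0, 0)),
                 "sd_D undefined")
  expect_true(is.na(t1$summary$sd_D))
  # differing location sets across times drop the missing location
  r <- rbind(make_readings(rbind(c(50, 0, 0), c(60, 0, 0)), time_min = 0,
                           locations = c("A1", "A2")),
             make_readings(rbind(c(55, 0, 0)), time_min = 1,
                           locations = "A1"))
  w <- capture_warnings(t2 <- mixedness_trajectory(r, color_lab(40, 0, 0)))
  expect_true(any(grepl("differs across time", w)))
  expect_true(any(grepl("sd_D undefined", w)))
  expect_identical(t2$summary$n_locations, c(2L, 1L))
  dup <- rbind(one, one)
  expect_error(mixedness_trajectory(dup, color_lab(40, 0, 0)), "duplicated")
})

test_that("trend fitting recovers exact polynomials and matches the normal equations", {
  tt <- 0:10
  y <- 2 - 0.5 * tt + 0.03 * tt^2
  f <- fit_trend(tt, y, degree = 2)
  expect_equal(f$coefficients, c(2, -0.5, 0.03), tolerance = 1e-10)
  expect_lt(f$rss, 1e-18)
  f0 <- fit_trend(tt, rep(4.2, 11), degree = 0)
  expect_equal(f0$coefficients, 4.2)
  set.seed(23)
  yr <- rnorm(11)
  f2 <- fit_trend(tt, yr, degree = 2)
  expect_equal(f2$coefficients, oracle_poly_fit(tt, yr, 2),
               tolerance = 1e-8)
  expect_error(fit_trend(1:2, 1:2, degree = 2), "at least degree \\+ 1")
})

test_that("replicate variability summarizes channels and distances", {
  ref <- color_lab(50, 0, 0)
  same <- rbind(c(48, 1, 2), c(48, 1, 2), c(48, 1, 2))
  v <- replicate_variability(same, ref)
  expect_equal(unname(v$channel_sd), c(0, 0, 0))
  expect_equal(v$d_sd, 0)
  # n = 2 closed form: SD = |difference| / sqrt(2)
  two <- rbind(c(48, 1, 2), c(52, 3, -2))
  v2 <- replicate_variability(two, ref)
  expect_equal(unname(v2$channel_sd), abs(two[1, ] - two[2, ]) / sqrt(2))
  # six random replicates vs the direct formulas
  set.seed(31)
  six <- cbind(runif(6, 40, 60), runif(6, -5, 5), runif(6, -5, 5))
  v6 <- replicate_variability(six, ref)
  expect_equal(unname(v6$channel_mean), unname(colMeans(six)))
  expect_equal(unname(v6$channel_sd), unname(apply(six, 2, sd)))
  d <- apply(six, 1, function(p) sqrt(sum((p - unclass(ref))^2)))
  expect_equal(v6$d_mean, mean(d))
  expect_equal(v6$d_sd, sd(d))
  expect_error(replicate_variability(rbind(c(1, 2, 3)), ref), "at least 2")
})
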