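tmp <- function(...) file.path(tempdir(), ...)

test_that("the image pipeline runs end to end on a simulated scene", {
  scene_dir <- tmp("iface_scene")
  out_dir <- tmp("iface_out")
  unlink(c(scene_dir, out_dir), recursive = TRUE)
  run_simulate(list(scene = list(pattern = "top_bottom_layers", seed = 8),
                    times = c(0, 1, 2, 4, 8, 13), out_dir = scene_dir))
  expect_true(file.exists(file.path(scene_dir, "time_map.json")))
  res <- run_analyze_images(list(
    images_dir = scene_dir,
    time_map = file.path(scene_dir, "time_map.json"),
    reference = list(mode = "mean_over_locations"),
    out_dir = out_dir))
  tab <- read.csv(file.path(out_dir, "trajectory.csv"))
  expect_identical(nrow(tab), 16L * 6L)  # grid cells x frames
  expect_identical(names(tab),
                   c("time_min", "location", "D", "mean_D", "sd_D"))
  expect_true(file.exists(file.path(out_dir, "resolved_config.json")))
  expect_true(file.exists(file.path(out_dir, "trend.json")))
  expect_true(file.exists(file.path(out_dir, "trajectory.png")))
  # the mixed end state is closer to the reference than the start
  s <- res$trajectory$summary
  expect_lt(s$mean_D[nrow(s)], s$mean_D[1])
})

test_that("a single frame at the reference gives an all-zero distance field", {
  scene_dir <- tmp("iface_one")
  out_dir <- tmp("iface_one_out")
  unlink(c(scene_dir, out_dir), recursive = TRUE)
  run_simulate(list(scene = list(pattern = "uniform", noise_sd = 0,
                                 seed = 1, tau = 0.01),
                    times = 13, out_dir = scene_dir))
  suppressWarnings(res <- run_analyze_images(list(
    images_dir = scene_dir,
    time_map = file.path(scene_dir, "time_map.json"),
    out_dir = out_dir)))
  expect_true(all(res$table$D < 1e-8))
})

test_that("missing frames and malformed time maps abort the image run", {
  scene_dir <- tmp("iface_missing")
  unlink(scene_dir, recursive = TRUE)
  run_simulate(list(scene = list(seed = 2), times = c(0, 13),
                    out_dir = scene_dir))
  bad_map <- tmp("bad_map.json")
  jsonlite::write_json(list(frame_t0.png = 0, ghost.png = 7), bad_map,
                       auto_unbox = TRUE)
  expect_error(run_analyze_images(list(images_dir = scene_dir,
                                       time_map = bad_map,
                                       out_dir = tmp("x"))),
               "missing frame.*ghost")
})

test_that("the readings pipeline reproduces printed port distances", {
  # t = 40 min colorimeter reading at port 12M plus a final state whose
  # location mean equals the printed reference vector
  ref <- c(22.992, -1.398, 1.05)
  locs <- c("12M", "7U", "1U", "5U", "3L")
  readings <- rbind(
    data.frame(time_min = 40, location = "12M", space = "lab",
               c1 = 24.63, c2 = -0.61, c3 = 2.78),
    data.frame(time_min = 780, location = locs, space = "lab",
               c1 = ref[1], c2 = ref[2], c3 = ref[3]))
  csv <- tmp("readings.csv")
  write_color_table(readings, csv)
  out_dir <- tmp("readings_out")
  unlink(out_dir, recursive = TRUE)
  suppressWarnings(res <- run_analyze_readings(list(
    readings_csv = csv, out_dir = out_dir,
    reference = list(mode = "mean_over_locations"))))
  d12 <- res$table$D[res$table$location == "12M" &
                       res$table$time_min == 40]
  expect_equal(d12, 2.5094, tolerance = 1e-4)
})

test_that("the readings pipeline rejects malformed tables", {
  out_dir <- tmp("bad_readings_out")
  empty <- tmp("empty.csv")
  writeLines("time_min,location,space,c1,c2,c3", empty)
  expect_error(run_analyze_readings(list(readings_csv = empty,
                                         out_dir = out_dir)), "empty")
  dup <- data.frame(time_min = c(0, 0), location = c("A1", "A1"),
                    space = "lab", c1 = 50, c2 = 0, c3 = 0)
  dup_csv <- tmp("dup.csv")
  write_color_table(dup, dup_csv)
  expect_error(run_analyze_readings(list(readings_csv = dup_csv,
                                         out_dir = out_dir)),
               "duplicated")
  ok <- data.frame(time_min = c(0, 1), location = "Z9", space = "lab",
                   c1 = 50, c2 = 0, c3 = 0)
  ok_csv <- tmp("unknown_loc.csv")
  write_color_table(ok, ok_csv)
  expect_error(run_analyze_readings(list(readings_csv = ok_csv,
                                         locations = c("12M", "5U"),
                                         out_dir = out_dir)),
               "unknown location.*Z9")
})

test_that("indicator validation reports per-space verdicts", {
  # the default calibration restricted to the valid excursion range
  cal <- default_calibration()
  sub <- cal[cal$pH <= 10.6, ]
  tab <- data.frame(pH = sub$pH, space = "lab", c1 = sub$L, c2 = sub$a,
                    c3 = sub$b)
  csv <- tmp("indicator.csv")
  write.csv(tab, csv, row.names = FALSE)
  out_dir <- tmp("indicator_out")
  unlink(out_dir, recursive = TRUE)
  res <- run_validate_indicator(list(table_csv = csv, out_dir = out_dir))
  expect_true(res$lab$valid)
  expect_true(res$hsb$valid)
  rep <- jsonlite::read_json(file.path(out_dir, "validity.json"),
                             simplifyVector = TRUE)
  expect_identical(sort(names(rep)), c("hsb", "lab", "rgb"))
  expect_true(rep$lab$valid)

  # synthetic counterexample: Lab distances decrease but RGB ones do not
  lab_bad <- rbind(c(65.925, 22.816, -23.477),
                   c(31.582, 14.174, -18.881),
                   c(55.220, -7.276, 15.310),
                   c(33.384, -7.292, 19.232))
  tab2 <- data.frame(pH = c(2, 5, 8, 10.6), space = "lab",
                     c1 = lab_bad[, 1], c2 = lab_bad[, 2],
                     c3 = lab_bad[, 3])
  csv2 <- tmp("indicator_rgb.csv")
  write.csv(tab2, csv2, row.names = FALSE)
  res2 <- run_validate_indicator(list(table_csv = csv2,
                                      out_dir = tmp("indicator_out2")))
  expect_true(res2$lab$valid)
  expect_false(res2$rgb$valid)

  # one-row table is trivially valid; unsorted pH is rejected
  one <- tab[1, ]
  csv3 <- tmp("indicator_one.csv")
  write.csv(one, csv3, row.names = FALSE)
  res3 <- run_validate_indicator(list(table_csv = csv3,
                                      out_dir = tmp("indicator_out3")))
  expect_true(res3$lab$valid)
  unsorted <- tab[c(2, 1, 3), ]
  csv4 <- tmp("indicator_unsorted.csv")
  write.csv(unsorted, csv4, row.names = FALSE)
  expect_error(run_validate_indicator(list(table_csv = csv4,
                                           out_dir = tmp("y"))),
               "strictly increasing")
})

test_that("rheology fitting run writes a parameter table per segment", {
  segs <- blue_maize_segments()
  cur <- do.call(rbind, lapply(split(segs, vapply(segs, `[[`, 0, "pH")),
                               function(group) {
                                 make_rheometry(group, n_points = 25)
                               }))
  csv <- tmp("rheometry.csv")
  write.csv(cur, csv, row.names = FALSE)
  out_dir <- tmp("rheo_out")
  unlink(out_dir, recursive = TRUE)
  fits <- run_fit_rheology(list(
    rheometry_csv = csv,
    breakpoints = list(`10.6` = 500, `3.3` = c(500, 1000), `1.6` = 500),
    out_dir = out_dir))
  tab <- read.csv(file.path(out_dir, "power_law_fit.csv"))
  expect_identical(nrow(tab), 10L)  # one row per input segment
  expect_identical(names(tab), c("pH", "shear_range", "n_minus_1", "K", "n"))
  # noiseless input: parameters recovered exactly
  for (seg in segs) {
    row <- tab[abs(tab$pH - seg$pH) < 1e-9 &
                 abs(tab$n - seg$n) < 1e-6, ]
    expect_identical(nrow(row), 1L)
    expect_equal(row$K, seg$K, tolerance = 1e-8)
  }
})

test_that("simulate runs are byte-reproducible from their resolved config", {
  d1 <- tmp("sim_rep1"); d2 <- tmp("sim_rep2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- list(scene = list(pattern = "stagnant_spot", seed = 33),
              times = c(0, 5, 13))
  run_simulate(c(cfg, list(out_dir = d1)))
  # re-run from the emitted resolved config
  rc <- jsonlite::read_json(file.path(d1, "resolved_config.json"),
                            simplifyVector = TRUE)
  rc$scene <- rc$scene[intersect(names(rc$scene),
                                 names(formals(scene_config)))]
  rc$out_dir <- d2
  run_simulate(rc)
  files <- setdiff(list.files(d1), "resolved_config.json")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
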