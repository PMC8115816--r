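escape_schedule <- rbind(c(0, pi), c(10, -2 * pi), c(14.5, pi))

escape_config <- function(seed = 1) {
  synthetic_config(duration_s = 30, dt = 0.05, amplitude = 5,
                   omega_schedule = escape_schedule,
                   turn_events = list(c(14.75, 0.15, 13)),
                   noise_sd = 0.05, seed = seed, name = "escape")
}

test_that("pose tables round trip losslessly and parse missing tokens", {
  out <- generate_series(synthetic_config(duration_s = 8, noise_sd = 0.3,
                                          gap_intervals = list(c(2, 2.3)),
                                          seed = 6, name = "rt"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_table(out$series, path)
  back <- read_pose_table(path, name = "rt")
  expect_equal(back$coeffs, out$series$coeffs, tolerance = 1e-12)
  expect_equal(back$times, out$series$times, tolerance = 1e-12)
  expect_equal(back$dt, out$series$dt, tolerance = 1e-9)
  # a single NaN cell yields one partially undefined sample
  tab <- data.frame(time = seq(0, 0.9, by = 0.1), a1 = 1:10, a2 = 2:11)
  tab$a2[4] <- "NaN"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, p2, row.names = FALSE, quote = FALSE)
  s2 <- read_pose_table(p2)
  expect_true(is.na(s2$coeffs[4, 2]) && !is.na(s2$coeffs[4, 1]))
})

test_that("malformed tables fail with distinct diagnostics", {
  tab <- data.frame(time = seq(0, 0.9, by = 0.1), a1 = rnorm(10), a2 = rnorm(10))
  shuffled <- tab[sample(10), ]
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(shuffled, p, row.names = FALSE)
  expect_error(read_pose_table(p), "not strictly increasing")
  irregular <- tab; irregular$time[5] <- irregular$time[5] + 0.03
  write.csv(irregular, p, row.names = FALSE)
  expect_error(read_pose_table(p), "irregular sampling")
  write.csv(data.frame(t = 1:5, a1 = 1:5, a2 = 1:5), p, row.names = FALSE)
  expect_error(read_pose_table(p), "time column")
  write.csv(data.frame(time = 1:5, a1 = 1:5), p, row.names = FALSE)
  expect_error(read_pose_table(p), "need >= 2")
})

test_that("change detection echoes its configuration and rejects overlap", {
  s <- cycle_series(duration_s = 130, dt = 1 / 16, noise_sd = 0.1)$series
  run <- run_change_detection(s, c(1, 1000), c(1001, 2000))
  expect_equal(run$summary$E, 5L)
  expect_equal(run$summary$theta, 2)
  expect_equal(run$summary$library_interval_samples, 1000L)
  expect_equal(run$summary$prediction_interval_samples, 1000L)
  expect_equal(run$summary$library_points, 995L)   # (E-1)*tau + Tp fewer
  expect_equal(run$summary$prediction_points, 995L)
  expect_error(run_change_detection(s, c(1, 1000), c(900, 1500)), "overlap")
})

test_that("an injected anomaly produces the global error peak at its window", {
  out <- cycle_series(duration_s = 100, dt = 1 / 16, noise_sd = 0, seed = 2,
                      anomaly_windows = list(list(window = c(72, 72.5625),
                                                  magnitude = 1)))
  s <- out$series
  run <- run_change_detection(s, c(1, 1000), c(1001, 1500))
  w <- range(which(out$truth$anomaly_mask))
  peak <- run$summary$peak_error_predicted_sample
  expect_gte(peak, w[1] - 5)
  expect_lte(peak, w[2] + 5)
  # mean error outside the anomaly neighbourhood is far below baseline
  err <- run$errors
  guard <- (w[1] - 6):(w[2] + 6)
  outside <- !(err$time_index + 1L) %in% guard
  expect_lt(mean(err$rms_whole[outside]),
            0.05 * err$constant_baseline_mean)
})

test_that("escape analysis takes 80% of pre-stimulus samples as library", {
  s <- generate_series(escape_config())$series
  run <- run_escape_analysis(s, stimulus_time = 10)
  expect_equal(run$summary$library_samples, 160L)  # 0.8 * 200 samples = 8 s
  expect_equal(run$summary$workflow, "escape_analysis")
  # error high during reversal/turn, low again during final forward phase
  tt <- s$times[run$errors$time_index]
  reversal <- tt >= 10 & tt <= 15
  final_fwd <- tt >= 20
  expect_gt(mean(run$errors$rms_whole[reversal]),
            mean(run$errors$rms_whole[final_fwd]))
  expect_error(run_escape_analysis(s, stimulus_time = 29.93,
                                   library_fraction = 1),
               "left to predict")
})

test_that("cross prediction is asymmetric and flags unshared behaviours", {
  lib_worm <- generate_series(synthetic_config(
    duration_s = 30, dt = 0.05, amplitude = 5, omega_schedule = pi,
    noise_sd = 0.05, seed = 3, name = "worm_fwd"))$series
  qry_worm <- generate_series(synthetic_config(
    duration_s = 30, dt = 0.05, amplitude = 5,
    omega_schedule = rbind(c(0, pi), c(10, -pi), c(20, pi)),
    noise_sd = 0.05, seed = 4, name = "worm_rev"))$series
  ab <- run_cross_prediction(lib_worm, qry_worm)
  tt <- qry_worm$times[ab$errors$time_index]
  rev_err <- mean(ab$errors$rms_whole[tt > 10.5 & tt < 19.5])
  fwd_err <- mean(ab$errors$rms_whole[tt < 9.5 | tt > 20.5])
  expect_gt(rev_err, 2 * fwd_err)  # reversal absent from the library
  ba <- run_cross_prediction(qry_worm, lib_worm)
  expect_false(isTRUE(all.equal(ab$errors$rms_whole, ba$errors$rms_whole)))
  # self-prediction with temporal exclusion stays at or below persistence
  cfg <- run_config(exclusion_steps = 2L)
  self <- run_cross_prediction(lib_worm, lib_worm, cfg)
  expect_lte(mean(self$errors$rms_whole), self$errors$constant_baseline_mean)
  # K mismatch is fatal, sampling-rate mismatch only warns
  k3 <- pose_series(lib_worm$coeffs[, 1:3], dt = lib_worm$dt)
  expect_error(run_cross_prediction(lib_worm, k3), "coefficients")
  slow <- pose_series(qry_worm$coeffs, dt = 1 / 16, name = "slow")
  expect_warning(run_cross_prediction(lib_worm, slow), "mismatch")
})

test_that("run outputs are byte-stable and self-consistent", {
  s <- generate_series(escape_config())$series
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run1 <- run_escape_analysis(s, 10, config = run_config(out_dir = d1))
  run_escape_analysis(s, 10, config = run_config(out_dir = d2))
  for (f in c("errors.csv", "classification.csv", "summary.txt", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  tab <- read.csv(file.path(d1, "errors.csv"))
  expect_equal(mean(tab$rms_whole), run1$summary$mean_rms_whole_rad,
               tolerance = 1e-9)
  expect_equal(mean(tab$constant_error),
               run1$summary$constant_baseline_mean_rad, tolerance = 1e-9)
  expect_equal(max(tab$rms_whole), run1$summary$peak_error_rad,
               tolerance = 1e-9)
  # error rows are timestamped at the lag-0 pose of each prediction
  expect_equal(tab$time, s$times[run1$errors$time_index], tolerance = 1e-9)
  cls <- read.csv(file.path(d1, "classification.csv"))
  expect_equal(nrow(cls), n_samples(s))
})

test_that("robustness workflow skips short series and writes grid tables", {
  worms <- list(make_henon_series(500, name = "long"),
                make_henon_series(40, name = "short"))
  d <- withr::local_tempdir()
  expect_message(
    grid <- run_robustness(worms, E_values = c(1, 3), theta_values = c(0, 2),
                           lib_points = 150, pred_points = 150,
                           config = run_config(out_dir = d)),
    "skipping worm 'short'")
  expect_equal(rownames(grid$e_scan), "long")
  etab <- read.csv(file.path(d, "robustness_E.csv"))
  expect_equal(etab$worm, c("long", "mean"))
  expect_equal(ncol(etab), 3L)
  expect_true(file.exists(file.path(d, "robustness_theta.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
})
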