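make_pred <- function(predicted, observed) {
  wormpred:::new_prediction_result(predicted, observed,
                                   seq_len(nrow(predicted)), 1L, "lib", "qry")
}

test_that("coefficient-to-angle conversion is the linear basis map", {
  b <- make_synthetic_basis(100, 5)
  expect_equal(eigen_to_angles(matrix(0, 3, 5), b), matrix(0, 3, 100))
  for (k in 1:5) {
    unit <- rep(0, 5); unit[k] <- 1
    expect_equal(drop(eigen_to_angles(unit, b)), unname(unclass(b)[, k]),
                 tolerance = 1e-12)
  }
  set.seed(1)
  c1 <- matrix(rnorm(10), 2, 5); c2 <- matrix(rnorm(10), 2, 5)
  expect_equal(eigen_to_angles(c1 + c2, b),
               eigen_to_angles(c1, b) + eigen_to_angles(c2, b),
               tolerance = 1e-12)
  expect_error(eigen_to_angles(matrix(0, 2, 4), b), "match")
})

test_that("orthonormal bases tie angle-space and coefficient-space RMS errors", {
  b <- make_synthetic_basis(100, 5)
  set.seed(2)
  pred <- make_pred(matrix(rnorm(250), 50, 5), matrix(rnorm(250), 50, 5))
  err <- rms_angle_error(pred, b)
  expect_equal(err$rms_whole, err$rms_coeff * sqrt(5 / 100), tolerance = 1e-10)
  expect_true(all(err$rms_whole >= 0))
  # identical prediction: zero everywhere
  same <- make_pred(pred$observed, pred$observed)
  expect_true(all(rms_angle_error(same, b)$rms_whole == 0))
  # hand-computed single sample: coefficient error (0.1, 0, 0, 0, 0)
  toy <- make_pred(matrix(c(0.1, 0, 0, 0, 0), 1), matrix(0, 1, 5))
  expect_equal(rms_angle_error(toy, b)$rms_whole, 0.1 / sqrt(100),
               tolerance = 1e-12)
})

test_that("region errors localise and decompose the whole-body error", {
  # block basis: coefficient k loads only angles of region k
  blocks <- matrix(0, 100, 5)
  for (k in 1:5) blocks[((k - 1) * 20 + 1):(k * 20), k] <- 1 / sqrt(20)
  b <- eigen_basis(blocks)
  head_err <- make_pred(matrix(c(0.5, 0, 0, 0, 0), 1), matrix(0, 1, 5))
  re <- region_errors(head_err, b)
  expect_gt(re[1, 1], 0)
  expect_equal(unname(re[2:5, 1]), rep(0, 4))
  # uniform angle error: constant column spread over the whole body
  bu <- eigen_basis(cbind(rep(0.1, 100), unclass(make_synthetic_basis(100, 1))))
  uni <- make_pred(matrix(c(0.3, 0), 1), matrix(0, 1, 2))
  reu <- region_errors(uni, bu)
  expect_equal(unname(reu[, 1]), rep(rms_angle_error(uni, bu)$rms_whole, 5),
               tolerance = 1e-12)
  # decomposition: mean of squared region errors = squared whole-body error
  set.seed(3)
  rnd <- make_pred(matrix(rnorm(100), 20, 5), matrix(rnorm(100), 20, 5))
  bsyn <- make_synthetic_basis()
  rr <- region_errors(rnd, bsyn)
  expect_equal(colMeans(rr^2), rms_angle_error(rnd, bsyn)$rms_whole^2,
               tolerance = 1e-10)
  expect_error(region_errors(rnd, bsyn, n_regions = 3), "divide")
})

test_that("an anomaly in a head-loaded coefficient localises to the head region", {
  blocks <- matrix(0, 100, 5)
  for (k in 1:5) blocks[((k - 1) * 20 + 1):(k * 20), k] <- 1 / sqrt(20)
  b <- eigen_basis(blocks)  # a1 loads angles 1-20 (head)
  out <- cycle_series(duration_s = 60, dt = 1 / 16, noise_sd = 0, seed = 1,
                      anomaly_windows = list(list(window = c(45, 45.5),
                                                  magnitude = 0.8)))
  s <- out$series
  lib <- embed_continuous(s, E = 5, interval = c(1, 600))
  qry <- embed_continuous(s, E = 5, interval = c(601, 950))
  pr <- smap_predict(lib, qry, smap_config(theta = 2))
  re <- region_errors(pr, b)
  peak <- which.max(rms_angle_error(pr, b)$rms_whole)
  expect_equal(unname(which.max(re[, peak])), 1L)
})

test_that("planar worm reconstruction preserves segment lengths and direction", {
  straight <- angles_to_xy(rep(0, 100))
  expect_equal(straight[101, ], c(x = 1, y = 0))
  expect_equal(straight[, "y"], rep(0, 101))
  up <- angles_to_xy(rep(pi / 2, 100), segment_length = 0.01)
  expect_equal(up[101, ], c(x = 0, y = 1), tolerance = 1e-12)
  set.seed(4)
  wiggly <- angles_to_xy(rnorm(100), segment_length = 0.01)
  seg <- sqrt(rowSums(diff(wiggly)^2))
  expect_equal(sum(seg), 1, tolerance = 1e-12)
})

test_that("robustness scan shapes, mean curve and determinism", {
  worms <- list(make_henon_series(400, name = "w1"),
                make_henon_series(400, a = 1.3, name = "w2"))
  grid <- robustness_scan(worms, E_values = c(1, 3, 5),
                          theta_values = c(0, 2), lib_points = 150,
                          pred_points = 150)
  expect_equal(dim(grid$e_scan), c(2L, 3L))
  expect_equal(dim(grid$theta_scan), c(2L, 2L))
  expect_equal(grid$e_scan_mean, colMeans(grid$e_scan))
  expect_equal(grid$theta_scan_mean, colMeans(grid$theta_scan))
  grid2 <- robustness_scan(worms, E_values = c(1, 3, 5),
                           theta_values = c(0, 2), lib_points = 150,
                           pred_points = 150)
  expect_identical(grid$e_scan, grid2$e_scan)
  expect_identical(grid$theta_scan, grid2$theta_scan)
})

test_that("delay embedding pays off on partially observed nonlinear dynamics", {
  worm <- make_lorenz_series(1200)
  grid <- robustness_scan(worm, E_values = c(1, 5), theta_values = 2,
                          lib_points = 500, pred_points = 500)
  expect_lt(grid$e_scan[1, "E5"], grid$e_scan[1, "E1"])
})

test_that("basis files round trip exactly", {
  b <- make_synthetic_basis(60, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eigen_basis(b, path)
  b2 <- read_eigen_basis(path)
  expect_equal(unclass(b2), unclass(b), tolerance = 1e-15)
  expect_error(eigen_basis(matrix(rnorm(100), 50, 2)), "orthonormal")
})
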