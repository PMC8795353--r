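test_that("calibration curves reproduce the printed dose values", {
  hd <- calibration_curve("HD-v2")
  eb <- calibration_curve("EBT-3")
  expect_equal(as.numeric(dose_from_netod(0.05, hd)),
               -0.388 + 434.913 * 0.05, tolerance = 1e-12)
  expect_equal(as.numeric(dose_from_netod(0, eb)), 0.012, tolerance = 1e-12)
  expect_equal(as.numeric(dose_from_netod(0.5, eb)),
               0.012 + 2.797 * 0.5 + 3.982 * 0.5^2.784, tolerance = 1e-12)
})

test_that("calibration curves are monotone non-decreasing on their valid range", {
  for (ft in c("HD-v2", "EBT-3")) {
    cv <- calibration_curve(ft)
    u <- seq(cv$valid_range[1], cv$valid_range[2], length.out = 2000)
    d <- dose_from_netod(u, cv, clamp = FALSE)
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("negative doses are clamped and counted; extrapolation is flagged", {
  hd <- calibration_curve("HD-v2")
  d <- dose_from_netod(c(0, 0.0001, 0.01), hd)
  expect_equal(attr(d, "n_clamped"), 2L)   # intercept -0.388 at tiny netOD
  expect_true(all(d >= 0))
  expect_warning(dd <- dose_from_netod(0.3, hd), "range")
  expect_equal(attr(dd, "n_extrapolated"), 1L)
})

test_that("calibration inversion is the exact inverse", {
  for (ft in c("HD-v2", "EBT-3")) {
    cv <- calibration_curve(ft)
    doses <- c(0.5, 2, 5, 10, 15, 20)
    if (ft == "EBT-3") doses <- doses[doses <= 15]
    u <- netod_from_dose(doses, cv)
    back <- suppressWarnings(dose_from_netod(u, cv, clamp = FALSE))
    expect_equal(as.numeric(back), doses, tolerance = 1e-6)
    expect_error(netod_from_dose(1e5, cv), "range")
  }
})

test_that("gray to OD: white level, decade transmission, wedge calibration", {
  g <- matrix(c(65535, 6553.5, 655.35), 1, 3)
  od <- gray_to_od(g, white_ref = 65535)
  expect_equal(as.numeric(od), c(0, 1, 2), tolerance = 1e-4)
  ## saturated pixels are masked and counted
  od2 <- gray_to_od(matrix(c(0, 100), 1, 2), white_ref = 65535)
  expect_equal(attr(od2, "n_saturated"), 1L)
  expect_true(is.na(od2[1]))
  ## synthetic step wedge: distorted scanner response recovered within 0.5%
  od_true <- seq(0.1, 1.4, by = 0.1)
  od_raw <- 0.93 * od_true^1.06          # monotone distortion
  wedge <- data.frame(od_raw = od_raw, od_true = od_true)
  test_od <- c(0.25, 0.6, 1.1)
  gray <- matrix(65535 * 10^(-(0.93 * test_od^1.06)), 1)
  rec <- gray_to_od(gray, white_ref = 65535, wedge = wedge)
  expect_true(all(abs(as.numeric(rec) / test_od - 1) < 0.005))
})

test_that("netOD subtraction clamps negatives and keeps identities", {
  od <- matrix(c(0.2, 0.5, 0.05), 1, 3)
  expect_equal(as.numeric(net_od(od, 0)), as.numeric(od))
  z <- net_od(od, 0.1)
  expect_equal(as.numeric(z), c(0.1, 0.4, 0))
  expect_equal(attr(z, "n_clamped"), 1L)
  expect_true(all(net_od(matrix(0.3, 2, 2), 0.3) == 0))
})

test_that("LET quenching and cell-position corrections compose linearly", {
  expect_equal(apply_let_correction(0.7, 0.7), 1.0)
  m <- matrix(runif(16, 1, 5), 4, 4)
  expect_equal(apply_let_correction(m, 1), m)
  expect_equal(mean(apply_let_correction(m, 0.7)), mean(m) / 0.7)
  expect_error(apply_let_correction(1, 0))
  expect_equal(apply_cell_factor(m, 1), m)
  expect_equal(apply_cell_factor(10), 9)
  expect_equal(apply_cell_factor(apply_let_correction(m, 0.7), 0.9),
               0.9 * m / 0.7)
})
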