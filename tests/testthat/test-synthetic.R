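test_that("dose-map generator: exact uniform limit and determinism", {
  dm <- make_dose_map(5, lateral_variation_pct = 0, shadow_area_mm2 = 0,
                      noise_sd_gy = 0, size_px = 128, seed = 1)
  s <- dose_statistics(dm)
  expect_equal(s$mean_gy, 5)
  expect_equal(s$lateral_variation_pct, 0)
  a <- make_dose_map(8.5, seed = 2)
  b <- make_dose_map(8.5, seed = 2)
  expect_identical(a$values, b$values)
  expect_error(make_dose_map(5, shadow_area_mm2 = 100, seed = 1), "shadow")
})

test_that("dose statistics recover the generator's targets", {
  dm <- make_dose_map(8.5, lateral_variation_pct = 27, shadow_area_mm2 = 12,
                      noise_sd_gy = 0.1, size_px = 256, seed = 3)
  s <- dose_statistics(dm)
  expect_equal(s$mean_gy, 8.5, tolerance = 0.02)
  expect_equal(s$lateral_variation_pct, 27, tolerance = 0.06)
})

test_that("film-scan generator: OD0 baseline and noiseless inversion", {
  curve <- calibration_curve("HD-v2")
  zero <- make_dose_map(1e-9, lateral_variation_pct = 0, shadow_area_mm2 = 0,
                        noise_sd_gy = 0, size_px = 32, seed = 4)
  sc <- dose_map_to_film_scan(zero, curve, od0 = 0.05, noise_sd = 0, seed = 5)
  ## zero dose maps to the netOD of D = 0 on the HD-v2 curve (+OD0)
  u0 <- netod_from_dose(0, curve)
  expect_equal(mean(sc$gray), 65535 * 10^-(u0 + 0.05), tolerance = 1e-4)
  ## noiseless round trip through the full dosimetry chain
  dm <- make_dose_map(20, lateral_variation_pct = 10, shadow_area_mm2 = 0,
                      noise_sd_gy = 0, size_px = 64, seed = 6)
  sc2 <- dose_map_to_film_scan(dm, curve, od0 = 0.05, noise_sd = 0, seed = 7)
  fd <- film_dosimetry(sc2, curve, eta = 1, cell_factor = 1,
                       shadow_area_mm2 = 0, bin = 1)
  expect_equal(fd$stats$mean_gy, dose_statistics(dm, bin = 1)$mean_gy,
               tolerance = 5e-3)
  ## doses beyond the invertible range are refused
  big <- make_dose_map(150, lateral_variation_pct = 0, shadow_area_mm2 = 0,
                       noise_sd_gy = 0, size_px = 32, seed = 8)
  expect_error(dose_map_to_film_scan(big, curve, seed = 9), "range")
})

test_that("plate generator: blanks, truth bookkeeping, overlap failure", {
  blank <- make_plate_image(0, size_px = 128, seed = 10)
  expect_equal(attr(blank, "truth")$n_colonies, 0)
  img <- make_plate_image(30, size_px = 256, margin_px = 14, seed = 11)
  trth <- attr(img, "truth")
  expect_equal(nrow(trth$colonies), 30)
  expect_true(all(inside_ellipse(trth$well, trth$colonies$x, trth$colonies$y)))
  i2 <- make_plate_image(30, size_px = 256, margin_px = 14, seed = 11)
  expect_identical(as.numeric(img), as.numeric(i2))
  expect_error(make_plate_image(400, size_px = 128, max_tries = 20, seed = 12),
               "without overlap")
})

test_that("survival dataset generator follows the model and is seeded", {
  p <- list(c = 0.917, a = 0.456, b = 0.056)
  doses <- c(0.5, 1, 2.1, 5.3, 8.3, 10.5)
  recs <- make_survival_dataset(p, doses, modality = "x-ray",
                                cell_line = "PC3", seeded = 2e5,
                                dose_error_rel = 0, seed = 13)
  out <- survival_records_sf(recs)
  g <- group_and_average(out, exclude_above_gy = Inf)
  model <- p$c * exp(-p$a * g$dose_gy - p$b * g$dose_gy^2)
  ## near-noiseless limit (large seeded count): SF matches the model
  expect_equal(g$mean_sf, model, tolerance = 0.02)
  ## survival decreases monotonically with dose
  expect_true(all(diff(g$mean_sf[order(g$dose_gy)]) < 0))
  r2 <- make_survival_dataset(p, doses, modality = "x-ray", cell_line = "PC3",
                              seeded = 2e5, dose_error_rel = 0, seed = 13)
  expect_identical(recs$colonies, r2$colonies)
})
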