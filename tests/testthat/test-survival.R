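test_that("plating efficiency and surviving fraction basics", {
  expect_equal(plating_efficiency(50, 100), 0.5)
  expect_equal(plating_efficiency(0, 100), 0)
  expect_error(plating_efficiency(5, 0))
  expect_warning(pe <- plating_efficiency(120, 100), "more colonies")
  expect_gt(pe, 1)
  expect_equal(surviving_fraction(0.35, 0.35), 1)
  expect_equal(surviving_fraction(0, 0.35), 0)
  expect_error(surviving_fraction(0.5, 0))
  ## scale invariance: doubling colonies and seeded leaves SF unchanged
  expect_equal(surviving_fraction(plating_efficiency(40, 200), 0.5),
               surviving_fraction(plating_efficiency(80, 400), 0.5))
})

test_that("sham normalisation is per experiment", {
  rec <- data.frame(
    cell_line = "A",
    modality = c("sham", "sham", "x-ray", "x-ray"),
    dose_gy = c(0, 0, 2, 2),
    colonies = c(50, 80, 25, 40),
    seeded = 100,
    experiment = c(1, 2, 1, 2))
  out <- survival_records_sf(rec)
  expect_equal(out$sf[3], 0.25 / 0.5)
  expect_equal(out$sf[4], 0.40 / 0.8)
  ## same SF in both experiments despite different sham efficiency
  expect_equal(out$sf[3], out$sf[4])
  expect_error(survival_records_sf(rec[rec$modality != "sham", ]), "sham")
})

test_that("background subtraction: identities, clamping, idempotence", {
  rec <- data.frame(
    cell_line = "A", modality = "proton",
    dose_gy = c(8, 8, 35, 35),
    colonies = 1, seeded = 100, experiment = 1,
    sf = c(0.02, 0.30, 0.02, 0.02))
  out <- subtract_background(rec)
  expect_equal(attr(out, "background")[["A"]], 0.02)
  expect_equal(out$sf_corr, c(0, 0.28, 0, 0))      # SF = background -> 0
  ## zero background is the identity
  rec0 <- rec; rec0$sf[3:4] <- 0
  expect_equal(subtract_background(rec0)$sf_corr[2], rec0$sf[2])
  ## idempotence: re-estimating from corrected data subtracts ~nothing
  out2 <- out; out2$sf <- out$sf_corr
  expect_equal(subtract_background(out2)$sf_corr, out$sf_corr)
  expect_error(subtract_background(rec[rec$dose_gy < 30, ]), "lethal")
})

test_that("background recovery matches the injected shadow fraction", {
  recs <- make_survival_dataset(list(c = 0.998, a = 0.452, b = 0.028),
                                doses = c(8.5, 15.8, 21.0, 37.1),
                                modality = "proton", seeded = 5000,
                                background_fraction = 0.02, seed = 12)
  recs <- survival_records_sf(recs)
  out <- subtract_background(recs)
  bg <- attr(out, "background")[["RWPE1"]]
  expect_lt(abs(bg - 0.02), 0.005)
  ## within the printed 1.5-2.7% shadow band
  expect_gt(bg, 0.015); expect_lt(bg, 0.027)
})

test_that("two-stage averaging matches a hand-computed oracle", {
  rec <- data.frame(
    cell_line = "A", modality = "x-ray",
    dose_gy = 2,
    colonies = c(10, 20, 30, 40, 50, 60), seeded = 100,
    experiment = c(1, 1, 1, 2, 2, 2),
    sf = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  g <- group_and_average(rec)
  ## experiment means 0.2 and 0.5, cross-experiment mean 0.35, sd .212
  expect_equal(g$mean_sf, 0.35)
  expect_equal(g$sd_sf, stats::sd(c(0.2, 0.5)))
  expect_equal(g$n_experiments, 2)
  ## single experiment: SD reported missing
  g1 <- group_and_average(rec[rec$experiment == 1, ])
  expect_true(is.na(g1$sd_sf))
  ## identical replicates: SD zero
  rec2 <- rec; rec2$sf <- 0.3
  expect_equal(group_and_average(rec2)$sd_sf, 0)
  ## lethal groups are excluded from the reported curve
  rec3 <- rbind(rec, within(rec[1, ], dose_gy <- 35))
  expect_false(35 %in% group_and_average(rec3)$dose_gy)
})

test_that("ODR fit: exact recovery in the noiseless limit", {
  d <- c(0.5, 1, 2, 5, 8, 10.5)
  y <- 1 * exp(-0.5 * d - 0.05 * d^2)
  ft <- fit_survival_odr(d, rep(1e-6, 6), y, rep(1e-6, 6))
  expect_equal(unname(ft$coefficients), c(1, 0.5, 0.05), tolerance = 1e-6)
  expect_true(all(ft$se >= 0))
  expect_error(fit_survival_odr(d[1:3], rep(1, 3), y[1:3], rep(1, 3)))
})

test_that("ODR reduces to weighted nonlinear least squares as dose errors vanish", {
  set.seed(5)
  d <- c(0.5, 1, 2.1, 5.3, 8.3, 10.5)
  y <- 0.998 * exp(-0.452 * d - 0.028 * d^2) * (1 + rnorm(6, 0, 0.05))
  sy <- 0.05 * pmax(y, 1e-4)
  ft <- fit_survival_odr(d, rep(1e-9, 6), y, sy)
  nls_fit <- minpack.lm::nlsLM(y ~ cc * exp(-a * d - b * d^2),
                               start = list(cc = 1, a = 0.4, b = 0.03),
                               weights = 1 / sy^2)
  expect_equal(unname(ft$coefficients), unname(coef(nls_fit)), tolerance = 1e-4)
})

test_that("ODR agrees with an independent profiled-objective minimiser", {
  set.seed(6)
  d <- c(0.5, 1, 2.1, 5.3, 8.3, 10.5)
  f <- 0.998 * exp(-0.452 * d - 0.028 * d^2)
  y <- f + rnorm(6, 0, 0.08 * f)
  x <- d + rnorm(6, 0, 0.25)
  sx <- rep(0.25, 6); sy <- 0.08 * f
  ft <- fit_survival_odr(x, sx, y, sy)
  orc <- odr_oracle(x, sx, y, sy, start = unname(ft$coefficients) * 1.15)
  expect_equal(unname(ft$coefficients), unname(orc$par), tolerance = 1e-3)
})

test_that("fitted survival curve is non-increasing for non-negative a, b", {
  d <- c(0.5, 1, 2, 5, 8, 10.5)
  y <- 0.95 * exp(-0.4 * d - 0.03 * d^2)
  ft <- fit_survival_odr(d, rep(0.1, 6), y, 0.02 * y)
  pred <- predict(ft, seq(0, 12, by = 0.1))
  expect_true(all(diff(pred) <= 1e-12))
})

test_that("parameter recovery is unbiased with calibrated coverage", {
  doses <- c(0.5, 1, 2.1, 5.3, 8.3, 10.5)
  sx <- c(0.3, 0.3, 0.3, 0.4, 0.4, 0.6)
  p <- list(c = 0.998, a = 0.452, b = 0.028)
  st <- odr_recovery_study(p, doses, sx, target = 0.060, which = "a",
                           n_rep = 200, seed = 42)
  ## bias below 10% of the printed uncertainty of each parameter
  expect_lt(abs(st$mean[["c"]] - 0.998), 0.1 * 0.029 + 3 * st$sd[["c"]] / sqrt(200))
  expect_lt(abs(st$mean[["a"]] - 0.452), 0.1 * 0.060 + 3 * st$sd[["a"]] / sqrt(200))
  expect_lt(abs(st$mean[["b"]] - 0.028), 0.1 * 0.008 + 3 * st$sd[["b"]] / sqrt(200))
  ## 1-SE interval coverage near the nominal 68%
  q <- st$q
  set.seed(77)
  cov <- 0; nr <- 150
  for (i in seq_len(nr)) {
    dd <- simulate_survival_points(p, doses, sx, 0.15, q)
    ft <- tryCatch(fit_survival_odr(dd$x, dd$sx, dd$y, dd$sy),
                   error = function(e) NULL)
    if (!is.null(ft)) cov <- cov + (abs(ft$coefficients[["a"]] - 0.452) <= ft$se[2])
  }
  expect_gt(cov / nr, 0.55)
  expect_lt(cov / nr, 0.80)
})
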