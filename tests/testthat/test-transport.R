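test_that("time of flight follows relativistic kinematics", {
  expect_equal(time_of_flight(2.4, 1.766), 82.518, tolerance = 1e-4)
  ## linear in path
  expect_equal(time_of_flight(3, 2 * 1.766), 2 * time_of_flight(3, 1.766))
  ## strictly decreasing in energy
  e <- seq(0.2, 9, by = 0.2)
  expect_true(all(diff(time_of_flight(e, 1.766)) < 0))
  expect_error(time_of_flight(0, 1))
})

test_that("bunch duration: mono-energetic and two-point closed forms", {
  mono <- fake_oncell(rep(2.4, 100))
  expect_warning(d <- bunch_duration(mono, 1.766, tt), "mono-energetic")
  expect_equal(d, 0)
  two <- fake_oncell(c(rep(3, 50), rep(6, 50)))
  expect_equal(bunch_duration(two, 1.766, tt),
               time_of_flight(3, 1.766) - time_of_flight(6, 1.766),
               tolerance = 1e-10)
})

test_that("a widened spectrum has a longer bunch than a narrowed one", {
  set.seed(2)
  wide <- fake_oncell(runif(4000, 3, 7))
  narrow <- fake_oncell(runif(4000, 4, 5))
  expect_gt(bunch_duration(wide, 1.766, tt), bunch_duration(narrow, 1.766, tt))
})

test_that("on-cell spectrum: determinism, zero stack, all-stopped error", {
  sp <- proton_spectrum()
  oc1 <- on_cell_spectrum(sp, tables = tt, n = 2e4, seed = 5)
  oc2 <- on_cell_spectrum(sp, tables = tt, n = 2e4, seed = 5)
  expect_identical(oc1$E_cell, oc2$E_cell)
  ## zero-thickness stack: sample mean equals the doubly truncated
  ## exponential mean (the propagation floor drops E < 0.05 MeV)
  a <- 0.05 / sp$E0; z <- sp$Emax / sp$E0
  mu <- sp$E0 * ((1 + a) * exp(-a) - (1 + z) * exp(-z)) / (exp(-a) - exp(-z))
  oc0 <- on_cell_spectrum(sp, stack = absorber_stack(material_layer("air", 0)),
                          tables = tt, n = 5e4, seed = 6)
  expect_lt(abs(oc0$mean_energy - mu), 3 * stats::sd(oc0$E_cell) / sqrt(oc0$n_on_cell))
  ## energies insufficient to cross a thick stack
  thick <- absorber_stack(material_layer("water", 5000))
  expect_error(on_cell_spectrum(proton_spectrum(Emax = 2), stack = thick,
                                tables = tt, n = 1000, seed = 1), "stopped")
})

test_that("transport conserves particle number exactly", {
  mp <- transport_fluence_map(beamline_geometry(), proton_spectrum(),
                              focus_strength = 3000, n = 2e4, seed = 9,
                              tables = tt)
  expect_identical(mp$n_emitted,
                   mp$n_aperture_rejected + mp$n_outside_extent + mp$n_binned)
  expect_error(transport_fluence_map(beamline_geometry(), proton_spectrum(),
                                     focus_strength = -1, n = 2e4, tables = tt))
})

test_that("zero focusing gives the ballistic divergence cone", {
  geom <- beamline_geometry(dipole_field_mt = 0)
  mp <- transport_fluence_map(geom, proton_spectrum(), focus_strength = 0,
                              n = 5e4, seed = 10, tables = tt, bin_mm = 1)
  ## uniform cone of 11 mrad half-angle: flat disc of radius ~19.4 mm
  expect_equal(spot_fwhm(mp), 2 * 0.011 * 1.766 * 1000, tolerance = 0.05)
})

test_that("increasing focusing strength shrinks the beam before the focal point", {
  med_r <- vapply(c(1600, 2000, 2400, 2800), function(k) {
    mp <- transport_fluence_map(beamline_geometry(), proton_spectrum(),
                                focus_strength = k, n = 3e4, seed = 33,
                                tables = tt)
    pp <- mp$particles
    stats::median(sqrt(pp$x_mm^2 + pp$y_mm^2)[pp$in_aperture & pp$survives])
  }, 0)
  expect_true(all(diff(med_r) < 0))
})

test_that("cell-to-film factor: identity stack and mono-energetic oracle", {
  oc <- fake_oncell(rep(4, 10), rep(4, 10))
  zero <- absorber_stack(material_layer("air", 0))
  same <- material_layer("water", 5)
  expect_equal(cell_to_film_dose_factor(oc, zero, tt, cell_layer = same,
                                        film_layer = same), 1)
  ## 5 MeV beam, thin-layer scoring: hand-computed two-point ratio
  oc5 <- fake_oncell(rep(5, 10), rep(5, 10))
  st <- intermediate_stack()
  e_film <- propagate_stack(5, st, tt)
  expected <- stopping_power(tt, "water", 5) / stopping_power(tt, "film", e_film)
  got <- cell_to_film_dose_factor(oc5, st, tt, scoring = "fluence_s")
  expect_equal(got, expected, tolerance = 1e-10)
  ## deposition scoring approaches the thin-layer limit
  got_dep <- cell_to_film_dose_factor(oc5, st, tt)
  expect_equal(got_dep, expected, tolerance = 0.05)
  ## everything stopped before the film is an error
  slow <- fake_oncell(rep(0.5, 10), rep(0.5, 10))
  expect_error(cell_to_film_dose_factor(slow, st, tt), "stopped")
})

test_that("geometry constructor validates fields", {
  expect_error(beamline_geometry(nonsense = 1), "unknown")
  g <- beamline_geometry(flight_path_mm = 1731)
  expect_equal(g$flight_path_mm, 1731)
})
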