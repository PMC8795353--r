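## Simplified beamline transport: chromatic thin lens standing in for the
## active plasma lens, small-angle dipole dispersion, Monte-Carlo ray
## tracing to the sample plane, time-of-flight kinematics.

.C_M_PER_NS <- 0.299792458

.pmom <- function(E) sqrt(E^2 + 2 * .PROTON_MASS_MEV * E)  # MeV/c

#' Beamline geometry parameters
#'
#' Defaults follow the printed layout of the laser-driven beamline this
#' package models: 100 um FWHM source, 260 mrad FWHM divergence limited to
#' an 11 mrad acceptance half-angle, a 33 mm plasma lens starting 13 mm
#' from the source (thin-lens plane at its centre, 29.5 mm), a 1 mm lens
#' channel, a 264 mT x 138 mm dipole, a 10 mm diameter irradiation cup at
#' 1766 mm, and 0.2 Hz repetition rate. The dipole position along the line
#' is not printed; the default (centre at 1200 mm) places it between the
#' lens and the current transformer / exit window.
#'
#' @param ... override any field by name.
#' @return object of class `beamline_geometry`.
#' @export
beamline_geometry <- function(...) {
  g <- list(
    source_fwhm_um       = 100,
    divergence_fwhm_mrad = 260,
    acceptance_mrad      = 11,
    lens_z_mm            = 29.5,
    lens_channel_mm      = 1,
    dipole_field_mt      = 264,
    dipole_length_mm     = 138,
    dipole_z_mm          = 1200,
    flight_path_mm       = 1766,
    cup_diameter_mm      = 10,
    rep_rate_hz          = 0.2
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(g))
  if (length(unknown)) stop("beamline_geometry: unknown fields: ",
                            paste(unknown, collapse = ", "))
  g[names(ov)] <- ov
  stopifnot(g$acceptance_mrad <= g$divergence_fwhm_mrad,
            all(unlist(g[c("source_fwhm_um", "flight_path_mm",
                           "lens_z_mm", "cup_diameter_mm")]) > 0))
  structure(g, class = "beamline_geometry")
}

## Monte-Carlo ray trace to the sample plane. Angles are sampled uniformly
## over the acceptance cone (the 260 mrad FWHM divergence is flat to <1%
## over the 11 mrad acceptance). Returns per-particle energy, transverse
## position at the sample plane (m) and an in-channel-aperture flag.
.trace_rays <- function(geometry, spectrum, focus_strength, n) {
  stopifnot(focus_strength >= 0)
  E <- sample_spectrum(spectrum, n)
  p <- .pmom(E)
  s_sigma <- geometry$source_fwhm_um * 1e-6 / 2.3548
  x0 <- stats::rnorm(n, 0, s_sigma); y0 <- stats::rnorm(n, 0, s_sigma)
  phi <- stats::runif(n, 0, 2 * pi)
  th  <- geometry$acceptance_mrad * 1e-3 * sqrt(stats::runif(n))
  tx <- th * cos(phi); ty <- th * sin(phi)
  z1 <- geometry$lens_z_mm * 1e-3
  L  <- geometry$flight_path_mm * 1e-3
  zd <- geometry$dipole_z_mm * 1e-3
  x1 <- x0 + tx * z1; y1 <- y0 + ty * z1
  in_aperture <- sqrt(x1^2 + y1^2) < geometry$lens_channel_mm * 1e-3 / 2
  ## chromatic thin lens, f prop p; zero strength = ballistic (f = Inf)
  f <- if (focus_strength > 0) p / focus_strength else Inf
  tx2 <- tx - x1 / f; ty2 <- ty - y1 / f
  ## small-angle dipole kick, downward, applied at the dipole centre
  alpha <- 0.2998 * (geometry$dipole_field_mt * 1e-3) *
    (geometry$dipole_length_mm * 1e-3) / (p / 1000)
  xs <- x1 + tx2 * (L - z1)
  ys <- y1 + ty2 * (L - z1) - alpha * (L - zd)
  list(E = E, xs = xs, ys = ys, in_aperture = in_aperture)
}

#' Monte-Carlo fluence map at the sample plane
#'
#' Traces `n` protons through the chromatic thin-lens + dipole model and
#' bins the transverse positions at the sample plane. The map is centred
#' on the fluence centroid of protons that survive the exit-window +
#' air entrance stack (the dose-carrying beam the cup is aligned on).
#' Particle number is conserved exactly:
#' `n == n_aperture_rejected + n_outside_extent + sum(counts)`.
#'
#' @param geometry a [beamline_geometry()].
#' @param spectrum a [proton_spectrum()].
#' @param focus_strength lens strength kappa, defined by 1/f = kappa/p with
#'   p in MeV/c (kappa in MeV/c per metre). Must be > 0.
#' @param n number of protons (>= 1e4).
#' @param seed integer seed.
#' @param tables [stopping_tables()] (built on demand when `NULL`).
#' @param bin_mm bin size of the map.
#' @param extent_mm half-width of the binned region around the beam centre.
#' @return object of class `fluence_map`: `counts` matrix, bin `edges_mm`
#'   (centred coordinates), bookkeeping counts, the centroid used, and the
#'   per-particle sample-plane data.
#' @export
transport_fluence_map <- function(geometry, spectrum, focus_strength, n,
                                  seed = NULL, tables = NULL,
                                  bin_mm = 1, extent_mm = 60) {
  if (n < 1e4) stop("transport_fluence_map: need n >= 1e4")
  if (focus_strength < 0) stop("transport_fluence_map: focus_strength must be >= 0")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tables)) tables <- stopping_tables()
  tr <- .trace_rays(geometry, spectrum, focus_strength, n)
  Ec <- propagate_stack(tr$E, entrance_stack(), tables)
  surv <- !is.na(Ec) & tr$in_aperture
  if (!any(surv)) stop("transport_fluence_map: no protons survive to the sample plane")
  cx <- mean(tr$xs[surv]); cy <- mean(tr$ys[surv])
  x <- (tr$xs - cx) * 1e3; y <- (tr$ys - cy) * 1e3  # mm, beam-centred
  edges <- seq(-extent_mm, extent_mm, by = bin_mm)
  ok <- tr$in_aperture
  inext <- ok & x >= -extent_mm & x < extent_mm & y >= -extent_mm & y < extent_mm
  ix <- findInterval(x[inext], edges, rightmost.closed = TRUE)
  iy <- findInterval(y[inext], edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  counts <- matrix(tabulate((iy - 1L) * nb + ix, nbins = nb * nb), nb, nb)
  structure(list(
    counts = counts, edges_mm = edges,
    n_emitted = n,
    n_aperture_rejected = sum(!ok),
    n_outside_extent = sum(ok & !inext),
    n_binned = sum(inext),
    centroid_m = c(cx, cy),
    particles = list(E = tr$E, E_cell = Ec, x_mm = x, y_mm = y,
                     in_aperture = tr$in_aperture, survives = !is.na(Ec))
  ), class = "fluence_map")
}

#' Relative dose standard deviation over the central field
#'
#' Bins the dose (fluence weighted by the water stopping power at the
#' on-sample energy) on `bin_mm` pixels and reports SD/mean over bins whose
#' centres lie inside the central circle, after subtracting the expected
#' Monte-Carlo sampling variance so the statistic reflects the beam profile
#' rather than finite sampling.
#'
#' @param map a `fluence_map`.
#' @param tables [stopping_tables()].
#' @param diameter_mm evaluation circle diameter (default the 10 mm cup).
#' @param bin_mm dose-pixel size.
#' @return list: `rel_sd`, `mean_dose_weight`, `n_protons`.
#' @export
fluence_uniformity <- function(map, tables, diameter_mm = 10, bin_mm = 1) {
  stopifnot(inherits(map, "fluence_map"))
  pp <- map$particles
  r <- sqrt(pp$x_mm^2 + pp$y_mm^2)
  sel <- pp$in_aperture & pp$survives & r < diameter_mm / 2
  if (sum(sel) < 100) stop("fluence_uniformity: too few protons in the field")
  w <- stopping_power(tables, "water", pmin(pp$E_cell[sel], 10))
  half <- diameter_mm / 2
  edges <- seq(-half, half, by = bin_mm)
  nb <- length(edges) - 1L
  ix <- findInterval(pp$x_mm[sel], edges, rightmost.closed = TRUE)
  iy <- findInterval(pp$y_mm[sel], edges, rightmost.closed = TRUE)
  idx <- (iy - 1L) * nb + ix
  dose <- numeric(nb * nb); cnt <- numeric(nb * nb)
  for (k in seq_along(idx)) { dose[idx[k]] <- dose[idx[k]] + w[k]; cnt[idx[k]] <- cnt[idx[k]] + 1 }
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  cc <- expand.grid(x = ctr, y = ctr)
  keep <- sqrt(cc$x^2 + cc$y^2) <= half - bin_mm / 2
  v <- dose[keep]
  mc_var <- mean(cnt[keep]) * mean(w^2)  # Poisson-compound sampling variance
  rel_sd <- sqrt(max(stats::var(v) - mc_var, 0)) / mean(v)
  list(rel_sd = rel_sd, mean_dose_weight = mean(v), n_protons = sum(sel))
}

#' Azimuthally averaged fluence-spot FWHM
#'
#' @param map a `fluence_map`.
#' @param dr_mm radial bin width.
#' @return FWHM of the radial fluence density, mm.
#' @export
spot_fwhm <- function(map, dr_mm = 0.5) {
  stopifnot(inherits(map, "fluence_map"))
  pp <- map$particles
  r <- sqrt(pp$x_mm^2 + pp$y_mm^2)
  r <- r[pp$in_aperture & pp$survives]
  br <- seq(0, max(40, max(r)), by = dr_mm)
  h <- graphics::hist(r[r < max(br)], breaks = br, plot = FALSE)
  dens <- h$counts / (2 * pi * pmax(h$mids, dr_mm / 2) * dr_mm)
  2 * h$mids[max(which(dens >= max(dens) / 2))]
}

#' Tune the lens strength for a uniform cup-filling spot
#'
#' Scans candidate focusing strengths; among those whose fluence-spot FWHM
#' lies within [1, 1.4] x cup diameter (the spot covers the cup without
#' wasteful dilution) the strength with the smallest central-field dose SD
#' is selected. Falls back to the FWHM closest to the cup diameter if no
#' candidate lands in the window.
#'
#' @inheritParams transport_fluence_map
#' @param strengths candidate kappa values to scan.
#' @param n protons per scan point.
#' @return list: `strength`, `scan` (data.frame of strength, fwhm_mm, rel_sd).
#' @export
tune_focusing <- function(geometry, spectrum, tables,
                          strengths = seq(1600, 4000, by = 300),
                          n = 2e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scan <- lapply(strengths, function(k) {
    m <- transport_fluence_map(geometry, spectrum, k, n, tables = tables)
    u <- fluence_uniformity(m, tables, diameter_mm = geometry$cup_diameter_mm)
    data.frame(strength = k, fwhm_mm = spot_fwhm(m), rel_sd = u$rel_sd)
  })
  scan <- do.call(rbind, scan)
  cup <- geometry$cup_diameter_mm
  ok <- scan$fwhm_mm >= cup & scan$fwhm_mm <= 1.4 * cup
  best <- if (any(ok)) {
    scan$strength[ok][which.min(scan$rel_sd[ok])]
  } else {
    scan$strength[which.min(abs(scan$fwhm_mm - cup))]
  }
  list(strength = best, scan = scan)
}

#' On-sample proton spectrum after the entrance stack
#'
#' Samples source energies from the spectrum, optionally applies the
#' transport acceptance (chromatic lens + dipole dispersion + cup
#' aperture), propagates through the entrance stack and discards stopped
#' protons.
#'
#' @param spectrum a [proton_spectrum()].
#' @param stack entrance [absorber_stack()] (default 25 um kapton + 97 mm air).
#' @param tables [stopping_tables()].
#' @param n number of source protons sampled (>= 1000).
#' @param seed integer seed.
#' @param geometry optional [beamline_geometry()]; when supplied, only
#'   protons traced into the cup are kept.
#' @param focus_strength lens strength; required with `geometry`.
#' @return object of class `on_cell_spectrum`: `E_source`, `E_cell` (MeV),
#'   `mean_energy`, counts, and the generating configuration.
#' @export
on_cell_spectrum <- function(spectrum, stack = entrance_stack(), tables,
                             n = 1e5, seed = NULL,
                             geometry = NULL, focus_strength = NULL) {
  if (n < 1000) stop("on_cell_spectrum: need n >= 1000")
  if (!is.null(seed)) set.seed(seed)
  n_out_cup <- 0L
  if (is.null(geometry)) {
    E <- sample_spectrum(spectrum, n)
  } else {
    if (is.null(focus_strength)) stop("on_cell_spectrum: focus_strength required with geometry")
    tr <- .trace_rays(geometry, spectrum, focus_strength, n)
    Ec0 <- propagate_stack(tr$E, stack, tables)
    surv <- !is.na(Ec0) & tr$in_aperture
    if (!any(surv)) stop("on_cell_spectrum: all protons stopped in the entrance stack")
    cx <- mean(tr$xs[surv]); cy <- mean(tr$ys[surv])
    r <- sqrt((tr$xs - cx)^2 + (tr$ys - cy)^2)
    incup <- tr$in_aperture & r < geometry$cup_diameter_mm * 1e-3 / 2
    n_out_cup <- sum(!incup)
    E <- tr$E[incup]
  }
  Ec <- propagate_stack(E, stack, tables)
  alive <- !is.na(Ec)
  if (!any(alive)) stop("on_cell_spectrum: all protons stopped in the entrance stack")
  structure(list(
    E_source = E[alive], E_cell = Ec[alive],
    mean_energy = mean(Ec[alive]),
    n_sampled = n, n_out_cup = n_out_cup,
    n_stopped = sum(!alive), n_on_cell = sum(alive),
    stack = stack, spectrum = spectrum
  ), class = "on_cell_spectrum")
}

#' @export
print.on_cell_spectrum <- function(x, ...) {
  cat(sprintf("On-sample spectrum: %d protons, mean energy %.2f MeV (%d stopped, %d outside cup)\n",
              x$n_on_cell, x$mean_energy, x$n_stopped, x$n_out_cup))
  invisible(x)
}

#' Cell-to-film dose ratio through the intermediate absorber stack
#'
#' Scores the dose (energy deposited per unit mass) of the on-sample
#' protons in a thin cell layer, transports them through the intermediate
#' stack (cell layer, air gap, mylar exit window, air gap), scores the dose
#' in the film active layer, and returns cell dose / film dose. Protons
#' stopping inside a scoring layer deposit their full remaining energy;
#' protons stopping en route contribute nothing to the film. With
#' `scoring = "fluence_s"` the thin-layer limit (fluence times mass
#' stopping power at the layer entrance) is used instead.
#'
#' @param oncell an [on_cell_spectrum()].
#' @param stack intermediate [absorber_stack()] between cell and film;
#'   its first layer should be the cell layer itself.
#' @param tables [stopping_tables()].
#' @param cell_layer,film_layer scoring [material_layer()]s.
#' @param scoring "deposition" (default) or "fluence_s".
#' @return the dimensionless dose ratio (cell / film).
#' @export
cell_to_film_dose_factor <- function(oncell, stack = intermediate_stack(),
                                     tables,
                                     cell_layer = material_layer("water", 5),
                                     film_layer = material_layer("film", 10),
                                     scoring = c("deposition", "fluence_s")) {
  stopifnot(inherits(oncell, "on_cell_spectrum"))
  scoring <- match.arg(scoring)
  E <- oncell$E_cell
  if (!length(E)) stop("cell_to_film_dose_factor: empty on-cell spectrum")
  Ef <- if (length(stack$layers)) propagate_stack(E, stack, tables) else E
  ok <- !is.na(Ef)
  if (!any(ok)) stop("cell_to_film_dose_factor: all protons stopped before the film")
  if (scoring == "fluence_s") {
    d_cell <- mean(stopping_power(tables, cell_layer$material, pmin(E, 10)))
    d_film <- sum(stopping_power(tables, film_layer$material, pmin(Ef[ok], 10))) / length(E)
    return(d_cell / d_film)
  }
  dep_in <- function(Ein, layer) {
    Eout <- propagate_stack(Ein, absorber_stack(list(layer)), tables)
    sum(ifelse(is.na(Eout), Ein, Ein - Eout))
  }
  d_cell <- dep_in(E, cell_layer) / cell_layer$areal_g_cm2 / length(E)
  d_film <- dep_in(Ef[ok], film_layer) / film_layer$areal_g_cm2 / length(E)
  d_cell / d_film
}

#' Relativistic proton time of flight
#'
#' @param E kinetic energy in MeV (> 0), vectorised.
#' @param path_m flight path in metres (> 0).
#' @return time in nanoseconds; strictly decreasing in `E`, linear in path.
#' @export
time_of_flight <- function(E, path_m) {
  if (any(E <= 0) || any(path_m <= 0)) stop("time_of_flight: E and path must be > 0")
  g <- 1 + E / .PROTON_MASS_MEV
  beta <- sqrt(1 - 1 / g^2)
  path_m / (beta * .C_M_PER_NS)
}

## Per-particle arrival times at the sample: vacuum flight at the source
## energy over the path upstream of the entrance stack, plus the exact
## slowing-down transit through each stack layer, computed from the
## per-material time-integral splines (t = [T(E_in) - T(E_out)] / rho).
arrival_times <- function(oncell, path_m, tables) {
  d_deg <- sum(vapply(oncell$stack$layers, function(l) l$thickness_um, 0)) * 1e-6
  t <- time_of_flight(oncell$E_source, path_m - d_deg)
  E <- pmin(oncell$E_source, 10)
  for (layer in oncell$stack$layers) {
    rg <- tables$ranges[[layer$material]]
    Eout <- rg$E_of_R(pmax(rg$R_of_E(E) - layer$areal_g_cm2, 0))
    t <- t + (rg$T_of_E(E) - rg$T_of_E(Eout)) / layer$density
    E <- Eout
  }
  t
}

## Weighted quantile (inverse of the right-continuous weighted step CDF).
.wquantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; cw <- cumsum(w[o]) / sum(w)
  vapply(p, function(pi) x[which(cw >= pi)[1]], 0)
}

#' Dose-weighted on-sample bunch duration
#'
#' Arrival-time spread of the on-sample bunch, each proton weighted by its
#' stopping power in the cell layer (dose weighting). The default measure
#' is the 0.1-99.9% dose-weighted arrival span, the bunch length that
#' enters the instantaneous dose rate; `measure = "fwhm"` gives the
#' histogram FWHM of the same distribution.
#'
#' @param oncell an [on_cell_spectrum()].
#' @param path_m source-to-sample flight path in metres (default 1.766).
#' @param tables [stopping_tables()].
#' @param measure "span" (default) or "fwhm".
#' @param trim tail dose fraction excluded on each side for the span.
#' @return duration in ns (0, with a warning, for a mono-energetic bunch).
#' @export
bunch_duration <- function(oncell, path_m = 1.766, tables,
                           measure = c("span", "fwhm"), trim = 0.001) {
  stopifnot(inherits(oncell, "on_cell_spectrum"))
  measure <- match.arg(measure)
  t <- arrival_times(oncell, path_m, tables)
  w <- stopping_power(tables, "water", pmin(oncell$E_cell, 10))
  if (diff(range(t)) < 1e-9) {
    warning("bunch_duration: mono-energetic bunch, duration 0")
    return(0)
  }
  if (measure == "span") {
    q <- .wquantile(t, w, c(trim, 1 - trim))
    return(q[2] - q[1])
  }
  h <- graphics::hist(t, breaks = seq(min(t), max(t) + 1, by = 1), plot = FALSE)
  wsum <- vapply(seq_along(h$mids), function(i) {
    sum(w[t >= h$breaks[i] & t < h$breaks[i + 1]])
  }, 0)
  above <- which(wsum >= max(wsum) / 2)
  h$mids[max(above)] - h$mids[min(above)] + 1
}
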