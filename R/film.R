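## Radiochromic-film dosimetry: gray value -> optical density -> netOD ->
## dose, with LET quenching and cell-position corrections.

#' Film calibration curve
#'
#' The two film models supported are calibrated against a 300 kV X-ray
#' reference for doses of 5-15 Gy. HD-v2 uses a linear dose-netOD relation
#' D = a + b*netOD (a = -0.388 Gy, b = 434.913 Gy); EBT-3 uses
#' D = a + b*netOD + c*netOD^d (a = 0.012, b = 2.797, c = 3.982,
#' d = 2.784). Both are monotone non-decreasing over their valid netOD
#' ranges.
#'
#' @param film_type "HD-v2" or "EBT-3", or "custom" with explicit params.
#' @param params named list (a, b and optionally c, d) for custom curves.
#' @param valid_range netOD range over which the curve is considered
#'   calibrated; values outside trigger an extrapolation flag.
#' @export
calibration_curve <- function(film_type = c("HD-v2", "EBT-3", "custom"),
                              params = NULL, valid_range = NULL) {
  film_type <- match.arg(film_type)
  if (film_type == "HD-v2") {
    params <- list(a = -0.388, b = 434.913)
    form <- "linear"
    if (is.null(valid_range)) valid_range <- c(0, 0.25)  # high-dose film
  } else if (film_type == "EBT-3") {
    params <- list(a = 0.012, b = 2.797, c = 3.982, d = 2.784)
    form <- "linear_plus_power"
    if (is.null(valid_range)) valid_range <- c(0, 1.5)
  } else {
    stopifnot(!is.null(params), all(c("a", "b") %in% names(params)))
    form <- if (all(c("c", "d") %in% names(params))) "linear_plus_power" else "linear"
    if (is.null(valid_range)) valid_range <- c(0, 1)
  }
  structure(list(film_type = film_type, form = form, params = params,
                 valid_range = valid_range),
            class = "calibration_curve")
}

.curve_eval <- function(curve, netod) {
  p <- curve$params
  d <- p$a + p$b * netod
  if (curve$form == "linear_plus_power") d <- d + p$c * pmax(netod, 0)^p$d
  d
}

#' Dose from netOD
#'
#' Evaluates the calibration curve; negative computed doses (possible for
#' HD-v2 at very small netOD because of its negative intercept) are clamped
#' to zero and counted. netOD outside the calibrated range triggers a
#' warning and an `extrapolated` attribute.
#'
#' @param netod numeric vector/matrix of net optical densities.
#' @param curve a [calibration_curve()].
#' @param clamp clamp negative doses at 0 (default TRUE).
#' @return doses in Gy, with attributes `n_clamped` and `n_extrapolated`.
#' @export
dose_from_netod <- function(netod, curve, clamp = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  out_of_range <- netod < curve$valid_range[1] | netod > curve$valid_range[2]
  if (any(out_of_range)) {
    warning(sprintf("dose_from_netod: %d value(s) outside the calibrated netOD range; extrapolating",
                    sum(out_of_range)))
  }
  d <- .curve_eval(curve, netod)
  n_clamped <- 0L
  if (clamp) {
    n_clamped <- sum(d < 0)
    d[d < 0] <- 0
  }
  attr(d, "n_clamped") <- n_clamped
  attr(d, "n_extrapolated") <- sum(out_of_range)
  d
}

#' Invert a calibration curve (dose -> netOD)
#'
#' Monotone root finding on the calibration curve; used by the synthetic
#' film generator. Errors if any dose lies outside the invertible range.
#'
#' @param dose doses in Gy.
#' @param curve a [calibration_curve()].
#' @return netOD values with `dose_from_netod(netod, curve)` reproducing
#'   `dose` to numerical precision.
#' @export
netod_from_dose <- function(dose, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  lo <- curve$valid_range[1]; hi <- curve$valid_range[2]
  dmin <- .curve_eval(curve, lo); dmax <- .curve_eval(curve, hi)
  bad <- dose < min(0, dmin) | dose > dmax
  if (any(bad)) {
    stop(sprintf("netod_from_dose: %d dose value(s) outside the invertible range [%.3g, %.3g] Gy (first offender: %.3g)",
                 sum(bad), min(0, dmin), dmax, dose[which(bad)[1]]))
  }
  shape <- dim(dose)
  grid <- seq(lo, hi, length.out = 4096)
  dg <- .curve_eval(curve, grid)
  out <- stats::approx(dg, grid, xout = pmax(dose, dmin), ties = "ordered")$y
  ## polish with one round of root finding where the curve is nonlinear
  if (curve$form == "linear_plus_power") {
    out <- vapply(seq_along(out), function(i) {
      stats::uniroot(function(u) .curve_eval(curve, u) - pmax(dose[i], dmin),
                     lower = lo, upper = hi, tol = 1e-12)$root
    }, 0)
  }
  if (!is.null(shape)) dim(out) <- shape
  out
}

#' 16-bit film scan container
#'
#' @param gray matrix of 16-bit gray values (0-65535).
#' @param dpi scan resolution.
#' @param film_type "HD-v2" or "EBT-3".
#' @param od0 optical density of the unirradiated reference.
#' @export
film_scan <- function(gray, dpi, film_type = c("HD-v2", "EBT-3"), od0 = 0) {
  film_type <- match.arg(film_type)
  stopifnot(is.matrix(gray), all(gray >= 0), all(gray <= 65535), dpi > 0, od0 >= 0)
  structure(list(gray = gray, dpi = dpi, film_type = film_type, od0 = od0,
                 pixel_mm = 25.4 / dpi),
            class = "film_scan")
}

#' Gray values to optical density
#'
#' OD = -log10(gray / white reference), optionally corrected by a monotone
#' step-wedge calibration. Saturated (zero) pixels are masked (NA) and
#' counted. The white reference defaults to the maximum representable
#' value; in practice, pass the median of an unexposed border region.
#'
#' @param scan a [film_scan()] (or bare gray matrix).
#' @param white_ref white-level gray value.
#' @param wedge optional data.frame with columns `od_raw`, `od_true` from a
#'   calibrated step wedge; a monotone spline through these points corrects
#'   the raw OD. Identity when NULL.
#' @return OD matrix (attribute `n_saturated` counts masked pixels).
#' @export
gray_to_od <- function(scan, white_ref = 65535, wedge = NULL) {
  gray <- if (inherits(scan, "film_scan")) scan$gray else scan
  stopifnot(white_ref > 0)
  sat <- gray <= 0
  g <- gray
  g[sat] <- NA_real_
  od <- -log10(g / white_ref)
  od[od < 0] <- 0
  if (!is.null(wedge)) {
    stopifnot(all(c("od_raw", "od_true") %in% names(wedge)))
    o <- order(wedge$od_raw)
    fn <- stats::splinefun(wedge$od_raw[o], wedge$od_true[o], method = "hyman")
    od <- fn(od)
    od[od < 0] <- 0
  }
  attr(od, "n_saturated") <- sum(sat)
  od
}

#' netOD = OD - OD0, clamped at zero
#'
#' @param od OD map.
#' @param od0 reference (unirradiated) OD, >= 0.
#' @return netOD map; attribute `n_clamped` counts negative values set to 0.
#' @export
net_od <- function(od, od0) {
  stopifnot(od0 >= 0)
  x <- od - od0
  n <- sum(x < 0, na.rm = TRUE)
  x[x < 0] <- 0
  attr(x, "n_clamped") <- n
  x
}

#' LET quenching correction: D_real = D / eta
#'
#' Radiochromic film under-responds at high linear energy transfer near the
#' Bragg peak; the measured dose is divided by the weighted quenching
#' factor eta (default 0.7 for the proton spectrum this package models).
#'
#' @param dose dose map in Gy.
#' @param eta quenching factor, 0 < eta <= 1.
#' @export
apply_let_correction <- function(dose, eta = 0.7) {
  if (eta <= 0 || eta > 1) stop("apply_let_correction: need 0 < eta <= 1")
  dose / eta
}

#' Cell-position correction: on-cell dose = film dose x factor
#'
#' Accounts for the absorbers between the cell layer and the film; the
#' printed correction factor for this beamline is 0.9.
#'
#' @param dose film-measured dose in Gy.
#' @param factor multiplicative correction (> 0).
#' @export
apply_cell_factor <- function(dose, factor = 0.9) {
  if (factor <= 0) stop("apply_cell_factor: factor must be > 0")
  dose * factor
}
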