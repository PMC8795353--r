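## Dose maps, the crescent-shadow geometry, dose statistics and dose-rate
## arithmetic.

#' 2D dose map with ROI and shadow masks
#'
#' @param values dose matrix in Gy.
#' @param pixel_mm pixel size.
#' @param roi_diameter_mm diameter of the circular irradiation field
#'   (default the 10 mm cell cup).
#' @param center_px ROI centre in (row, col) pixels; defaults to the image
#'   centre.
#' @param shadow logical matrix marking the un-irradiated crescent (or NULL).
#' @export
dose_map <- function(values, pixel_mm, roi_diameter_mm = 10,
                     center_px = NULL, shadow = NULL) {
  stopifnot(is.matrix(values), pixel_mm > 0, roi_diameter_mm > 0)
  if (is.null(center_px)) center_px <- (dim(values) + 1) / 2
  nr <- nrow(values); nc <- ncol(values)
  rr <- matrix(seq_len(nr), nr, nc) - center_px[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center_px[2]
  roi <- (rr^2 + cc^2) * pixel_mm^2 <= (roi_diameter_mm / 2)^2
  if (is.null(shadow)) shadow <- matrix(FALSE, nr, nc)
  stopifnot(identical(dim(shadow), dim(values)))
  structure(list(values = values, pixel_mm = pixel_mm,
                 roi_diameter_mm = roi_diameter_mm, center_px = center_px,
                 roi = roi, shadow = shadow & roi),
            class = "dose_map")
}

#' Area of a circular segment cut by a horizontal chord
#'
#' Chord at signed distance `d` from the centre (positive toward the
#' segment side); the segment is the region between the chord and the
#' nearer arc. `d = r` gives 0 (tangent), `d = 0` the half disc, `d = -r`
#' the full disc.
#'
#' @param r circle radius.
#' @param d signed chord distance from the centre, in [-r, r].
#' @return segment area in the same squared units.
#' @export
circular_segment_area <- function(r, d) {
  stopifnot(r > 0, all(abs(d) <= r))
  r^2 * acos(d / r) - d * sqrt(r^2 - d^2)
}

#' Solve the chord offset giving a requested segment area
#'
#' Calibration helper for the crescent shadow: finds the chord distance
#' whose circular segment matches `target_area` (e.g. the printed 12 mm^2
#' shadow at the film plane of a 10 mm field).
#'
#' @param r circle radius (mm).
#' @param target_area requested segment area (mm^2), within (0, pi r^2).
#' @return signed chord distance from the centre, mm.
#' @export
solve_chord_offset <- function(r, target_area) {
  stopifnot(target_area >= 0, target_area <= pi * r^2)
  if (target_area == 0) return(r)
  stats::uniroot(function(d) circular_segment_area(r, d) - target_area,
                 lower = -r, upper = r, tol = 1e-12)$root
}

#' Crescent shadow mask from chord geometry
#'
#' The upper edge of the cup holder casts a shadow over the top of the
#' circular field: the mask is the circular segment above a horizontal
#' chord at distance `chord_offset_mm` from the ROI centre. An offset at or
#' beyond the circle edge yields an empty mask with a warning.
#'
#' @param dim_px image dimensions (rows, cols).
#' @param pixel_mm pixel size.
#' @param center_px ROI centre (row, col).
#' @param roi_diameter_mm field diameter.
#' @param chord_offset_mm signed chord distance from the centre (positive
#'   = chord above centre, smaller crescent).
#' @return logical matrix; attribute `area_mm2` holds the analytic segment
#'   area.
#' @export
shadow_mask <- function(dim_px, pixel_mm, center_px, roi_diameter_mm = 10,
                        chord_offset_mm) {
  r <- roi_diameter_mm / 2
  if (chord_offset_mm >= r) {
    warning("shadow_mask: chord does not intersect the field; empty mask")
    m <- matrix(FALSE, dim_px[1], dim_px[2])
    attr(m, "area_mm2") <- 0
    return(m)
  }
  stopifnot(chord_offset_mm >= -r)
  nr <- dim_px[1]; nc <- dim_px[2]
  rr <- (matrix(seq_len(nr), nr, nc) - center_px[1]) * pixel_mm
  cc <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - center_px[2]) * pixel_mm
  inroi <- rr^2 + cc^2 <= r^2
  ## image row coordinates increase downward; the shadow is the top segment
  m <- inroi & (-rr >= chord_offset_mm)
  attr(m, "area_mm2") <- circular_segment_area(r, chord_offset_mm)
  m
}

## block-mean binning, truncating incomplete edge blocks
.bin_matrix <- function(x, k) {
  if (k <= 1) return(x)
  nr <- (nrow(x) %/% k) * k; nc <- (ncol(x) %/% k) * k
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  xr <- rowsum(x, rep(seq_len(nr %/% k), each = k))
  t(rowsum(t(xr), rep(seq_len(nc %/% k), each = k))) / k^2
}

#' Dose statistics over the irradiated field
#'
#' Bins the map (default 4x4 pixels) to suppress scanner noise, then
#' reports the mean dose and lateral variation (SD/mean, %) over the ROI
#' excluding the shadow crescent, plus a dose histogram.
#'
#' @param dm a [dose_map()].
#' @param bin binning factor.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return list: `mean_gy`, `lateral_variation_pct`, `n_pixels`, `histogram`.
#' @export
dose_statistics <- function(dm, bin = 4, breaks = 50) {
  stopifnot(inherits(dm, "dose_map"))
  v <- .bin_matrix(dm$values, bin)
  roi <- .bin_matrix((dm$roi & !dm$shadow) * 1, bin) > 0.5
  x <- v[roi]
  x <- x[!is.na(x)]
  if (!length(x)) stop("dose_statistics: empty effective ROI")
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(mean_gy = mean(x),
       lateral_variation_pct = 100 * stats::sd(x) / mean(x),
       n_pixels = length(x),
       histogram = h)
}

#' Dose-per-shot and dose rates
#'
#' Pulsed mode (`n_shots` given): dose/shot = mean dose / shots,
#' instantaneous dose rate IDR = dose per shot / bunch duration, mean dose
#' rate MDR = dose per shot x repetition rate. Continuous-wave mode
#' (`total_s` given, `n_shots` NULL): IDR = MDR = mean dose / total time.
#'
#' @param mean_dose_gy mean dose over the field, Gy.
#' @param n_shots number of pulses (NULL for continuous delivery).
#' @param rep_rate_hz pulse repetition rate.
#' @param bunch_ns bunch duration in nanoseconds (default 33 ns, the value
#'   consistent with the printed per-shot IDR arithmetic; the time-of-flight
#'   estimate from [bunch_duration()] may be passed instead).
#' @param total_s total delivery time for continuous-wave mode.
#' @return list: `dose_per_shot_gy`, `idr_gy_s`, `mdr_gy_s`, `total_s`.
#' @export
dose_rates <- function(mean_dose_gy, n_shots = NULL, rep_rate_hz = 0.2,
                       bunch_ns = 33, total_s = NULL) {
  if (is.null(n_shots)) {
    if (is.null(total_s) || total_s <= 0) stop("dose_rates: continuous mode needs total_s > 0")
    rate <- mean_dose_gy / total_s
    return(list(dose_per_shot_gy = NA_real_, idr_gy_s = rate,
                mdr_gy_s = rate, total_s = total_s))
  }
  stopifnot(n_shots >= 1, rep_rate_hz > 0, bunch_ns > 0)
  dps <- mean_dose_gy / n_shots
  list(dose_per_shot_gy = dps,
       idr_gy_s = dps / (bunch_ns * 1e-9),
       mdr_gy_s = dps * rep_rate_hz,
       total_s = n_shots / rep_rate_hz)
}

#' Printed dose-group summary table
#'
#' The per-group dosimetry table of the modelled irradiation campaign
#' (radiation type, cell line, mean dose, shots, durations, per-shot dose
#' and rates), shipped as packaged data and used as tabulated input by the
#' dose-rate bookkeeping.
#'
#' @return data.frame, one row per dose group.
#' @export
dose_group_table <- function() {
  f <- system.file("extdata", "dose_groups.csv", package = "protonflash",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Recompute per-shot dose and rates for every dose group
#'
#' Applies [dose_rates()] to each row of the dose-group table: pulsed
#' arithmetic for the proton groups, continuous-wave for the X-ray groups.
#'
#' @param groups data.frame in [dose_group_table()] layout.
#' @param bunch_ns bunch duration used for proton IDR.
#' @return the table with recomputed `dose_per_shot_gy`, `idr_gy_s`,
#'   `mdr_gy_s` columns.
#' @export
dose_group_rates <- function(groups = dose_group_table(), bunch_ns = 33) {
  out <- groups
  out$dose_per_shot_gy <- NA_real_
  out$idr_gy_s <- NA_real_
  out$mdr_gy_s <- NA_real_
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    if (g$radiation == "x-ray") {
      r <- dose_rates(g$mean_dose_gy, total_s = g$total_duration_s)
    } else {
      r <- dose_rates(g$mean_dose_gy, n_shots = g$n_shots,
                      rep_rate_hz = g$rep_rate_hz, bunch_ns = bunch_ns)
    }
    out$dose_per_shot_gy[i] <- r$dose_per_shot_gy
    out$idr_gy_s[i] <- r$idr_gy_s
    out$mdr_gy_s[i] <- r$mdr_gy_s
  }
  out
}
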