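## Synthetic-data generators: every input the analysis chain consumes can
## be produced with known ground truth, deterministically under a fixed
## (config, seed) pair.

#' Synthetic quasi-uniform dose map with crescent shadow
#'
#' A smooth low-order field (sum of 2D Legendre modes with seeded random
#' coefficients) is scaled to the requested mean and lateral variation
#' inside the 10 mm field, the crescent shadow is zeroed, and Gaussian
#' noise is added.
#'
#' @param mean_gy target mean dose over ROI minus shadow (> 0).
#' @param lateral_variation_pct target SD/mean in percent (before noise).
#' @param shadow_area_mm2 crescent area; 0 for no shadow.
#' @param noise_sd_gy additive Gaussian noise SD.
#' @param pixel_mm pixel size; `size_px` image side.
#' @param roi_diameter_mm field diameter.
#' @param seed integer seed (required).
#' @return a [dose_map()] with attribute `truth` (generator parameters and
#'   the exact pre-noise mean/SD).
#' @export
make_dose_map <- function(mean_gy, lateral_variation_pct = 18,
                          shadow_area_mm2 = 12, noise_sd_gy = 0.2,
                          pixel_mm = 0.1, size_px = 256,
                          roi_diameter_mm = 10, seed) {
  stopifnot(mean_gy > 0, lateral_variation_pct >= 0, noise_sd_gy >= 0)
  r <- roi_diameter_mm / 2
  if (shadow_area_mm2 >= pi * r^2) stop("make_dose_map: shadow larger than ROI")
  set.seed(seed)
  ctr <- c(size_px, size_px) / 2 + 0.5
  u <- ((seq_len(size_px) - ctr[1]) * pixel_mm) / r   # normalised [-1,1] on ROI
  U <- matrix(u, size_px, size_px); V <- t(U)
  ## clamp coordinates radially to the unit disc so the low-order field
  ## stays within its in-ROI range outside the irradiated spot
  rr <- sqrt(U^2 + V^2)
  sc <- ifelse(rr > 1, 1 / rr, 1)
  U <- U * sc; V <- V * sc
  modes <- list(U, V, (3 * U^2 - 1) / 2, (3 * V^2 - 1) / 2, U * V)
  coef <- stats::rnorm(3)
  pick <- sample.int(length(modes), 3)
  m <- Reduce(`+`, Map(function(co, mo) co * mo, coef, modes[pick]))
  shadow <- if (shadow_area_mm2 > 0) {
    off <- solve_chord_offset(r, shadow_area_mm2)
    shadow_mask(c(size_px, size_px), pixel_mm, ctr, roi_diameter_mm, off)
  } else matrix(FALSE, size_px, size_px)
  dm0 <- dose_map(m, pixel_mm, roi_diameter_mm, ctr, shadow)
  sel <- dm0$roi & !dm0$shadow
  s <- lateral_variation_pct / 100
  g <- if (s > 0 && stats::sd(m[sel]) > 0) {
    1 + s * (m - mean(m[sel])) / stats::sd(m[sel])
  } else matrix(1, size_px, size_px)
  vals <- mean_gy * g
  vals[vals < 0] <- 0
  vals[shadow] <- 0
  true_mean <- mean(vals[sel]); true_sd <- stats::sd(vals[sel])
  if (noise_sd_gy > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, noise_sd_gy)
    vals[vals < 0] <- 0
  }
  out <- dose_map(vals, pixel_mm, roi_diameter_mm, ctr, shadow)
  attr(out, "truth") <- list(mean_gy = mean_gy,
                             lateral_variation_pct = lateral_variation_pct,
                             pre_noise_mean_gy = true_mean,
                             pre_noise_sd_gy = true_sd,
                             shadow_area_mm2 = shadow_area_mm2,
                             noise_sd_gy = noise_sd_gy, seed = seed)
  out
}

#' Render a dose map as a synthetic 16-bit film scan
#'
#' Inverts the calibration curve (monotone root find) to netOD, adds the
#' unirradiated reference OD, converts to 16-bit gray through the scanner
#' model gray = 65535 * 10^(-OD), and adds Gaussian read noise.
#'
#' @param dm a [dose_map()] (doses must lie in the curve's invertible range).
#' @param curve a [calibration_curve()].
#' @param od0 reference OD of the unirradiated film.
#' @param noise_sd read noise SD in gray counts (default 150).
#' @param seed integer seed.
#' @return a [film_scan()] with attribute `truth`.
#' @export
dose_map_to_film_scan <- function(dm, curve, od0 = 0.05, noise_sd = 150, seed) {
  stopifnot(inherits(dm, "dose_map"), inherits(curve, "calibration_curve"))
  set.seed(seed)
  netod <- netod_from_dose(dm$values, curve)
  od <- netod + od0
  gray <- 65535 * 10^(-od)
  if (noise_sd > 0) gray <- gray + stats::rnorm(length(gray), 0, noise_sd)
  gray <- round(pmin(pmax(gray, 0), 65535))
  dim(gray) <- dim(dm$values)
  out <- film_scan(gray, dpi = 25.4 / dm$pixel_mm, film_type =
                     if (curve$film_type %in% c("HD-v2", "EBT-3")) curve$film_type else "HD-v2",
                   od0 = od0)
  attr(out, "truth") <- list(od0 = od0, noise_sd = noise_sd, seed = seed,
                             curve = curve$film_type)
  out
}

#' Synthetic colony-plate photograph with ground truth
#'
#' Bright elliptical well on a dark background with a mild linear gradient;
#' colonies are dark Gaussian-profile elliptical spots placed without
#' overlap by rejection sampling (bounded retries). The Gaussian radial
#' profile guarantees a positive-definite Hessian at each colony centre at
#' the detection scale.
#'
#' @param n_colonies number of colonies (>= 0).
#' @param size_px image side.
#' @param well a [well_ellipse()]; default a slightly elliptical,
#'   slightly rotated well filling most of the frame.
#' @param r_range colony Gaussian radius range, pixels.
#' @param contrast_range colony depth range (intensity units).
#' @param bg_level,well_level background / well intensities.
#' @param gradient amplitude of the linear background gradient.
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param margin_px minimum colony-centre distance from the well boundary.
#' @param max_tries rejection-sampling attempts per colony.
#' @param seed integer seed (required).
#' @return numeric matrix in [0, 1] with attribute `truth` (well, per-colony
#'   centres/radii/contrasts, seed).
#' @export
make_plate_image <- function(n_colonies, size_px = 512, well = NULL,
                             r_range = c(2, 3.2), contrast_range = c(0.35, 0.6),
                             bg_level = 0.15, well_level = 0.85,
                             gradient = 0.03, noise_sd = 0.01,
                             margin_px = 20, max_tries = 1000, seed) {
  stopifnot(n_colonies >= 0)
  set.seed(seed)
  if (is.null(well)) {
    well <- well_ellipse(size_px / 2, size_px / 2,
                         major = 0.45 * size_px, minor = 0.42 * size_px,
                         angle = stats::runif(1, 0, pi))
  }
  xg <- matrix(seq_len(size_px), size_px, size_px)
  yg <- t(xg)
  img <- bg_level + gradient * ((xg + yg) / (2 * size_px) - 0.5)
  wellmask <- inside_ellipse(well, xg, yg)
  img[wellmask] <- img[wellmask] + (well_level - bg_level)
  img <- .filter_reflect(img, outer(.gauss_kernels(1.5)$g0, .gauss_kernels(1.5)$g0))
  placed <- data.frame(x = numeric(), y = numeric(), r = numeric(),
                       ry = numeric(), angle = numeric(), contrast = numeric())
  if (n_colonies > 0) {
    for (i in seq_len(n_colonies)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        px <- stats::runif(1, 1, size_px); py <- stats::runif(1, 1, size_px)
        if (!inside_ellipse(well, px, py, margin_px)) next
        rr <- stats::runif(1, r_range[1], r_range[2])
        if (nrow(placed)) {
          d <- sqrt((placed$x - px)^2 + (placed$y - py)^2)
          if (any(d < 2.2 * (placed$r + rr) + 3)) next
        }
        ok <- TRUE; break
      }
      if (!ok) stop("make_plate_image: could not place colony ", i,
                    " without overlap; use fewer or smaller colonies")
      placed[i, ] <- list(px, py, rr, rr * stats::runif(1, 0.8, 1),
                          stats::runif(1, 0, pi),
                          stats::runif(1, contrast_range[1], contrast_range[2]))
    }
    for (i in seq_len(nrow(placed))) {
      p <- placed[i, ]
      w <- ceiling(4 * p$r)
      xs <- max(1, round(p$x) - w):min(size_px, round(p$x) + w)
      ys <- max(1, round(p$y) - w):min(size_px, round(p$y) + w)
      dx <- outer(xs - p$x, rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - p$y)
      ca <- cos(p$angle); sa <- sin(p$angle)
      xr <- dx * ca + dy * sa; yr <- -dx * sa + dy * ca
      img[xs, ys] <- img[xs, ys] -
        p$contrast * exp(-0.5 * ((xr / p$r)^2 + (yr / p$ry)^2))
    }
  }
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(size_px, size_px)
  attr(img, "truth") <- list(well = well, colonies = placed,
                             n_colonies = n_colonies, seed = seed)
  img
}

#' Synthetic clonogenic-survival plate records
#'
#' Per-plate colony counts are binomial draws: irradiated cells survive
#' with probability SF(dose) from the linear-quadratic model, while the
#' shadow subpopulation (fraction `background_fraction`) is unirradiated
#' and plates like sham cells, so
#' colonies ~ Binomial(seeded, pe_sham * ((1 - bg) SF + bg)).
#' Sham plates are generated per experiment. Measured doses are jittered
#' per the lateral/sample variation error model.
#'
#' @param params named list/vector (c, a, b) of the true survival model.
#' @param doses nominal dose groups (Gy).
#' @param modality "proton" or "x-ray" (background only for protons).
#' @param cell_line label.
#' @param seeded cells seeded per plate.
#' @param pe_sham sham plating efficiency.
#' @param replicates plates per dose group and experiment.
#' @param experiments number of independent experiments.
#' @param background_fraction unirradiated (shadow) fraction in [0, 0.1].
#' @param dose_error_rel relative SD of the measured dose.
#' @param seed integer seed (required).
#' @return data.frame of plate records (see [survival_records_sf()]) with
#'   attribute `truth`.
#' @export
make_survival_dataset <- function(params, doses, modality = c("proton", "x-ray"),
                                  cell_line = "RWPE1", seeded = 500,
                                  pe_sham = 0.7, replicates = 3,
                                  experiments = 2,
                                  background_fraction = 0.02,
                                  dose_error_rel = 0.1, seed) {
  modality <- match.arg(modality)
  stopifnot(background_fraction >= 0, background_fraction <= 0.1,
            pe_sham > 0, pe_sham <= 1)
  set.seed(seed)
  bg <- if (modality == "proton") background_fraction else 0
  cc <- params[["c"]]; a <- params[["a"]]; b <- params[["b"]]
  rows <- list()
  for (e in seq_len(experiments)) {
    for (rep_i in seq_len(replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        cell_line = cell_line, modality = "sham", dose_group = 0,
        dose_gy = 0, colonies = stats::rbinom(1, seeded, pe_sham),
        seeded = seeded, experiment = e)
    }
    for (d in doses) {
      sf_true <- min(.lq_model(d, cc, a, b), 1)
      p <- pe_sham * ((1 - bg) * sf_true + bg)
      dmeas <- d * (1 + stats::rnorm(1, 0, dose_error_rel))
      for (rep_i in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          cell_line = cell_line, modality = modality, dose_group = d,
          dose_gy = dmeas, colonies = stats::rbinom(1, seeded, p),
          seeded = seeded, experiment = e)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(params = c(c = cc, a = a, b = b),
                             doses = doses, modality = modality,
                             pe_sham = pe_sham, seeded = seeded,
                             background_fraction = bg, seed = seed)
  out
}
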