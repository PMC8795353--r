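## Clonogenic survival: plating efficiency, sham normalisation, lethal-dose
## background subtraction, two-stage group averaging, and orthogonal
## distance regression of the linear-quadratic survival model
## y = c * exp(-a x - b x^2).

#' Plating efficiency
#'
#' @param colonies colony counts (>= 0).
#' @param seeded cells seeded (> 0).
#' @return colonies / seeded. Values > 1 (miscounts) are returned as-is
#'   with a warning and a `miscount` attribute.
#' @export
plating_efficiency <- function(colonies, seeded) {
  if (any(seeded <= 0)) stop("plating_efficiency: seeded must be > 0")
  if (any(colonies < 0)) stop("plating_efficiency: colonies must be >= 0")
  pe <- colonies / seeded
  if (any(pe > 1)) {
    warning("plating_efficiency: more colonies than cells seeded")
    attr(pe, "miscount") <- pe > 1
  }
  pe
}

#' Surviving fraction relative to the sham mean
#'
#' Normalisation is per experiment: each experiment's plating efficiencies
#' are divided by that experiment's mean sham plating efficiency.
#'
#' @param pe plating efficiencies.
#' @param pe_sham_mean mean sham plating efficiency (> 0), scalar or one
#'   value per element of `pe`.
#' @export
surviving_fraction <- function(pe, pe_sham_mean) {
  if (any(pe_sham_mean <= 0)) stop("surviving_fraction: sham plating efficiency must be > 0")
  pe / pe_sham_mean
}

#' Build per-plate surviving fractions from a record table
#'
#' Expects one row per plate with columns `cell_line`, `modality`
#' ("proton", "x-ray" or "sham"), `dose_gy`, `colonies`, `seeded`,
#' `experiment`. Sham rows define the per-experiment (and per-cell-line)
#' normalisation.
#'
#' @param records data.frame of plate records.
#' @return the table with `pe` and `sf` columns added (sham rows keep their
#'   own normalised values).
#' @export
survival_records_sf <- function(records) {
  need <- c("cell_line", "modality", "dose_gy", "colonies", "seeded", "experiment")
  stopifnot(all(need %in% names(records)))
  records$pe <- plating_efficiency(records$colonies, records$seeded)
  key <- interaction(records$cell_line, records$experiment, drop = TRUE)
  sham_mean <- tapply(records$pe[records$modality == "sham"],
                      key[records$modality == "sham"], mean)
  if (any(!levels(key) %in% names(sham_mean)) || any(is.na(sham_mean)) ||
      any(sham_mean <= 0)) {
    stop("survival_records_sf: every cell line x experiment needs sham plates with positive plating efficiency")
  }
  records$sf <- surviving_fraction(records$pe, as.numeric(sham_mean[as.character(key)]))
  records
}

#' Subtract the lethal-dose background surviving fraction
#'
#' For proton irradiations the crescent-shadow region leaves a small
#' unirradiated subpopulation; its surviving fraction is estimated from
#' lethal-dose exposures (> `lethal_gy`) and subtracted from all proton
#' surviving fractions (clamped at 0, since a surviving fraction is a
#' probability). X-ray records are returned unchanged. The background is
#' estimated per cell line.
#'
#' @param records output of [survival_records_sf()].
#' @param lethal_gy lethal-dose threshold (default 30 Gy).
#' @return the table with an `sf_corr` column; attribute `background`
#'   gives the per-cell-line background estimates.
#' @export
subtract_background <- function(records, lethal_gy = 30) {
  stopifnot("sf" %in% names(records))
  records$sf_corr <- records$sf
  bg <- c()
  for (cl in unique(records$cell_line)) {
    pr <- records$modality == "proton" & records$cell_line == cl
    if (!any(pr)) next
    lethal <- pr & records$dose_gy > lethal_gy
    if (!any(lethal)) {
      stop(sprintf("subtract_background: no lethal-dose (> %g Gy) proton records for %s",
                   lethal_gy, cl))
    }
    b <- mean(records$sf[lethal])
    bg[cl] <- b
    records$sf_corr[pr] <- pmax(records$sf[pr] - b, 0)
  }
  attr(records, "background") <- bg
  records
}

#' Two-stage group averaging of surviving fractions
#'
#' Replicate plates are averaged within each experiment first, then the
#' cross-experiment mean and standard deviation are reported per cell line,
#' modality and nominal dose group. Lethal-dose groups (> `exclude_above_gy`)
#' are excluded from the reported curve.
#'
#' @param records output of [survival_records_sf()] (optionally with
#'   `sf_corr` from [subtract_background()]).
#' @param value column to average ("sf_corr" when present, else "sf").
#' @param exclude_above_gy exclusion threshold for the reported curve
#'   (default 30 Gy; `Inf` keeps everything).
#' @return data.frame: cell_line, modality, dose_gy (group-mean measured
#'   dose), mean_sf, sd_sf (NA for a single experiment), n_experiments.
#'   Grouping uses the nominal `dose_group` column when present, otherwise
#'   the measured `dose_gy`.
#' @export
group_and_average <- function(records, value = NULL, exclude_above_gy = 30) {
  if (is.null(value)) value <- if ("sf_corr" %in% names(records)) "sf_corr" else "sf"
  stopifnot(value %in% names(records))
  r <- records[records$modality != "sham" & records$dose_gy <= exclude_above_gy, ]
  r$.grp <- if ("dose_group" %in% names(r)) r$dose_group else r$dose_gy
  per_exp <- stats::aggregate(
    cbind(sf = r[[value]], dose = r$dose_gy),
    by = list(cell_line = r$cell_line, modality = r$modality,
              grp = r$.grp, experiment = r$experiment),
    FUN = mean)
  out <- stats::aggregate(
    per_exp$sf,
    by = list(cell_line = per_exp$cell_line, modality = per_exp$modality,
              grp = per_exp$grp),
    FUN = function(v) c(mean = mean(v),
                        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                        n = length(v)))
  dose <- stats::aggregate(
    per_exp$dose,
    by = list(cell_line = per_exp$cell_line, modality = per_exp$modality,
              grp = per_exp$grp),
    FUN = mean)
  data.frame(cell_line = out$cell_line, modality = out$modality,
             dose_group = out$grp, dose_gy = dose$x,
             mean_sf = out$x[, "mean"], sd_sf = out$x[, "sd"],
             n_experiments = out$x[, "n"])
}

.lq_model <- function(x, cc, a, b) cc * exp(-a * x - b * x^2)

## starting values from a log-linear fit
.lq_start <- function(x, y) {
  ypos <- pmax(y, max(y, na.rm = TRUE) * 1e-4)
  co <- stats::coef(stats::lm(log(ypos) ~ x + I(x^2)))
  c(cc = exp(co[[1]]), a = -co[[2]], b = -co[[3]])
}

#' Orthogonal distance regression of the survival model
#'
#' Fits y = c * exp(-a x - b x^2) with errors in both variables by
#' minimising the weighted orthogonal objective
#' sum_i [ (y_i - f(x_i + d_i))^2 / sy_i^2 + d_i^2 / sx_i^2 ]
#' over (c, a, b) and the latent dose shifts d_i, as one stacked
#' nonlinear least-squares problem solved by Levenberg-Marquardt. Parameter
#' uncertainties come from the Jacobian-based covariance of the full
#' problem, scaled by the residual variance.
#'
#' @param x doses (Gy), at least 4 points.
#' @param sx dose standard errors (> 0).
#' @param y surviving fractions.
#' @param sy surviving-fraction standard errors (> 0).
#' @param start optional named starting values (cc, a, b).
#' @param constrain_b if TRUE, b is constrained >= 0 (fitted on a squared
#'   scale); default unconstrained.
#' @return list of class `survival_fit`: `coefficients` (c, a, b),
#'   `se`, `cov` (3x3), `delta` (latent dose shifts), `residual`
#'   (weighted RMS orthogonal residual), `converged`, `info`.
#' @export
fit_survival_odr <- function(x, sx, y, sy, start = NULL, constrain_b = FALSE) {
  stopifnot(length(x) >= 4, length(sx) == length(x),
            length(y) == length(x), length(sy) == length(x),
            all(sx > 0), all(sy > 0))
  n <- length(x)
  if (is.null(start)) start <- .lq_start(x, y)
  if (constrain_b) start["b"] <- sqrt(max(start[["b"]], 1e-8))
  par0 <- c(start[["cc"]], start[["a"]], start[["b"]], rep(0, n))
  resid_fn <- function(p) {
    b <- if (constrain_b) p[3]^2 else p[3]
    d <- p[-(1:3)]
    c((y - .lq_model(x + d, p[1], p[2], b)) / sy, d / sx)
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5, 9)) {
    stop("fit_survival_odr: Levenberg-Marquardt did not converge (info = ",
         fit$info, ": ", fit$message, ")")
  }
  p <- fit$par
  b_hat <- if (constrain_b) p[3]^2 else p[3]
  dof <- max(2 * n - (n + 3), 1)
  s2 <- fit$deviance / dof
  covfull <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e) {
    matrix(NA_real_, n + 3, n + 3)
  })
  cov3 <- covfull[1:3, 1:3]
  if (constrain_b) {   # delta method for b = p3^2
    J <- diag(3); J[3, 3] <- 2 * p[3]
    cov3 <- J %*% cov3 %*% t(J)
  }
  coefs <- c(c = p[1], a = p[2], b = b_hat)
  structure(list(coefficients = coefs,
                 se = sqrt(pmax(diag(cov3), 0)),
                 cov = cov3,
                 delta = p[-(1:3)],
                 residual = sqrt(fit$deviance / (2 * n)),
                 converged = TRUE,
                 info = fit$info),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  co <- x$coefficients; se <- x$se
  cat(sprintf("LQ survival ODR fit: c = %.4g +- %.2g, a = %.4g +- %.2g /Gy, b = %.4g +- %.2g /Gy^2\n",
              co[1], se[1], co[2], se[2], co[3], se[3]))
  invisible(x)
}

#' Predicted surviving fraction from a fit
#'
#' @param object a `survival_fit`.
#' @param newdata doses in Gy (vector).
#' @param ... unused.
#' @export
predict.survival_fit <- function(object, newdata, ...) {
  co <- object$coefficients
  .lq_model(newdata, co[1], co[2], co[3])
}

#' Overall noise scale matching a target parameter uncertainty
#'
#' For the errors-in-variables study design (dose errors `sx_shape`,
#' relative survival errors `sy_rel` of the model value), all error bars
#' are scaled by a common factor q so that the linearised ODR standard
#' error of one parameter matches a target value. The linearised
#' per-point variance is sy^2 + (f'(x) sx)^2, so the parameter SE is
#' proportional to q and the match is exact.
#'
#' @param params true (c, a, b).
#' @param doses design doses.
#' @param sx_shape dose error shape (Gy).
#' @param sy_rel relative survival error shape (fraction of f(x)).
#' @param target target standard error.
#' @param which parameter whose SE is matched ("c", "a" or "b").
#' @return the scale factor q.
#' @export
survival_noise_scale <- function(params, doses, sx_shape, sy_rel = 0.15,
                                 target, which = c("a", "b", "c")) {
  which <- match.arg(which)
  cc <- params[["c"]]; a <- params[["a"]]; b <- params[["b"]]
  f <- .lq_model(doses, cc, a, b)
  fp <- -(a + 2 * b * doses) * f
  var1 <- (sy_rel * f)^2 + (fp * sx_shape)^2   # q = 1 variance
  J <- cbind(f / cc, -doses * f, -doses^2 * f)
  Fi <- t(J) %*% (J / var1)
  se1 <- sqrt(diag(solve(Fi)))[match(which, c("c", "a", "b"))]
  target / se1
}

#' Simulate one errors-in-variables survival dataset
#'
#' Observed doses are the design doses plus Gaussian jitter `q * sx_shape`;
#' observed survival is the model at the design dose plus Gaussian noise
#' `q * sy_rel * f(x)`.
#'
#' @inheritParams survival_noise_scale
#' @param q overall noise scale (from [survival_noise_scale()]).
#' @return data.frame: x, sx, y, sy (the per-point error bars used).
#' @export
simulate_survival_points <- function(params, doses, sx_shape, sy_rel = 0.15, q) {
  f <- .lq_model(doses, params[["c"]], params[["a"]], params[["b"]])
  sx <- q * sx_shape
  sy <- q * sy_rel * f
  data.frame(x = doses + stats::rnorm(length(doses), 0, sx),
             sx = sx,
             y = f + stats::rnorm(length(doses), 0, sy),
             sy = sy)
}

#' Parameter-recovery study for the ODR fitter
#'
#' Generates `n_rep` synthetic datasets from a printed parameter set at the
#' printed design doses, with noise scaled so the single-fit uncertainty of
#' the tracked parameter matches its printed value, fits each by ODR, and
#' reports the mean recovered parameters.
#'
#' @inheritParams survival_noise_scale
#' @param n_rep number of replicate datasets.
#' @param seed integer seed.
#' @return list: `mean` (average fitted c, a, b), `sd`, `fits` matrix,
#'   `q` (noise scale), `n_failed`.
#' @export
odr_recovery_study <- function(params, doses, sx_shape, sy_rel = 0.15,
                               target, which = "a", n_rep = 200, seed = 1) {
  q <- survival_noise_scale(params, doses, sx_shape, sy_rel, target, which)
  set.seed(seed)
  fits <- matrix(NA_real_, n_rep, 3, dimnames = list(NULL, c("c", "a", "b")))
  n_failed <- 0L
  for (i in seq_len(n_rep)) {
    d <- simulate_survival_points(params, doses, sx_shape, sy_rel, q)
    ft <- tryCatch(fit_survival_odr(d$x, d$sx, d$y, d$sy),
                   error = function(e) NULL)
    if (is.null(ft)) { n_failed <- n_failed + 1L; next }
    fits[i, ] <- ft$coefficients
  }
  ok <- stats::complete.cases(fits)
  list(mean = colMeans(fits[ok, , drop = FALSE]),
       sd = apply(fits[ok, , drop = FALSE], 2, stats::sd),
       fits = fits, q = q, n_failed = n_failed)
}
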