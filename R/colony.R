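## Colony counting: Gaussian scale space, Hessian dark-elliptic-feature
## detection, iterative tangential voting for the well boundary, direct
## least-squares ellipse fitting, and the composed plate counter.
##
## Image convention: plain numeric matrices in [0, 1]; the first index is
## treated as x and the second as y throughout.

## moment-corrected 1D Gaussian derivative kernels at scale sigma
.gauss_kernels <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(2L, ceiling(4 * sigma))
  u <- seq(-r, r)
  g0 <- stats::dnorm(u, 0, sigma); g0 <- g0 / sum(g0)
  g1 <- -(u / sigma^2) * stats::dnorm(u, 0, sigma)
  g1 <- g1 - mean(g1)
  g1 <- g1 / sum(-u * g1)          # correlation gives exact d/dx on ramps
  g2 <- ((u^2 - sigma^2) / sigma^4) * stats::dnorm(u, 0, sigma)
  g2 <- g2 - mean(g2)
  g2 <- g2 * 2 / sum(u^2 * g2)     # exact d2/dx2 on quadratics
  list(g0 = g0, g1 = g1, g2 = g2, radius = r)
}

## filter with reflective boundary handling
.filter_reflect <- function(img, kernel) {
  r <- (dim(kernel) - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  if (any(r >= c(nr, nc))) stop("kernel larger than image")
  ix <- c(rev(seq_len(r[1])), seq_len(nr), nr + 1 - seq_len(r[1]))
  iy <- c(rev(seq_len(r[2])), seq_len(nc), nc + 1 - seq_len(r[2]))
  pad <- img[ix, iy]
  out <- EBImage::filter2(pad, kernel, boundary = "circular")
  out[r[1] + seq_len(nr), r[2] + seq_len(nc)]
}

#' Gaussian scale-space smoothing
#'
#' Convolution of the image with a normalised Gaussian of standard
#' deviation `sigma` (reflective boundary). A constant image is unchanged
#' and the image mean is preserved up to boundary handling.
#'
#' @param img numeric matrix in [0, 1].
#' @param sigma scale in pixels (> 0; must be small against the image).
#' @return list of class `scale_space`: `smoothed`, `original`, `sigma`.
#' @export
gaussian_scale_space <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  k <- .gauss_kernels(sigma)
  if (k$radius >= min(dim(img))) stop("gaussian_scale_space: sigma too large for image")
  sm <- .filter_reflect(img, outer(k$g0, k$g0))
  structure(list(smoothed = sm, original = img, sigma = sigma),
            class = "scale_space")
}

#' Scale-space derivatives and Hessian field
#'
#' First and second derivatives of the scale-space image, computed in a
#' single pass with Gaussian-derivative filters at the smoothing scale
#' (consistent scale-space derivatives rather than finite differences on
#' the smoothed image). `ixy` is symmetric by construction.
#'
#' @param img numeric matrix, or a `scale_space` object.
#' @param sigma scale in pixels (ignored when a `scale_space` is given).
#' @return list of class `hessian_field`: `ix, iy, ixx, ixy, iyy`,
#'   `smoothed`, `sigma`.
#' @export
hessian_field <- function(img, sigma = 2) {
  if (inherits(img, "scale_space")) { sigma <- img$sigma; img <- img$original }
  stopifnot(is.matrix(img))
  k <- .gauss_kernels(sigma)
  structure(list(
    ix  = .filter_reflect(img, outer(k$g1, k$g0)),
    iy  = .filter_reflect(img, outer(k$g0, k$g1)),
    ixx = .filter_reflect(img, outer(k$g2, k$g0)),
    ixy = .filter_reflect(img, outer(k$g1, k$g1)),
    iyy = .filter_reflect(img, outer(k$g0, k$g2)),
    smoothed = .filter_reflect(img, outer(k$g0, k$g0)),
    sigma = sigma
  ), class = "hessian_field")
}

#' Classify Hessian definiteness: dark / bright elliptic feature
#'
#' A pixel is a DARK elliptic feature when the Hessian of the scale-space
#' image is positive definite there (locally convex intensity bowl, i.e. a
#' point darker than its neighbourhood), BRIGHT when negative definite,
#' NEITHER otherwise. Definiteness is tested via the leading-minor
#' criterion (ixx sign and determinant), equivalent to the eigenvalue
#' signs.
#'
#' @param ixx,ixy,iyy Hessian entries (vectors/matrices), or `ixx` may be a
#'   single 2x2 symmetric matrix or a `hessian_field`.
#' @return character vector/matrix with values "DARK", "BRIGHT", "NEITHER".
#' @export
classify_elliptic <- function(ixx, ixy = NULL, iyy = NULL) {
  if (inherits(ixx, "hessian_field")) {
    h <- ixx; ixx <- h$ixx; ixy <- h$ixy; iyy <- h$iyy
  } else if (is.matrix(ixx) && is.null(ixy) && identical(dim(ixx), c(2L, 2L))) {
    h <- ixx; ixx <- h[1, 1]; ixy <- h[1, 2]; iyy <- h[2, 2]
  }
  stopifnot(all(is.finite(ixx)), all(is.finite(ixy)), all(is.finite(iyy)))
  det <- ixx * iyy - ixy^2
  out <- ifelse(det > 0 & ixx > 0, "DARK",
                ifelse(det > 0 & ixx < 0, "BRIGHT", "NEITHER"))
  if (is.matrix(ixx)) dim(out) <- dim(ixx)
  out
}

#' Well ellipse
#'
#' @param cx,cy centre in pixels (x = first image index, y = second).
#' @param major,minor semi-axes in pixels, major >= minor > 0.
#' @param angle rotation in radians.
#' @param residual RMS fit residual (optional).
#' @export
well_ellipse <- function(cx, cy, major, minor, angle = 0, residual = NA_real_) {
  stopifnot(major >= minor, minor > 0)
  structure(list(cx = cx, cy = cy, major = major, minor = minor,
                 angle = angle, residual = residual),
            class = "well_ellipse")
}

#' @export
print.well_ellipse <- function(x, ...) {
  cat(sprintf("Well ellipse: centre (%.1f, %.1f), semi-axes %.1f x %.1f px, rotation %.1f deg\n",
              x$cx, x$cy, x$major, x$minor, 180 * x$angle / pi))
  invisible(x)
}

#' Test points against a (shrunk) well ellipse
#'
#' @param well a [well_ellipse()].
#' @param x,y point coordinates.
#' @param margin_px erosion margin subtracted from both semi-axes.
#' @return logical vector.
#' @export
inside_ellipse <- function(well, x, y, margin_px = 0) {
  a <- max(well$major - margin_px, 1e-6)
  b <- max(well$minor - margin_px, 1e-6)
  ca <- cos(well$angle); sa <- sin(well$angle)
  xr <- (x - well$cx) * ca + (y - well$cy) * sa
  yr <- -(x - well$cx) * sa + (y - well$cy) * ca
  (xr / a)^2 + (yr / b)^2 <= 1
}

## Otsu threshold on a numeric vector in [0, 1]
.otsu <- function(v, nbins = 256) {
  h <- graphics::hist(v, breaks = seq(0, 1, length.out = nbins + 1), plot = FALSE)
  w <- h$counts / sum(h$counts); m <- h$mids
  omega <- cumsum(w); mu <- cumsum(w * m); mu_t <- mu[length(mu)]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  m[which.max(sb)]
}

#' Colony mask and count from a Hessian field
#'
#' DARK-classified pixels inside the (eroded) well are grouped into
#' 8-connected components; components smaller than `min_area` or with mean
#' (smoothed) intensity above `max_mean_intensity` are discarded as noise.
#' The intensity threshold defaults to the Otsu split of the well-interior
#' intensities, which separates stained-colony pixels from background.
#'
#' @param hf a [hessian_field()].
#' @param well a [well_ellipse()].
#' @param min_area minimum component area in pixels (default 20).
#' @param max_mean_intensity maximum mean intensity of a kept component;
#'   NULL for the Otsu default.
#' @param margin_px erosion of the well before masking (default
#'   3 sigma + 3, keeping the rim's edge response out).
#' @return list of class `colony_result`: `count`, `mask`, `labels`,
#'   `centroids` (x, y), `regions` data.frame (area, mean_intensity),
#'   `well`, and the thresholds used.
#' @export
colony_mask <- function(hf, well, min_area = 20, max_mean_intensity = NULL,
                        margin_px = NULL) {
  stopifnot(inherits(hf, "hessian_field"))
  if (!inherits(well, "well_ellipse")) stop("colony_mask: no well ellipse")
  if (is.null(margin_px)) margin_px <- 3 * hf$sigma + 3
  nr <- nrow(hf$ixx); nc <- ncol(hf$ixx)
  xg <- matrix(seq_len(nr), nr, nc)
  yg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inwell <- inside_ellipse(well, xg, yg, margin_px)
  dark <- classify_elliptic(hf) == "DARK" & inwell
  lab <- EBImage::bwlabel(dark * 1)
  lab <- matrix(as.integer(lab), nr, nc)
  nlab <- max(lab)
  if (nlab == 0) {
    return(structure(list(count = 0L, mask = dark & FALSE, labels = lab,
                          centroids = data.frame(x = numeric(), y = numeric()),
                          regions = data.frame(area = integer(),
                                               mean_intensity = numeric()),
                          well = well, min_area = min_area,
                          intensity_threshold = NA_real_),
                     class = "colony_result"))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  area <- tabulate(l, nlab)
  meani <- as.numeric(rowsum(hf$smoothed[idx], l)) / area
  if (is.null(max_mean_intensity)) {
    ## Otsu split of the well interior, capped by a background-proximity
    ## guard: on a colony-free well the Otsu threshold falls inside the
    ## noise distribution itself, so regions must also be markedly darker
    ## than the background level to count
    wellpix <- hf$smoothed[inwell]
    max_mean_intensity <- min(.otsu(wellpix),
                              stats::median(wellpix) - 4 * stats::mad(wellpix))
  }
  keep <- which(area >= min_area & meani <= max_mean_intensity)
  relab <- integer(nlab); relab[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nr, nc)
  lab2[idx] <- relab[l]
  kidx <- which(lab2 > 0); l2 <- lab2[kidx]
  cx <- as.numeric(rowsum(xg[kidx], l2)) / tabulate(l2, length(keep))
  cy <- as.numeric(rowsum(yg[kidx], l2)) / tabulate(l2, length(keep))
  structure(list(count = length(keep), mask = lab2 > 0, labels = lab2,
                 centroids = data.frame(x = cx, y = cy),
                 regions = data.frame(area = area[keep],
                                      mean_intensity = meani[keep]),
                 well = well, min_area = min_area,
                 intensity_threshold = max_mean_intensity),
            class = "colony_result")
}

#' @export
print.colony_result <- function(x, ...) {
  cat(sprintf("Colony result: %d colonies\n", x$count))
  invisible(x)
}

## oriented double-cone voting kernel (undirected orientation phi)
.vote_kernel <- function(phi, aperture_rad, radius) {
  u <- seq(-radius, radius)
  U <- matrix(u, length(u), length(u))
  V <- t(U)
  r <- sqrt(U^2 + V^2)
  ang <- atan2(V, U) %% pi
  d <- abs(ang - (phi %% pi))
  d <- pmin(d, pi - d)
  k <- (r >= 1 & r <= radius & d <= aperture_rad / 2) *
    exp(-r^2 / (2 * (radius / 1.5)^2))
  if (sum(k) > 0) k <- k / sum(k)
  k
}

#' Well-boundary enhancement by iterative tangential voting
#'
#' Gradient-magnitude edge points cast votes along their local tangent
#' direction (perpendicular to the gradient) into double-cone kernels; the
#' angular aperture narrows each iteration, so saliency concentrates on
#' long coherent curves such as the well boundary. Candidate boundary
#' points are the edge points whose final saliency exceeds the median
#' saliency of all edge points.
#'
#' @param img numeric matrix in [0, 1].
#' @param n_iterations voting iterations (default 3).
#' @param aperture_deg start and end full apertures in degrees
#'   (narrowed linearly; default 60 -> 20).
#' @param vote_radius kernel radius in pixels.
#' @param n_orient number of orientation bins over half a turn.
#' @param edge_quantile gradient-magnitude quantile defining edge points.
#' @param sigma_edge gradient scale in pixels.
#' @return list of class `well_saliency`: `saliency` matrix, `points`
#'   data.frame (x, y, saliency), `saliency_history` (per-iteration
#'   saliency at the edge points), `edge_idx`.
#' @export
enhance_well_boundary <- function(img, n_iterations = 3,
                                  aperture_deg = c(60, 20),
                                  vote_radius = 15, n_orient = 18,
                                  edge_quantile = 0.99, sigma_edge = 2) {
  stopifnot(is.matrix(img), n_iterations >= 1)
  hf <- hessian_field(img, sigma_edge)
  mag <- sqrt(hf$ix^2 + hf$iy^2)
  thr <- stats::quantile(mag, edge_quantile)
  edge <- mag >= thr
  if (!any(edge)) stop("enhance_well_boundary: no edges found")
  tangent <- (atan2(hf$iy, hf$ix) + pi / 2) %% pi
  bin <- pmin(1L + floor(tangent / pi * n_orient), n_orient)
  apertures <- seq(aperture_deg[1], aperture_deg[2],
                   length.out = n_iterations) * pi / 180
  w <- mag * edge
  w <- w / sum(w)
  history <- vector("list", n_iterations)
  sal <- NULL
  for (it in seq_len(n_iterations)) {
    sal <- matrix(0, nrow(img), ncol(img))
    for (b in seq_len(n_orient)) {
      wb <- w * (bin == b & edge)
      if (!any(wb > 0)) next
      phi <- (b - 0.5) * pi / n_orient
      sal <- sal + .filter_reflect(wb, .vote_kernel(phi, apertures[it], vote_radius))
    }
    history[[it]] <- sal[edge]
    w <- sal * edge
    if (sum(w) <= 0) break
    w <- w / sum(w)
  }
  eidx <- which(edge)
  s <- sal[eidx]
  keep <- s >= stats::median(s)
  pts <- data.frame(
    x = ((eidx - 1) %% nrow(img)) + 1,
    y = ((eidx - 1) %/% nrow(img)) + 1,
    saliency = s
  )[keep, ]
  structure(list(saliency = sal, points = pts,
                 saliency_history = history, edge_idx = eidx),
            class = "well_saliency")
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable direct conic fit constrained to an ellipse
#' (Halir-Flusser formulation of the Fitzgibbon fit), followed by
#' conversion to geometric parameters. Errors on fewer than 6 points or
#' degenerate configurations.
#'
#' @param x,y point coordinates (or a two-column matrix/data.frame as `x`).
#' @param weights optional non-negative point weights.
#' @return a [well_ellipse()] with the RMS algebraic residual.
#' @export
fit_ellipse <- function(x, y = NULL, weights = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 6) stop("fit_ellipse: need at least 6 points")
  if (is.null(weights)) weights <- rep(1, length(x))
  sw <- sqrt(weights / mean(weights))
  mx <- mean(x); my <- mean(y); sc <- stats::sd(c(x - mx, y - my))
  if (!is.finite(sc) || sc == 0) stop("fit_ellipse: degenerate points")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2) * sw
  D2 <- cbind(xs, ys, 1) * sw
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) stop("fit_ellipse: degenerate points"))
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  ok <- which(Re(4 * ev$vectors[1, ] * ev$vectors[3, ] - ev$vectors[2, ]^2) > 0 &
                abs(Im(ev$values)) < 1e-8)
  if (!length(ok)) stop("fit_ellipse: points do not determine an ellipse")
  v1 <- Re(ev$vectors[, ok[1]])
  conic <- c(v1, as.numeric(T1 %*% v1))  # A B C D E F in scaled frame
  ## un-scale: x = (X - mx)/sc
  A <- conic[1] / sc^2; B <- conic[2] / sc^2; C <- conic[3] / sc^2
  D <- conic[4] / sc - 2 * A * mx - B * my
  E <- conic[5] / sc - 2 * C * my - B * mx
  F <- conic[6] + A * mx^2 + B * mx * my + C * my^2 -
    conic[4] * mx / sc - conic[5] * my / sc
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Mq, symmetric = TRUE)
  ax <- sqrt(-Fc / eg$values)
  if (any(!is.finite(ax))) stop("fit_ellipse: points do not determine an ellipse")
  i_major <- which.max(ax)
  angle <- atan2(eg$vectors[2, i_major], eg$vectors[1, i_major]) %% pi
  res <- sqrt(mean((cbind(x^2, x * y, y^2, x, y, 1) %*% c(A, B, C, D, E, F))^2))
  well_ellipse(cx, cy, max(ax), min(ax), angle, residual = res)
}

## robust trimmed refit: discard points with large algebraic residual
.fit_ellipse_robust <- function(pts, n_rounds = 3) {
  keep <- rep(TRUE, nrow(pts))
  we <- fit_ellipse(pts$x, pts$y, weights = pts$saliency)
  for (i in seq_len(n_rounds)) {
    a <- we$major; b <- we$minor
    ca <- cos(we$angle); sa <- sin(we$angle)
    xr <- (pts$x - we$cx) * ca + (pts$y - we$cy) * sa
    yr <- -(pts$x - we$cx) * sa + (pts$y - we$cy) * ca
    d <- sqrt((xr / a)^2 + (yr / b)^2) - 1   # normalised radial residual
    s <- stats::mad(d, center = 0)
    keep <- abs(d) <= max(3 * s, 0.02)
    if (sum(keep) < 6) break
    we <- fit_ellipse(pts$x[keep], pts$y[keep], weights = pts$saliency[keep])
  }
  we
}

#' Default plate-processing configuration
#'
#' @param sigma detection scale in pixels (expected colony radius / sqrt 2).
#' @param min_area,max_mean_intensity colony filters (see [colony_mask()]).
#' @param ... overrides for the voting stage
#'   (n_iterations, aperture_deg, vote_radius, edge_quantile).
#' @export
plate_config <- function(sigma = 3, min_area = 20, max_mean_intensity = NULL,
                         ...) {
  cfg <- list(sigma = sigma, min_area = min_area,
              max_mean_intensity = max_mean_intensity,
              n_iterations = 3, aperture_deg = c(60, 20),
              vote_radius = 15, edge_quantile = 0.99)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("plate_config: unknown fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Count colonies on a plate photograph
#'
#' Two consecutive stages: (1) well detection — tangential-voting boundary
#' enhancement followed by a robust direct least-squares ellipse fit; (2)
#' colony detection — dark elliptic features of the scale-space Hessian
#' inside the well, filtered by size and intensity. Deterministic for a
#' fixed configuration. Colour arrays are converted to grayscale by
#' luminance first.
#'
#' @param img numeric matrix in [0, 1], or an array with a third (colour)
#'   dimension.
#' @param config a [plate_config()].
#' @return list: `result` (a `colony_result`), `well` (the fitted
#'   [well_ellipse()]), `saliency` (the voting output).
#' @export
count_plate <- function(img, config = plate_config()) {
  if (length(dim(img)) == 3) {
    w <- c(0.2126, 0.7152, 0.0722)[seq_len(dim(img)[3])]
    img <- apply(sweep(img, 3, w / sum(w), "*"), c(1, 2), sum)
  }
  stopifnot(is.matrix(img))
  ws <- enhance_well_boundary(img, n_iterations = config$n_iterations,
                              aperture_deg = config$aperture_deg,
                              vote_radius = config$vote_radius,
                              edge_quantile = config$edge_quantile)
  well <- .fit_ellipse_robust(ws$points)
  hf <- hessian_field(img, config$sigma)
  res <- colony_mask(hf, well, min_area = config$min_area,
                     max_mean_intensity = config$max_mean_intensity)
  list(result = res, well = well, saliency = ws)
}
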