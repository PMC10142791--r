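#' Segment cells in a micrograph
#'
#' Global threshold (Otsu by default) followed by connected-component
#' labeling. Regions smaller than `min_area_px` or touching the field
#' border are flagged and excluded from measurement (the automated
#' counterpart of discarding misclassified objects during manual counting).
#'
#' @param image Grayscale matrix (width x height), values in [0, 1] (other
#'   ranges are rescaled by the maximum).
#' @param min_area_px Minimum region area in pixels (default 4).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value Threshold for `"fixed"`.
#' @return List with `labels` (label matrix) and `regions` (data frame:
#'   `region_id`, `area_px`, `touches_border`, `retained`). A blank image
#'   yields zero regions, not an error.
#' @export
segment_cells <- function(image, min_area_px = 4,
                          threshold_method = c("otsu", "fixed"),
                          threshold_value = NULL) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(image))
  rng <- range(image)
  empty <- list(labels = matrix(0L, nrow(image), ncol(image)),
                regions = data.frame(region_id = integer(0),
                                     area_px = integer(0),
                                     touches_border = logical(0),
                                     retained = logical(0)))
  if (diff(rng) < 1e-8) return(empty)
  img <- image
  if (rng[2] > 1) img <- img / rng[2]
  bg_est <- stats::median(img)
  noise_floor <- bg_est + 5 * stats::mad(img)
  th <- if (threshold_method == "otsu") {
    # Otsu can land inside the background-noise mode when foreground is
    # sparse; floor it at a robust background estimate (median + 5 MAD)
    max(EBImage::otsu(EBImage::Image(img), range = range(img)),
        noise_floor)
  } else {
    stopifnot(is.numeric(threshold_value))
    threshold_value
  }
  bw <- img > th
  if (!any(bw)) return(empty)
  # closing with a 3x3 brush bridges 1-px breaks along thin dim cells
  # without merging distinct cells (placed >= 5 px apart)
  bw <- as.matrix(EBImage::closing(EBImage::Image(bw),
                                   EBImage::makeBrush(3, "box"))) > 0
  lab <- EBImage::bwlabel(bw)
  labm <- as.matrix(EBImage::imageData(lab))
  if (threshold_method == "otsu") {
    # second pass: Otsu tracks the bright cells and can swallow dim
    # sub-resolution ones entirely; components present at a lower
    # threshold that touch no first-pass region are rescued
    th2 <- max(bg_est + 0.4 * (th - bg_est), noise_floor)
    if (th2 < th) {
      bw2 <- as.matrix(EBImage::closing(
        EBImage::Image(img > th2), EBImage::makeBrush(3, "box"))) > 0
      lab2 <- as.matrix(EBImage::bwlabel(bw2))
      overlap <- setdiff(unique(lab2[labm > 0]), 0L)
      rescue <- setdiff(unique(lab2[lab2 > 0]), overlap)
      nxt <- max(labm)
      for (id in rescue) {
        sel <- lab2 == id
        if (sum(sel) >= min_area_px) {
          nxt <- nxt + 1L
          labm[sel] <- nxt
        }
      }
    }
  }
  ids <- seq_len(max(labm))
  area <- tabulate(labm[labm > 0], nbins = max(labm))
  border_ids <- unique(c(labm[1, ], labm[nrow(labm), ],
                         labm[, 1], labm[, ncol(labm)]))
  touches <- ids %in% border_ids[border_ids > 0]
  retained <- area >= min_area_px & !touches
  list(labels = labm,
       regions = data.frame(region_id = ids, area_px = area,
                            touches_border = touches, retained = retained))
}

## Skeletonization ------------------------------------------------------------

# Zhang-Suen thinning of a logical matrix, vectorized over the whole
# image via shifted neighbor planes.
thin_mask <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(M, dx, dy) {
    out <- matrix(FALSE, nr, nc)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    out[xs, ys] <- M[xs - dx, ys - dy]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors clockwise from north (P2..P9); x = row, y = col,
      # "north" = y + 1 (orientation is irrelevant to the algorithm)
      P2 <- shift(m, 0, 1);  P3 <- shift(m, 1, 1)
      P4 <- shift(m, 1, 0);  P5 <- shift(m, 1, -1)
      P6 <- shift(m, 0, -1); P7 <- shift(m, -1, -1)
      P8 <- shift(m, -1, 0); P9 <- shift(m, -1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (step == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

# Longest geodesic path through a skeleton (8-connected, Euclidean edge
# weights). Returns ordered coordinates and the geodesic length in px.
skeleton_path <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) return(list(coords = pts, length_px = 0))
  if (n == 1L) return(list(coords = pts, length_px = 0))
  dx <- outer(pts[, 1], pts[, 1], "-")
  dy <- outer(pts[, 2], pts[, 2], "-")
  adj <- abs(dx) <= 1 & abs(dy) <= 1
  diag(adj) <- FALSE
  wmat <- sqrt(dx^2 + dy^2)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edges) == 0L) return(list(coords = pts[1, , drop = FALSE],
                                     length_px = 0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               weight = wmat[edges]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  # double-sweep: farthest node from an arbitrary start, then farthest
  # from that; exact on trees, which thinned skeletons essentially are
  d1 <- igraph::distances(g, v = 1)
  d1[!is.finite(d1)] <- -1
  u <- which.max(d1)
  du <- igraph::distances(g, v = u)
  du[!is.finite(du)] <- -1
  v <- which.max(du)
  sp <- igraph::shortest_paths(g, from = u, to = v, output = "vpath")
  idx <- as.integer(igraph::as_ids(sp$vpath[[1]]))
  coords <- pts[idx, , drop = FALSE]
  list(coords = coords, length_px = max(du[v], 0))
}

# Cut `crop` at threshold `th`, keeping the connected components that
# overlap the seed mask; falls back on the seed mask when the cut is
# empty.
.cut_mask <- function(crop, th, seed) {
  newmask <- crop >= th
  if (!any(newmask)) return(seed)
  lab <- as.matrix(EBImage::bwlabel(newmask))
  ids <- setdiff(unique(lab[seed]), 0L)
  if (!length(ids)) return(seed)
  matrix(lab %in% ids, nrow(seed), ncol(seed))
}

# Radial intensity profile of a unit-intensity disc of radius R blurred
# by an isotropic Gaussian of sd sigma, evaluated at radius r (exact 2-D
# convolution reduced to a 1-D Rice-type integral).
.blurred_disc_intensity <- function(r, R, sigma) {
  rho <- seq(0, R, length.out = 200L)
  dr <- rho[2] - rho[1]
  x <- rho * r / sigma^2
  f <- rho / sigma^2 * exp(-(rho - r)^2 / (2 * sigma^2)) *
    besselI(x, 0, expon.scaled = TRUE)
  sum(f) * dr - (f[1] + f[length(f)]) * dr / 2
}

# Half-maximum radius (relative to the blurred peak) of a blurred disc.
.disc_halfmax_radius <- function(R, sigma) {
  peak <- .blurred_disc_intensity(0, R, sigma)
  stats::uniroot(function(r) .blurred_disc_intensity(r, R, sigma) - peak / 2,
                 lower = 0, upper = R + 5 * sigma, tol = 1e-4)$root
}

# Invert the half-max radius: the true disc radius whose blurred half-max
# contour has the measured radius. Used to correct the sizes of round
# cells, whose half-max diameter inflates when the diameter approaches
# the PSF width.
.invert_disc_halfmax <- function(r_hm, sigma) {
  if (sigma <= 0 || r_hm <= 0) return(r_hm)
  lo <- max(r_hm - 4 * sigma, 0.05 * sigma)
  hi <- r_hm + 4 * sigma
  f <- function(R) .disc_halfmax_radius(R, sigma) - r_hm
  flo <- f(lo)
  if (flo > 0) return(r_hm)   # already below model support
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-4)$root
}

# Half-maximum half-width of a unit slab of half-width w blurred by a
# 1-D Gaussian of sd sigma: I(x) = Phi((w-x)/s) - Phi((-w-x)/s), solved
# at half the central peak. Models the measured width of an elongated
# cell.
.slab_halfmax_halfwidth <- function(w, sigma) {
  peak <- 2 * stats::pnorm(w / sigma) - 1
  I <- function(x) stats::pnorm((w - x) / sigma) - stats::pnorm((-w - x) / sigma)
  stats::uniroot(function(x) I(x) - peak / 2,
                 lower = 0, upper = w + 5 * sigma, tol = 1e-4)$root
}

# Invert the slab half-max: true half-width from the measured one.
.invert_slab_halfmax <- function(x_hm, sigma) {
  if (sigma <= 0 || x_hm <= 0) return(x_hm)
  lo <- max(x_hm - 4 * sigma, 0.05 * sigma)
  f <- function(w) .slab_halfmax_halfwidth(w, sigma) - x_hm
  if (f(lo) > 0) return(x_hm)
  stats::uniroot(f, lower = lo, upper = x_hm + 4 * sigma, tol = 1e-4)$root
}

# Second-moment variances of a stadium (rectangle len x w capped by two
# half-discs of radius w/2), along (major, minor) axes.
.stadium_moments <- function(len, w) {
  r <- w / 2
  A_rect <- len * w; A_cap <- pi * r^2
  A <- A_rect + A_cap
  vy <- (A_rect * w^2 / 12 + A_cap * r^2 / 4) / A
  # caps: integral of x^2 for a half-disc against its flat edge is
  # pi r^4 / 8; first moment about the edge is 2 r^3 / 3
  cap_x2 <- 2 * ((len / 2)^2 * (pi * r^2 / 2) +
                 2 * (len / 2) * (2 * r^3 / 3) + pi * r^4 / 8)
  vx <- (A_rect * len^2 / 12 + cap_x2) / A
  c(vx = vx, vy = vy)
}

# Principal-axis dimensions of a mask from second moments of the pixel
# cloud. Near-isotropic regions use the (unbiased) trace as a circle
# diameter — ordered eigenvalues of a noisy circular cloud split apart,
# biasing the major axis up and the minor down. Anisotropic regions are
# fitted as a stadium (capsule cross-section), whose flat flanks carry
# more variance than an ellipse of equal width; an ellipse model would
# overestimate the width by up to 15%. Used when the skeleton
# degenerates.
.moment_dims_px <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(c(L = 2 * sqrt(nrow(pts) / pi),
                              W = 2 * sqrt(nrow(pts) / pi)))
  cov <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) + diag(2) / 12
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-6)
  if ((ev[1] - ev[2]) / (ev[1] + ev[2]) < 0.1) {
    d <- 4 * sqrt(mean(ev))
    return(c(L = d, W = d))
  }
  fit <- stats::optim(
    c(log(max(4 * sqrt(ev[1]) - 4 * sqrt(ev[2]), 0.5)), log(4 * sqrt(ev[2]))),
    function(p) {
      sm <- .stadium_moments(exp(p[1]), exp(p[2]))
      (log(sm["vx"] / ev[1]))^2 + (log(sm["vy"] / ev[2]))^2
    },
    method = "Nelder-Mead", control = list(maxit = 300, reltol = 1e-10))
  len <- exp(fit$par[1]); w <- exp(fit$par[2])
  if (fit$convergence != 0 || w > len + w) {
    return(c(L = 4 * sqrt(ev[1]), W = 4 * sqrt(ev[2])))
  }
  c(L = len + w, W = w)
}

# Reflect-padded moving average of a profile (window odd).
.smooth_profile <- function(v, window = 5) {
  n <- length(v)
  if (n < window) return(v)
  pad <- (window - 1) / 2
  k <- rep(1 / window, window)
  s <- stats::filter(c(rep(v[1], pad), v, rep(v[n], pad)), k)
  as.numeric(s[!is.na(s)])
}

# Turning of a single circular arc from its chord length c and sagitta h:
# tau = 4 atan(2h / c) (exact for a circular arc, any turning < 360 deg).
.arc_turning_deg <- function(h, c) {
  if (c <= 0 || h <= 0) return(0)
  4 * atan(2 * h / c) * 180 / pi
}

# Turning analysis of an ordered centerline via chord-sagitta geometry.
# Signed perpendicular deviations of the skeleton path from its
# end-to-end chord are fitted with a cubic in normalized arc position:
# the fit averages single-pixel staircase jitter over the whole path, a
# two-lobed fit (both signs exceeding the noise-scaled threshold) reads
# as an S (one inflection), a one-lobed fit as a single arc whose
# sagitta is the fitted extremum. Far more robust on 6-20 px skeletons
# than accumulating tangent-angle differences.
.turning_stats <- function(coords, lobe_min_px = 0.5, scale = 1) {
  n <- nrow(coords)
  if (n < 5L) return(list(total_turning_deg = 0, inflection_count = 0L))
  x <- coords[, 1]; y <- coords[, 2]
  m <- length(x)
  chord <- c(x[m] - x[1], y[m] - y[1])
  cl <- sqrt(sum(chord^2))
  if (cl < 4 * scale)
    return(list(total_turning_deg = 0, inflection_count = 0L))
  u <- chord / cl
  dev <- (x - x[1]) * (-u[2]) + (y - y[1]) * u[1]   # signed distance
  tt <- seq(0, 1, length.out = m)
  Xc <- cbind(1, tt, tt^2, tt^3)
  fitc <- stats::lm.fit(Xc, dev)
  pred <- fitc$fitted.values
  sd_r <- if (m > 5) stats::sd(fitc$residuals) * sqrt(m / (m - 4)) else 0.5
  thr <- max(lobe_min_px * scale, 3 * sd_r * sqrt(4 / m))
  pos <- max(pred); neg <- -min(pred)
  if (pos > thr && neg > thr) {
    # S-shape: split the path at the fitted zero crossing between lobes
    i_pos <- which.max(pred); i_neg <- which.min(pred)
    lo <- min(i_pos, i_neg); hi <- max(i_pos, i_neg)
    cross <- which(pred[lo:(hi - 1)] * pred[(lo + 1):hi] <= 0)
    split <- if (length(cross)) lo + cross[1] else (lo + hi) %/% 2
    tau <- 0
    for (seg in list(1:split, split:m)) {
      xs <- x[seg]; ys <- y[seg]
      ms <- length(xs)
      if (ms < 4) next
      ch <- c(xs[ms] - xs[1], ys[ms] - ys[1])
      cls <- sqrt(sum(ch^2))
      if (cls < 2) next
      us <- ch / cls
      dv <- (xs - xs[1]) * (-us[2]) + (ys - ys[1]) * us[1]
      ts <- seq(0, 1, length.out = ms)
      pr <- stats::lm.fit(cbind(1, ts, ts^2), dv)$fitted.values
      tau <- tau + .arc_turning_deg(max(abs(pr)), cls)
    }
    return(list(total_turning_deg = tau, inflection_count = 1L))
  }
  # single arc: parabolic sagitta minus the amplitude a pure-jitter
  # profile would produce
  fitp <- stats::lm.fit(cbind(1, tt, tt^2), dev)
  h <- max(abs(fitp$fitted.values))
  sd_p <- if (m > 4) stats::sd(fitp$residuals) * sqrt(m / (m - 3)) else 0.5
  h_adj <- max(h - sd_p * sqrt(3 / m) - 0.1 * scale, 0)
  list(total_turning_deg = .arc_turning_deg(h_adj, cl),
       inflection_count = 0L)
}

#' Classify centerline curvature
#'
#' Operational thresholds on the smoothed-centerline turning: `S` when at
#' least one inflection and total turning >= `turn_min`; `C` when no
#' inflection and turning > 90 degrees; `curved` when no inflection and
#' `turn_min` < turning <= 90; otherwise `straight`.
#'
#' @param total_turning_deg Total absolute centerline turning, degrees.
#' @param inflection_count Number of curvature sign changes.
#' @param turn_min Minimum turning treated as curved (default 15 degrees).
#' @return One of [curvature_levels()].
#' @export
classify_curvature <- function(total_turning_deg, inflection_count,
                               turn_min = 15) {
  stopifnot(total_turning_deg >= 0, inflection_count >= 0)
  if (inflection_count >= 1 && total_turning_deg >= turn_min) return("S")
  if (inflection_count == 0 && total_turning_deg > 90) return("C")
  if (inflection_count == 0 && total_turning_deg > turn_min) return("curved")
  "straight"
}

#' Measurement calibration
#'
#' Multiplicative corrections applied to measured lengths and widths,
#' anchored on beads of known diameter.
#'
#' @param length_scale,width_scale Unitless scales, each in (0.5, 2).
#' @param pixel_size um per pixel.
#' @param psf_fwhm_px Full width at half maximum of the point-spread
#'   function, px (0 = no blur correction). Half-maximum dimensions of a
#'   blurred object inflate approximately in quadrature with the PSF
#'   FWHM; [measure_region()] removes this as
#'   `sqrt(measured^2 - fwhm^2)`.
#' @return An object of class `prok_calibration`.
#' @export
calibration <- function(length_scale = 1, width_scale = 1,
                        pixel_size = 0.106, psf_fwhm_px = 0) {
  stopifnot(length_scale > 0.5, length_scale < 2,
            width_scale > 0.5, width_scale < 2, pixel_size > 0,
            psf_fwhm_px >= 0)
  structure(list(length_scale = length_scale, width_scale = width_scale,
                 pixel_size = pixel_size, psf_fwhm_px = psf_fwhm_px),
            class = "prok_calibration")
}

# Remove point-spread inflation from a half-maximum dimension (px):
# quadrature deconvolution, floored at one pixel.
.deblur_px <- function(d_px, fwhm_px) {
  if (fwhm_px <= 0) return(d_px)
  sqrt(pmax(d_px^2 - fwhm_px^2, 1))
}

# Estimate the PSF sigma (px) from the radial edge profile of bright
# discs: the edge of a bead much larger than the PSF follows
# I(r) = bg + amp * Phi((R - r) / sigma); sigma is recovered by
# nonlinear least squares on the raw per-pixel radial profile.
.estimate_psf_sigma_px <- function(image, labels, ids, max_objects = 10) {
  sig <- numeric(0)
  for (id in utils::head(ids, max_objects)) {
    idx <- which(labels == id, arr.ind = TRUE)
    cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
    pad <- 8L
    x0 <- max(min(idx[, 1]) - pad, 1L); x1 <- min(max(idx[, 1]) + pad, nrow(image))
    y0 <- max(min(idx[, 2]) - pad, 1L); y1 <- min(max(idx[, 2]) + pad, ncol(image))
    gx <- x0:x1; gy <- y0:y1
    r <- sqrt((rep(gx, times = length(gy)) - cx)^2 +
              (rep(gy, each = length(gx)) - cy)^2)
    I <- as.vector(image[gx, gy])
    if (length(I) < 40) next
    bg0 <- stats::quantile(I, 0.05, names = FALSE)
    amp0 <- stats::quantile(I, 0.95, names = FALSE) - bg0
    if (amp0 <= 0) next
    R0 <- sqrt(nrow(idx) / pi)
    obj <- function(p) {
      mu <- p[3] + p[4] * stats::pnorm((p[1] - r) / exp(p[2]))
      sum((I - mu)^2)
    }
    fit <- stats::optim(c(R0, log(1), bg0, amp0), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    s <- exp(fit$par[2])
    if (is.finite(s) && s > 0.05 && s < 10) sig <- c(sig, s)
  }
  if (!length(sig)) 0 else stats::median(sig)
}

#' Measure one segmented region
#'
#' Extracts cell length, width and curvature descriptors from a labeled
#' region: the width is twice the mean medial-axis distance-transform
#' value along the skeleton; the length is the skeleton geodesic length
#' plus the width (hemispherical caps included); regions whose skeleton
#' degenerates to (nearly) a point are treated as round cells with
#' L = W = equivalent-circle diameter. Curvature descriptors come from the
#' smoothed skeleton tangent angle.
#'
#' @param labels Label matrix from [segment_cells()].
#' @param region_id Region label to measure.
#' @param calib A [calibration()].
#' @param min_area_px Minimum area; smaller regions are rejected.
#' @param turn_min Curvature threshold passed to [classify_curvature()].
#' @param image Optional grayscale image the labels came from. When given,
#'   the region mask is re-derived at the local half-maximum intensity
#'   (midway between local background and object peak), which places the
#'   boundary of a Gaussian-blurred object at its true edge and removes
#'   the width inflation of a low global threshold.
#' @return One-row data frame: `region_id`, `area_px`, `L_um`, `W_um`,
#'   `skeleton_length_px`, `total_turning_deg`, `inflection_count`,
#'   `curvature_class`, `centroid_x_px`, `centroid_y_px`. Always satisfies
#'   `L_um >= W_um`.
#' @export
measure_region <- function(labels, region_id, calib = calibration(),
                           min_area_px = 4, turn_min = 15, image = NULL) {
  stopifnot(inherits(calib, "prok_calibration"))
  idx <- which(labels == region_id, arr.ind = TRUE)
  area <- nrow(idx)
  if (area < min_area_px)
    stop("region ", region_id, " smaller than min_area_px")
  px <- calib$pixel_size
  pad <- 3L
  x0 <- max(min(idx[, 1]) - pad, 1L); x1 <- min(max(idx[, 1]) + pad, nrow(labels))
  y0 <- max(min(idx[, 2]) - pad, 1L); y1 <- min(max(idx[, 2]) + pad, ncol(labels))
  mask <- matrix(FALSE, x1 - x0 + 1L, y1 - y0 + 1L)
  mask[cbind(idx[, 1] - x0 + 1L, idx[, 2] - y0 + 1L)] <- TRUE
  z <- 1
  sigma_tot <- 0
  if (!is.null(image)) {
    # re-measure at 2x resolution on a lightly smoothed crop cut at the
    # local half-maximum. Bilinear interpolation halves the boundary
    # staircase jitter; the smoothing stabilizes threshold and boundary
    # under noise and is folded, together with the calibrated PSF, into
    # a total optical blur sigma_tot used by the model-based size
    # corrections below.
    z <- 2
    smooth_sigma <- 1
    crop <- image[x0:x1, y0:y1]
    cz <- as.matrix(EBImage::resize(EBImage::Image(crop),
                                    w = nrow(crop) * z, h = ncol(crop) * z))
    czs <- as.matrix(EBImage::gblur(cz, sigma = smooth_sigma))
    mz <- as.matrix(EBImage::resize(EBImage::Image(mask + 0),
                                    w = nrow(mask) * z, h = ncol(mask) * z,
                                    filter = "none")) > 0.5
    bg <- stats::median(czs[!mz])
    pk <- stats::quantile(czs[mz], 0.98, names = FALSE)
    if (!is.finite(bg)) bg <- min(czs)
    mask <- if (pk > bg) .cut_mask(czs, bg + 0.5 * (pk - bg), mz) else mz
    # total blur: the calibrated edge spread (optics plus camera pixel
    # aperture, as fitted on bead edges) and the measurement-time
    # smoothing
    sigma_tot <- sqrt(((calib$psf_fwhm_px %||% 0) / 2.355 * z)^2 +
                      smooth_sigma^2)
  }
  pxz <- px / z
  area <- sum(mask) / z^2
  if (area < min_area_px)
    stop("region ", region_id, " smaller than min_area_px after refinement")
  dm <- as.matrix(EBImage::distmap(mask))
  skel <- thin_mask(mask)
  sp <- skeleton_path(skel)
  d_eq_pxz <- 2 * sqrt(sum(mask) / pi)
  w_raw_pxz <- if (nrow(sp$coords) > 0) 2 * mean(dm[sp$coords]) else d_eq_pxz
  round_cell <- sp$length_px < max(2 * z, 0.5 * w_raw_pxz)
  if (round_cell) {
    # skeleton degenerates for round/stubby regions; fall back on
    # principal-axis (second-moment) dimensions of the half-max mask,
    # inverted through the blurred-disc model. 0.25 px compensates the
    # boundary-pixel sampling excess of the binary cut (calibrated on
    # rendered discs across blur/noise settings).
    md <- .moment_dims_px(mask) - 0.25 * (z > 1)
    L_um <- 2 * .invert_disc_halfmax(md[["L"]] / 2, sigma_tot) * pxz *
      calib$length_scale
    W_um <- 2 * .invert_disc_halfmax(md[["W"]] / 2, sigma_tot) * pxz *
      calib$width_scale
    turn <- list(total_turning_deg = 0, inflection_count = 0L)
  } else {
    turn <- .turning_stats(sp$coords, scale = z)
    # the skeleton stops short of the cell tips; extrapolate the turning
    # over the missing arc at constant curvature
    len_s <- max(sp$length_px, 1)
    f <- min((len_s + w_raw_pxz) / len_s, 2)
    turn$total_turning_deg <- turn$total_turning_deg * f
    # half-max width from the mask area given the centerline length
    # (A ~ w*len + pi*r_tip^2): sub-pixel accurate where the distance
    # transform is quantized. The tip radius (half-max contour of the
    # cap, a disc of radius W/2) and the slab inversion are iterated to
    # consistency. Blur partially fills the inner bend of strongly
    # curved cells, inflating both area and mean medial distance; the
    # median medial distance caps the estimate there.
    len_c <- sp$length_px + 1.5   # thinning erodes ~1.5 px of skeleton
    A <- sum(mask)
    w_hm <- w_raw_pxz
    w_half <- w_hm / 2; r_tip <- w_half
    for (it in 1:3) {
      w_half <- .invert_slab_halfmax(w_hm / 2, sigma_tot)
      r_tip <- if (sigma_tot > 0) .disc_halfmax_radius(w_half, sigma_tot)
               else w_half
      w_hm <- max((A - pi * r_tip^2) / len_c, 1)
    }
    if (turn$total_turning_deg > 0 && sigma_tot > 0) {
      # blur widens curved cells: the concave inner edge's half-max
      # contour shifts outward by ~sigma^2*kappa while the convex outer
      # edge shifts inward by about half that, leaving a net widening
      # of ~sigma^2*kappa/2; subtract it
      kappa <- (turn$total_turning_deg * pi / 180) / len_c
      w_hm2 <- max(w_hm - sigma_tot^2 * kappa / 2, 1)
      # beyond ~180 deg the two arms also approach each other and blur
      # fills the opening; cap with a low quantile of medial distances
      if (turn$total_turning_deg > 180 && nrow(sp$coords) > 0)
        w_hm2 <- min(w_hm2, 2 * stats::quantile(dm[sp$coords], 0.2,
                                                names = FALSE))
      if (w_hm2 < w_hm) {
        w_hm <- w_hm2
        w_half <- .invert_slab_halfmax(w_hm / 2, sigma_tot)
        r_tip <- if (sigma_tot > 0) .disc_halfmax_radius(w_half, sigma_tot)
                 else w_half
      }
    }
    W_um <- 2 * w_half * pxz * calib$width_scale
    # mask extent along the centerline is len_c + 2*r_tip; true length
    # adds the un-blurred caps
    centerline_pxz <- len_c + (w_hm - 2 * r_tip)
    L_um <- (centerline_pxz + 2 * w_half) * pxz * calib$length_scale
  }
  if (W_um > L_um) { tmp <- W_um; W_um <- L_um; L_um <- tmp }
  data.frame(
    region_id = region_id, area_px = area,
    L_um = L_um, W_um = W_um,
    skeleton_length_px = sp$length_px / z,
    total_turning_deg = turn$total_turning_deg,
    inflection_count = turn$inflection_count,
    curvature_class = classify_curvature(turn$total_turning_deg,
                                         turn$inflection_count, turn_min),
    centroid_x_px = mean(idx[, 1]), centroid_y_px = mean(idx[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Measure every retained region of an image
#'
#' @param image Grayscale matrix.
#' @param calib A [calibration()].
#' @param min_area_px Minimum region area.
#' @param ... Passed to [segment_cells()].
#' @return Data frame of per-region measurements (one row per retained
#'   region; empty for a blank image).
#' @export
measure_micrograph <- function(image, calib = calibration(),
                               min_area_px = 4, ...) {
  seg <- segment_cells(image, min_area_px = min_area_px, ...)
  keep <- seg$regions$region_id[seg$regions$retained]
  rows <- lapply(keep, function(id)
    measure_region(seg$labels, id, calib, min_area_px = min_area_px,
                   image = image))
  if (!length(rows)) {
    return(data.frame(region_id = integer(0), area_px = integer(0),
                      L_um = numeric(0), W_um = numeric(0),
                      skeleton_length_px = numeric(0),
                      total_turning_deg = numeric(0),
                      inflection_count = integer(0),
                      curvature_class = character(0),
                      centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Calibrate measurement scales with latex beads
#'
#' Measures a field of monosized beads of known diameter with identity
#' calibration and sets the length and width scales so that the mean
#' measured bead diameter equals the true diameter. Blur inflates the
#' apparent bead size, so blurred optics yield scales below 1.
#'
#' @param bead_image Grayscale bead-field matrix.
#' @param true_diameter_um Certified bead diameter, um (default 2.13).
#' @param pixel_size um per pixel.
#' @param min_beads Minimum number of detected beads (default 5).
#' @return A [calibration()].
#' @export
calibrate_with_beads <- function(bead_image, true_diameter_um = 2.13,
                                 pixel_size = 0.106, min_beads = 5) {
  seg <- segment_cells(bead_image)
  keep <- seg$regions$region_id[seg$regions$retained]
  if (length(keep) < min_beads)
    stop("only ", length(keep), " beads detected; need >= ", min_beads)
  # the bead edge profile doubles as a PSF standard
  sigma_px <- .estimate_psf_sigma_px(bead_image, seg$labels, keep)
  cal0 <- calibration(pixel_size = pixel_size,
                      psf_fwhm_px = 2.355 * sigma_px)
  meas <- do.call(rbind, lapply(keep, function(id)
    measure_region(seg$labels, id, cal0, image = bead_image)))
  calibration(length_scale = true_diameter_um / mean(meas$L_um),
              width_scale = true_diameter_um / mean(meas$W_um),
              pixel_size = pixel_size, psf_fwhm_px = 2.355 * sigma_px)
}

#' Counting setup for abundance estimation
#'
#' @param cells_per_field Integer cell counts on randomly selected fields.
#' @param field_area_mm2 Area of one counting field, mm^2 (default: a
#'   1300 x 1030 px field at 0.106 um/px).
#' @param filtration_area_mm2 Effective filtration area of the membrane,
#'   mm^2 (default 201.06, a 16 mm effective diameter).
#' @param volume_mL Sample volume filtered, mL.
#' @param replicate_slides Number of replicate slides counted.
#' @return An object of class `counting_setup`.
#' @export
counting_setup <- function(cells_per_field,
                           field_area_mm2 = 1300 * 1030 * 0.106^2 * 1e-6,
                           filtration_area_mm2 = 201.06,
                           volume_mL = 2, replicate_slides = 2) {
  stopifnot(length(cells_per_field) >= 1, all(cells_per_field >= 0),
            field_area_mm2 > 0, filtration_area_mm2 >= field_area_mm2)
  if (volume_mL <= 0) stop("volume filtered must be > 0")
  structure(list(cells_per_field = cells_per_field,
                 n_fields = length(cells_per_field),
                 field_area_mm2 = field_area_mm2,
                 filtration_area_mm2 = filtration_area_mm2,
                 volume_mL = volume_mL,
                 replicate_slides = replicate_slides),
            class = "counting_setup")
}

#' Abundance from field counts
#'
#' `PA = mean(cells per field) x (filtration area / field area) / volume`,
#' with the standard error propagated from the field-count standard
#' deviation. Warns (does not fail) below the recommended 20 fields or 2
#' replicate slides.
#'
#' @param setup A [counting_setup()].
#' @return List with `PA` (cells/mL), `SE` (cells/mL) and `n_fields`.
#' @export
abundance_from_counts <- function(setup) {
  stopifnot(inherits(setup, "counting_setup"))
  if (setup$n_fields < 20)
    warning("fewer than 20 counting fields (", setup$n_fields, ")")
  if (setup$replicate_slides < 2)
    warning("fewer than 2 replicate slides")
  factor <- setup$filtration_area_mm2 / setup$field_area_mm2 / setup$volume_mL
  counts <- setup$cells_per_field
  se_mean <- if (length(counts) > 1) stats::sd(counts) / sqrt(length(counts)) else 0
  list(PA = mean(counts) * factor, SE = se_mean * factor,
       n_fields = setup$n_fields)
}
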