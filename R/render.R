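#' Imaging field specification
#'
#' Geometry and photometry of a simulated epifluorescence field. Defaults
#' follow the acquisition setup of the survey: 1300 x 1030 px at
#' 0.106 um/px. Intensities are on a normalized [0, 1] scale (written to
#' 16-bit TIFF as value x 65535).
#'
#' @param width_px,height_px Field size in pixels.
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian point-spread sigma, um (0 = no blur). The
#'   default 0.1 um corresponds to the diffraction scale of a 100x/1.30
#'   oil objective at blue emission (FWHM ~ 0.24 um).
#' @param background_level Mean background intensity.
#' @param background_noise_sd Gaussian noise sd (0 = noise free).
#' @param signal_level Peak cell intensity before blur.
#' @param border_margin Pixels kept free of cells along the field edge.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(width_px = 1300L, height_px = 1030L,
                       pixel_size = 0.106, psf_sigma = 0.1,
                       background_level = 0.05,
                       background_noise_sd = 0.03,
                       signal_level = 0.6, border_margin = 10L) {
  stopifnot(width_px > 0, height_px > 0, pixel_size > 0, psf_sigma >= 0,
            background_noise_sd >= 0, signal_level > 0, border_margin >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 signal_level = signal_level,
                 border_margin = as.integer(border_margin)),
            class = "field_spec")
}

# Centerline polyline of one cell in local um coordinates (centered on the
# path midpoint, initial tangent along +x). Straight cells: a segment of
# length L - W; curved/C: one circular arc with the given total turning;
# S: two opposite-signed arcs of half the turning each. Returns an n x 2
# matrix (possibly a single point for round cells).
cell_centerline <- function(L, W, curvature_class = "straight",
                            turning_deg = 0, step_um = 0.05) {
  len <- max(L - W, 0)
  if (len < 1e-9) return(matrix(0, 1, 2))
  n <- max(ceiling(len / step_um), 8L)
  s <- seq(0, len, length.out = n + 1L)
  ds <- diff(s)
  if (curvature_class == "straight" || turning_deg <= 0) {
    pts <- cbind(s, 0)
  } else {
    kap0 <- (turning_deg * pi / 180) / len
    kap <- if (curvature_class == "S") {
      ifelse(s[-length(s)] < len / 2, kap0, -kap0)   # sign flips midway
    } else rep(kap0, n)
    theta <- c(0, cumsum(kap * ds))
    x <- c(0, cumsum(cos(theta[-length(theta)]) * ds))
    y <- c(0, cumsum(sin(theta[-length(theta)]) * ds))
    pts <- cbind(x, y)
  }
  sweep(pts, 2, colMeans(pts))   # center on the path midpoint
}

# Rotate (about origin) and translate a point matrix.
.transform_pts <- function(pts, angle, center) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(pts %*% t(R), 2, center, "+")
}

# Support polyline in px: centerline extended by W/2 along the end
# tangents so that the hemispherical caps are covered by the point set.
.support_polyline <- function(pts_px, r_px) {
  if (nrow(pts_px) == 1L) return(pts_px)
  t1 <- pts_px[1, ] - pts_px[2, ]
  t2 <- pts_px[nrow(pts_px), ] - pts_px[nrow(pts_px) - 1, ]
  t1 <- t1 / sqrt(sum(t1^2)); t2 <- t2 / sqrt(sum(t2^2))
  rbind(pts_px[1, ] + r_px * t1, pts_px,
        pts_px[nrow(pts_px), ] + r_px * t2)
}

# Min distance from each query point (m x 2) to a polyline (n x 2).
.dist_to_polyline <- function(q, pts) {
  if (nrow(pts) == 1L) {
    return(sqrt((q[, 1] - pts[1, 1])^2 + (q[, 2] - pts[1, 2])^2))
  }
  d <- rep(Inf, nrow(q))
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    v <- p1 - p0; vv <- sum(v^2)
    if (vv < 1e-12) next
    t <- ((q[, 1] - p0[1]) * v[1] + (q[, 2] - p0[2]) * v[2]) / vv
    t <- pmin(pmax(t, 0), 1)
    dx <- q[, 1] - (p0[1] + t * v[1]); dy <- q[, 2] - (p0[2] + t * v[2])
    d <- pmin(d, sqrt(dx * dx + dy * dy))
  }
  d
}

#' Place cells in a field without overlap
#'
#' Assigns a random position and orientation to each cell by rejection
#' sampling: cells must lie fully inside the field minus the border
#' margin, and capsule outlines of distinct cells must be separated by at
#' least `gap_px` pixels.
#'
#' @param cells Data frame from [sample_cells()] (columns `L_um`, `W_um`,
#'   `curvature_class`, `arc_turning_deg`).
#' @param field A [field_spec()].
#' @param seed Integer seed.
#' @param gap_px Minimum clearance between cell outlines, px (default 5:
#'   beyond that distance the overlapping point-spread halos of two
#'   bright neighbours stay below the detection threshold).
#' @param max_attempts Placement attempts per cell before failing.
#' @return `cells` with added columns `centroid_x_px`, `centroid_y_px`,
#'   `orientation_rad`, plus a `centerlines` attribute (list of px
#'   polylines used by the renderer).
#' @export
place_cells <- function(cells, field, seed = NULL, gap_px = 5,
                        max_attempts = 500L) {
  stopifnot(inherits(field, "field_spec"))
  n <- nrow(cells)
  px <- field$pixel_size
  with_seed(seed, {
    placed_pts <- matrix(numeric(0), 0, 2)
    placed_r <- numeric(0)
    centerlines <- vector("list", n)
    cx <- cy <- ang <- numeric(n)
    for (i in seq_len(n)) {
      local_um <- cell_centerline(cells$L_um[i], cells$W_um[i],
                                  cells$curvature_class[i],
                                  cells$arc_turning_deg[i])
      local_px <- local_um / px
      r_px <- cells$W_um[i] / 2 / px
      ext <- max(sqrt(rowSums(local_px^2))) + r_px + 1
      lo_x <- field$border_margin + ext + 1
      hi_x <- field$width_px - field$border_margin - ext
      lo_y <- field$border_margin + ext + 1
      hi_y <- field$height_px - field$border_margin - ext
      if (hi_x <= lo_x || hi_y <= lo_y)
        stop("field too small for cell ", i, " (extent ", round(ext), " px)")
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        cen <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
        th <- stats::runif(1, 0, 2 * pi)
        cand <- .transform_pts(local_px, th, cen)
        supp <- .support_polyline(cand, r_px)
        if (nrow(placed_pts)) {
          dmin <- min(.cross_min_dist(supp, placed_pts, placed_r) - r_px)
          if (dmin <= gap_px) next
        }
        ok <- TRUE
        cx[i] <- cen[1]; cy[i] <- cen[2]; ang[i] <- th
        centerlines[[i]] <- cand
        placed_pts <- rbind(placed_pts, supp)
        placed_r <- c(placed_r, rep(r_px, nrow(supp)))
        break
      }
      if (!ok)
        stop("could not place cell ", i, " after ", max_attempts,
             " attempts; field too crowded")
    }
    out <- cells
    out$centroid_x_px <- cx; out$centroid_y_px <- cy
    out$orientation_rad <- ang
    attr(out, "centerlines") <- centerlines
    out
  })
}

# For each query point, distance to nearest placed point minus that
# point's radius; returns the vector of adjusted distances.
.cross_min_dist <- function(q, pts, r) {
  out <- rep(Inf, nrow(q))
  for (j in seq_len(nrow(q))) {
    d <- sqrt((pts[, 1] - q[j, 1])^2 + (pts[, 2] - q[j, 2])^2) - r
    out[j] <- min(d)
  }
  out
}

#' Render a DAPI-like micrograph
#'
#' Rasterizes placed cells as bright capsules (straight cells) or
#' constant-width arcs (curved cells) on a dark background, convolves with
#' a Gaussian point-spread function, and adds background and Gaussian
#' noise. Pixel intensity within a cell ramps linearly over one pixel at
#' the boundary (antialiasing), so sub-pixel geometry is preserved.
#'
#' @param cells Data frame from [sample_cells()]; if placement columns are
#'   absent, [place_cells()] is applied first.
#' @param field A [field_spec()].
#' @param seed Integer seed (placement and noise).
#' @return List with `image` (width x height matrix, values in [0, 1]) and
#'   `truth` (the placed cell table).
#' @export
render_micrograph <- function(cells, field = field_spec(), seed = NULL) {
  stopifnot(inherits(field, "field_spec"))
  with_seed(seed, {
    if (nrow(cells) > 0 && is.null(cells$centroid_x_px))
      cells <- place_cells(cells, field)
    img <- matrix(0, field$width_px, field$height_px)
    centerlines <- attr(cells, "centerlines")
    px <- field$pixel_size
    for (i in seq_len(nrow(cells))) {
      pts <- centerlines[[i]]
      if (is.null(pts)) {   # rebuild from stored placement
        loc <- cell_centerline(cells$L_um[i], cells$W_um[i],
                               cells$curvature_class[i],
                               cells$arc_turning_deg[i]) / px
        pts <- .transform_pts(loc, cells$orientation_rad[i],
                              c(cells$centroid_x_px[i], cells$centroid_y_px[i]))
      }
      r_px <- cells$W_um[i] / 2 / px
      x0 <- max(floor(min(pts[, 1]) - r_px - 2), 1)
      x1 <- min(ceiling(max(pts[, 1]) + r_px + 2), field$width_px)
      y0 <- max(floor(min(pts[, 2]) - r_px - 2), 1)
      y1 <- min(ceiling(max(pts[, 2]) + r_px + 2), field$height_px)
      gx <- x0:x1; gy <- y0:y1
      q <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
      d <- .dist_to_polyline(q, pts)
      cov <- pmin(pmax(r_px - d + 0.5, 0), 1)
      patch <- matrix(cov, length(gx), length(gy))
      img[gx, gy] <- pmax(img[gx, gy], field$signal_level * patch)
    }
    if (field$psf_sigma > 0) {
      sig_px <- field$psf_sigma / px
      img <- as.matrix(EBImage::gblur(img, sigma = sig_px))
    }
    img <- img + field$background_level
    if (field$background_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       field$background_noise_sd),
                          nrow(img), ncol(img))
    img <- pmin(pmax(img, 0), 1)
    list(image = img, truth = cells)
  })
}

#' Render a calibration bead field
#'
#' Monosized fluorescent latex beads (default diameter 2.13 um) rendered
#' as discs under the same optics as the cell fields; used by
#' [calibrate_with_beads()].
#'
#' @param n_beads Number of beads.
#' @param diameter_um True bead diameter, um.
#' @param field A [field_spec()].
#' @param seed Integer seed.
#' @return As [render_micrograph()].
#' @export
render_bead_field <- function(n_beads = 20, diameter_um = 2.13,
                              field = field_spec(), seed = NULL) {
  beads <- data.frame(
    cell_id = seq_len(n_beads), cruise = "beads", morphotype = "cocci",
    L_um = diameter_um, W_um = diameter_um,
    curvature_class = "straight", arc_turning_deg = 0,
    stringsAsFactors = FALSE
  )
  render_micrograph(beads, field, seed)
}

#' Write a rendered image to 16-bit TIFF
#'
#' @param image Matrix in [0, 1] (width x height, as returned by
#'   [render_micrograph()]).
#' @param path Output file path.
#' @export
write_micrograph <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  # tiff expects row = y; transpose from (x, y) storage
  tiff::writeTIFF(t(image), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale micrograph (TIFF or PNG)
#'
#' @param path Image path.
#' @return Matrix in [0, 1], width x height orientation.
#' @export
read_micrograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF files")
    tiff::readTIFF(path)
  } else {
    as.matrix(EBImage::imageData(EBImage::channel(EBImage::readImage(path), "gray")))
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (ext %in% c("tif", "tiff")) t(m) else m
}
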