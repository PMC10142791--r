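#' Morphotype classes
#'
#' The seven operational cell-shape classes used throughout the package, in
#' canonical order: cocci, coccobacilli, rods, curved rods, vibrios
#' (C-shaped), spirillae (S-shaped) and filamentous forms.
#'
#' @return Character vector of the seven morphotype labels.
#' @export
morphotype_levels <- function() {
  c("cocci", "coccobacilli", "rods", "curved_rods",
    "vibrios", "spirillae", "filamentous")
}

#' Curvature classes
#'
#' Centerline curvature descriptors: `straight`, `curved` (single gentle
#' arc), `C` (single strong arc) and `S` (two opposite-signed arcs).
#'
#' @return Character vector of the four curvature labels.
#' @export
curvature_levels <- function() c("straight", "curved", "C", "S")

# canonical curvature class generated for each morphotype
.morphotype_curvature <- c(
  cocci = "straight", coccobacilli = "straight", rods = "straight",
  curved_rods = "curved", vibrios = "C", spirillae = "S",
  filamentous = "straight"
)

#' Construct a per-morphotype dimension profile
#'
#' Holds the generative parameters of one morphotype in one cruise: the
#' mean, standard deviation and observed range of cell length L and width W
#' (micrometres). The moments are interpreted as moments of the *observed*
#' (range-limited) cells; [sample_cells()] matches a truncated lognormal to
#' them.
#'
#' @param morphotype One of [morphotype_levels()].
#' @param L_mean,L_sd,L_min,L_max Length moments and bounds, um.
#' @param W_mean,W_sd,W_min,W_max Width moments and bounds, um. For cocci
#'   the width equals the length (single diameter measure) and these
#'   default to the L values.
#' @param curvature_class Curvature label; defaults to the canonical class
#'   for the morphotype.
#' @return An object of class `morphotype_profile`.
#' @export
morphotype_profile <- function(morphotype, L_mean, L_sd, L_min, L_max,
                               W_mean = L_mean, W_sd = L_sd,
                               W_min = L_min, W_max = L_max,
                               curvature_class = .morphotype_curvature[[morphotype]]) {
  morphotype <- match.arg(morphotype, morphotype_levels())
  stopifnot(
    L_min > 0, L_min <= L_mean, L_mean <= L_max,
    W_min > 0, W_min <= W_mean, W_mean <= W_max,
    W_mean <= L_mean, L_sd >= 0, W_sd >= 0
  )
  structure(
    list(morphotype = morphotype,
         L_mean = L_mean, L_sd = L_sd, L_min = L_min, L_max = L_max,
         W_mean = W_mean, W_sd = W_sd, W_min = W_min, W_max = W_max,
         curvature_class = match.arg(curvature_class, curvature_levels())),
    class = "morphotype_profile"
  )
}

#' Construct a community profile
#'
#' Bundles the per-morphotype dimension profiles of one cruise with a
#' morphotype composition and a cell density prior.
#'
#' @param cruise_label Cruise name, e.g. `"BANSIC-2012"`.
#' @param composition Named numeric vector of morphotype fractions; must be
#'   non-negative and sum to 1. Morphotypes not observed in the cruise get
#'   fraction 0.
#' @param profiles Named list of [morphotype_profile()] objects covering at
#'   least every morphotype with positive fraction.
#' @param density Cells per mL (order-of-magnitude prior; default `1e6`).
#' @param n_measured Number of cells measured in the original survey for
#'   this cruise (used by the analysis drivers to size simulations).
#' @return An object of class `community_profile`.
#' @export
community_profile <- function(cruise_label, composition, profiles,
                              density = 1e6, n_measured = NA_integer_) {
  stopifnot(is.character(cruise_label), length(cruise_label) == 1L,
            density > 0, all(composition >= 0))
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  present <- names(composition)[composition > 0]
  missing <- setdiff(present, names(profiles))
  if (length(missing))
    stop("no dimension profile for morphotype(s): ",
         paste(missing, collapse = ", "))
  structure(
    list(cruise_label = cruise_label, composition = composition,
         profiles = profiles, density = density, n_measured = n_measured),
    class = "community_profile"
  )
}

#' @export
print.community_profile <- function(x, ...) {
  cat("<community_profile> ", x$cruise_label,
      " (", sum(x$composition > 0), " morphotypes, density ",
      format(x$density, scientific = TRUE), " cells/mL)\n", sep = "")
  comp <- x$composition[x$composition > 0]
  cat("  composition:", paste(sprintf("%s %.3f", names(comp), comp),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Built-in cruise community profiles
#'
#' Per-morphotype length/width means, standard deviations and observed
#' ranges for the three Sicily Channel cruises (BANSIC-2012 in July 2012,
#' NOVESAR-2013 in January 2013, BANSIC-2013 in July 2013), as measured on
#' ~8800 DAPI-stained cells. Morphotypes not detected in a cruise (e.g.
#' vibrios and spirillae in winter) carry fraction 0 and no dimension
#' profile.
#'
#' The morphotype *composition* of each cruise was not reported as numbers;
#' the defaults here are chosen so that cocci dominate and the morphological
#' index (rods:cocci ratio) matches the reported per-cruise values
#' (0.5, 0.9 and 0.44), with the remaining mass split among the other
#' present morphotypes. Override `composition` on the returned objects for
#' other scenarios.
#'
#' The BANSIC-2013 curved-rod width bounds are corrupted in the source
#' table (they duplicate the length bounds and exclude the width mean);
#' they are replaced by the cruise's total-cells width minimum (0.11 um)
#' and its rods' width maximum (0.65 um).
#'
#' @return Named list of three [community_profile()] objects keyed by
#'   cruise label.
#' @export
builtin_cruise_profiles <- function() {
  mp <- morphotype_profile

  ban12 <- list(
    vibrios      = mp("vibrios",      2.52, 0.57, 1.46, 4.06, 0.40, 0.11, 0.21, 0.64),
    spirillae    = mp("spirillae",    2.90, 0.69, 1.39, 4.54, 0.35, 0.09, 0.21, 0.64),
    coccobacilli = mp("coccobacilli", 0.85, 0.19, 0.53, 1.68, 0.58, 0.12, 0.32, 1.05),
    cocci        = mp("cocci",        0.51, 0.15, 0.32, 1.38),
    rods         = mp("rods",         1.68, 0.66, 0.64, 6.34, 0.41, 0.10, 0.21, 0.76),
    curved_rods  = mp("curved_rods",  1.99, 0.55, 1.07, 5.08, 0.38, 0.12, 0.21, 0.81)
  )
  nov13 <- list(
    coccobacilli = mp("coccobacilli", 0.62, 0.17, 0.42, 1.70, 0.42, 0.08, 0.32, 0.95),
    cocci        = mp("cocci",        0.40, 0.09, 0.32, 0.95),
    rods         = mp("rods",         1.01, 0.36, 0.42, 3.23, 0.32, 0.08, 0.15, 0.65),
    curved_rods  = mp("curved_rods",  1.38, 0.33, 0.74, 2.24, 0.26, 0.07, 0.15, 0.44)
  )
  ban13 <- list(
    vibrios      = mp("vibrios",      2.23, 0.75, 1.14, 6.37, 0.36, 0.11, 0.15, 0.65),
    spirillae    = mp("spirillae",    2.35, 0.73, 0.71, 3.94, 0.34, 0.09, 0.15, 0.53),
    coccobacilli = mp("coccobacilli", 0.69, 0.18, 0.28, 2.19, 0.46, 0.14, 0.21, 1.83),
    cocci        = mp("cocci",        0.48, 0.14, 0.30, 1.27),
    # printed W bounds duplicate the L bounds; see help page
    rods         = mp("rods",         1.17, 0.43, 0.55, 2.86, 0.37, 0.11, 0.11, 0.65),
    curved_rods  = mp("curved_rods",  1.56, 0.50, 0.53, 3.59, 0.35, 0.10, 0.11, 0.65),
    filamentous  = mp("filamentous",  3.37, 1.54, 2.04, 6.41, 0.24, 0.012, 0.21, 0.24)
  )

  zero <- stats::setNames(numeric(7), morphotype_levels())
  comp12 <- zero
  comp12[c("cocci", "rods", "coccobacilli", "curved_rods", "vibrios", "spirillae")] <-
    c(0.40, 0.20, 0.24, 0.10, 0.04, 0.02)          # rods:cocci = 0.50
  comp13n <- zero
  comp13n[c("cocci", "rods", "coccobacilli", "curved_rods")] <-
    c(0.420, 0.378, 0.152, 0.050)                  # rods:cocci = 0.90
  comp13b <- zero
  comp13b[c("cocci", "rods", "coccobacilli", "curved_rods",
            "vibrios", "spirillae", "filamentous")] <-
    c(0.40, 0.176, 0.24, 0.10, 0.05, 0.024, 0.01)  # rods:cocci = 0.44

  list(
    "BANSIC-2012"  = community_profile("BANSIC-2012",  comp12,  ban12,
                                       n_measured = 4573L),
    "NOVESAR-2013" = community_profile("NOVESAR-2013", comp13n, nov13,
                                       n_measured = 1344L),
    "BANSIC-2013"  = community_profile("BANSIC-2013",  comp13b, ban13,
                                       n_measured = 2852L)
  )
}

# Environmental covariate profiles per cruise: mean, sd, min, max
# (T degC; S; DO mg/L; DEN kg/m3; FLUO ug/L; NO3, PO4, SiO4 umol/L).
.env_profiles <- function() {
  v <- function(mean, sd, min, max) c(mean = mean, sd = sd, min = min, max = max)
  list(
    "BANSIC-2012" = list(
      T    = v(18.20, 4.40, 14.80, 26.90),
      S    = v(38.30, 0.30, 37.30, 38.70),
      DO   = v(7.30, 0.60, 6.30, 8.10),
      DEN  = v(27.70, 1.29, 25.20, 28.80),
      FLUO = v(0.13, 0.11, 0.02, 0.39),
      NO3  = v(0.45, 0.37, 0.13, 1.62),
      PO4  = v(0.018, 0.020, 0.001, 0.070),
      SiO4 = v(0.85, 0.36, 0.20, 1.58)
    ),
    "NOVESAR-2013" = list(
      T    = v(14.90, 0.08, 14.80, 15.10),
      S    = v(38.40, 0.25, 38.00, 38.80),
      DO   = v(7.70, 0.38, 6.90, 8.20),
      DEN  = v(28.60, 0.18, 28.40, 28.90),
      FLUO = v(0.24, 0.12, 0.04, 0.38),
      NO3  = v(1.26, 0.90, 0.15, 3.12),
      PO4  = v(0.057, 0.042, 0.023, 0.127),
      SiO4 = v(1.22, 0.37, 0.74, 1.952)
    ),
    "BANSIC-2013" = list(
      T    = v(19.65, 3.75, 14.43, 24.58),
      S    = v(38.10, 0.42, 37.56, 38.71),
      DO   = v(7.64, 0.46, 7.04, 8.25),
      DEN  = v(27.08, 0.99, 25.50, 28.67),
      FLUO = v(0.07, 0.09, 0.01, 8.25),
      NO3  = v(0.38, 0.62, 0.03, 2.43),
      PO4  = v(0.02, 0.00, 0.02, 0.02),
      SiO4 = v(0.81, 0.69, 0.32, 3.18)
    )
  )
}
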