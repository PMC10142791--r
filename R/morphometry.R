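#' Classify a cell into its operational morphotype
#'
#' Applies the operational shape rules used for DAPI-stained
#' prokaryoplankton, in a fixed decision order:
#'
#' 1. length L > 4 um: `filamentous` (strict; 4.00 exactly is not);
#' 2. S-shaped centerline: `spirillae`;
#' 3. C-shaped centerline: `vibrios`;
#' 4. gently curved centerline: `curved_rods`;
#' 5. L >= 2 W ("length at least two times the width"): `rods`;
#' 6. L - W < 0.10 um ("differ by less than 0.10 um"): `cocci`
#'    (a difference of exactly 0.10 um is not cocci);
#' 7. otherwise: `coccobacilli`.
#'
#' The filament test precedes the curvature tests, so a > 4 um curved cell
#' is filamentous. Every valid input maps to exactly one class.
#'
#' @param L,W Length and width, um; must satisfy `L >= W > 0`.
#' @param curvature_class One of [curvature_levels()].
#' @param filament_min_L Filament length threshold, um (default 4.0).
#' @param cocci_max_diff Maximum L - W difference for cocci, um
#'   (default 0.10).
#' @param rod_aspect Minimum L / W ratio for rods (default 2).
#' @return Morphotype label (scalar; see [classify_morphotype_vec()] for
#'   the vectorized version).
#' @export
classify_morphotype <- function(L, W, curvature_class = "straight",
                                filament_min_L = 4.0,
                                cocci_max_diff = 0.10,
                                rod_aspect = 2.0) {
  stopifnot(length(L) == 1L, length(W) == 1L)
  if (!is.finite(L) || !is.finite(W) || W <= 0 || L < W)
    stop("invalid cell dimensions: need L >= W > 0")
  classify_morphotype_vec(L, W, curvature_class,
                          filament_min_L, cocci_max_diff, rod_aspect)
}

#' Vectorized morphotype classification
#'
#' @inheritParams classify_morphotype
#' @return Character vector of morphotype labels.
#' @seealso [classify_morphotype()] for the rule set.
#' @export
classify_morphotype_vec <- function(L, W, curvature_class = "straight",
                                    filament_min_L = 4.0,
                                    cocci_max_diff = 0.10,
                                    rod_aspect = 2.0) {
  n <- max(length(L), length(W), length(curvature_class))
  L <- rep_len(L, n); W <- rep_len(W, n)
  curvature_class <- rep_len(curvature_class, n)
  if (any(!is.finite(L) | !is.finite(W) | W <= 0 | L < W))
    stop("invalid cell dimensions: need L >= W > 0")
  if (!all(curvature_class %in% curvature_levels()))
    stop("unknown curvature class")
  # comparisons carry a 1e-9 um guard so that printed boundary values
  # (L - W = 0.10, L = 2W, L = 4.0) resolve as documented despite
  # floating-point subtraction
  out <- rep("coccobacilli", n)
  out[(L - W) - cocci_max_diff < -1e-9] <- "cocci"
  out[L - rod_aspect * W > -1e-9] <- "rods"
  out[curvature_class == "curved"] <- "curved_rods"
  out[curvature_class == "C"] <- "vibrios"
  out[curvature_class == "S"] <- "spirillae"
  out[L - filament_min_L > 1e-9] <- "filamentous"
  out
}

#' Cell biovolume from two linear dimensions
#'
#' Volume of a cylinder of width W capped by two hemispheres:
#' `V = (pi/4) W^2 (L - W/3)` (um^3). When `L = W` this reduces exactly to
#' the sphere `(pi/6) L^3`, consistent with treating coccoid cells as a
#' single diameter measure.
#'
#' @param L,W Length and width, um; vectorized, `L >= W > 0`.
#' @return Volume(s), um^3.
#' @export
cell_volume <- function(L, W) {
  if (any(!is.finite(L) | !is.finite(W) | W <= 0 | L < W))
    stop("cell_volume requires L >= W > 0")
  (pi / 4) * W^2 * (L - W / 3)
}

#' Volume-to-carbon conversion model
#'
#' Either a flat factor (`CCC = factor * V`, default 350 fg C um^-3) or an
#' allometric law (`CCC = a * V^b`, defaults a = 218 fg C, b = 0.86).
#'
#' @param kind `"flat"` or `"allometric"`.
#' @param flat_factor fg C per um^3 (flat model).
#' @param allo_a,allo_b Allometric coefficient (fg C) and exponent.
#' @return An object of class `carbon_model`.
#' @export
carbon_model <- function(kind = c("flat", "allometric"),
                         flat_factor = 350, allo_a = 218, allo_b = 0.86) {
  kind <- match.arg(kind)
  stopifnot(flat_factor > 0, allo_a > 0, allo_b > 0)
  structure(list(kind = kind, flat_factor = flat_factor,
                 allo_a = allo_a, allo_b = allo_b),
            class = "carbon_model")
}

#' Cell carbon content from biovolume
#'
#' @param V Biovolume(s), um^3, strictly positive.
#' @param model A [carbon_model()] (default flat, 350 fg C um^-3).
#' @return Carbon content(s), fg C per cell; strictly increasing in V.
#' @export
cell_carbon <- function(V, model = carbon_model()) {
  stopifnot(inherits(model, "carbon_model"))
  if (any(!is.finite(V) | V <= 0)) stop("cell_carbon requires V > 0")
  switch(model$kind,
         flat = model$flat_factor * V,
         allometric = model$allo_a * V^model$allo_b)
}

#' Prokaryotic biomass from abundance and per-cell carbon
#'
#' `PB = PA * mean(CCC) * 1e-6`, converting fg C/mL to ug C/L
#' (x 1e3 mL/L, x 1e-9 ug/fg).
#'
#' @param PA Prokaryotic abundance, cells/mL (>= 0).
#' @param CCC_values Per-cell carbon contents, fg C; must be non-empty when
#'   `PA > 0`.
#' @return Biomass, ug C per litre.
#' @export
sample_biomass <- function(PA, CCC_values) {
  stopifnot(length(PA) == 1L, is.finite(PA), PA >= 0)
  if (PA == 0) return(0)
  if (length(CCC_values) == 0) stop("CCC_values is empty while PA > 0")
  PA * mean(CCC_values) * 1e-6
}

#' Morphological index (rods : cocci)
#'
#' `M = %rods / %cocci`; the percentages share a denominator, so M is the
#' ratio of the two counts. Undefined (NA) when no cocci were counted.
#'
#' @param counts Named numeric vector or list of morphotype counts
#'   (must contain `rods` and `cocci` entries; absent = 0).
#' @return M, unitless; `NA` if the cocci count is zero.
#' @export
morphological_index <- function(counts) {
  counts <- unlist(counts)
  rods <- if ("rods" %in% names(counts)) counts[["rods"]] else 0
  cocci <- if ("cocci" %in% names(counts)) counts[["cocci"]] else 0
  if (is.na(cocci) || cocci <= 0) return(NA_real_)
  rods / cocci
}

#' Size-class spectrum
#'
#' Bins positive values into the survey's size classes and returns the
#' fraction in each class. The `volume` scheme uses 0.03-um^3-wide classes
#' from 0.02 to 0.20 um^3 plus an open top class (`[0, 0.02)`,
#' `[0.02, 0.05)`, ..., `[0.17, 0.20)`, `[0.20, Inf)`); the `length` scheme
#' uses 0.4-um-wide classes from 0.
#'
#' @param values Positive numeric vector (um^3 or um).
#' @param scheme `"volume"` or `"length"`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
size_class_histogram <- function(values, scheme = c("volume", "length")) {
  scheme <- match.arg(scheme)
  if (length(values) == 0) stop("empty input")
  stopifnot(all(is.finite(values) & values > 0))
  if (scheme == "volume") {
    edges <- c(0, seq(0.02, 0.20, by = 0.03), Inf)
  } else {
    edges <- c(seq(0, max(values) + 0.4, by = 0.4))
    if (edges[length(edges)] <= max(values)) edges <- c(edges, Inf)
  }
  labs <- paste0("[", format(edges[-length(edges)], trim = TRUE), ",",
                 format(edges[-1], trim = TRUE), ")")
  h <- table(cut(values, breaks = edges, right = FALSE, labels = labs))
  frac <- as.numeric(h) / length(values)
  stats::setNames(frac, labs)
}

#' Per-sample summary of prokaryoplankton traits
#'
#' Combines a per-cell trait table (columns `morphotype`, `VOL_um3`,
#' `CCC_fg`) with an abundance estimate into the per-sample summary:
#' abundance PA, mean/sd biovolume, mean carbon content, biomass PB,
#' morphotype counts and fractions, morphological index M, Shannon
#' diversity H' over morphotype counts, and the volume size-class spectrum.
#'
#' @param traits Data frame of per-cell traits.
#' @param PA Prokaryotic abundance, cells/mL.
#' @param shannon_base Logarithm base for H' (default 2, bits).
#' @return A one-row data frame; morphotype fractions appear as
#'   `frac_<morphotype>` columns and size classes as `volclass_<i>` columns.
#' @export
summarize_sample <- function(traits, PA, shannon_base = 2) {
  stopifnot(all(c("morphotype", "VOL_um3", "CCC_fg") %in% names(traits)),
            nrow(traits) > 0)
  counts <- table(factor(traits$morphotype, levels = morphotype_levels()))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  fracs <- counts / sum(counts)
  sc <- size_class_histogram(traits$VOL_um3, "volume")
  out <- data.frame(
    PA = PA,
    mean_VOL = mean(traits$VOL_um3),
    sd_VOL = stats::sd(traits$VOL_um3),
    mean_CCC = mean(traits$CCC_fg),
    PB = sample_biomass(PA, traits$CCC_fg),
    M = morphological_index(counts),
    H_prime = shannon_index(counts, base = shannon_base)
  )
  for (m in names(fracs)) out[[paste0("frac_", m)]] <- fracs[[m]]
  for (i in seq_along(sc)) out[[paste0("volclass_", i)]] <- sc[[i]]
  out
}
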