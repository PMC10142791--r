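.cell_table_cols <- c("cell_id", "cruise", "station", "depth_m",
                      "morphotype", "L_um", "W_um", "curvature_class")

#' Write a per-cell table with provenance header
#'
#' Comma-separated, UTF-8, '.' decimal, mandatory header; provenance
#' metadata (`# key: value` lines) precedes the header.
#'
#' @param cells Data frame of cells.
#' @param path Output path.
#' @param meta Named list of provenance fields (seed, config hash, ...).
#' @export
write_cell_table <- function(cells, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  utils::write.csv(cells, con, row.names = FALSE)
  invisible(path)
}

#' Read and validate a per-cell table
#'
#' Schema-validated CSV reader for per-cell measurement tables (columns
#' `cell_id`, `cruise`, `station`, `depth_m`, `morphotype`, `L_um`,
#' `W_um`, `curvature_class`, dimensions in um). Rows with non-positive or
#' reversed dimensions (`W > L`) are rejected; their line numbers are
#' reported in a warning and attached as the `rejected_lines` attribute.
#'
#' @param path CSV path (lines starting with `#` are provenance metadata).
#' @return Validated data frame; attributes `meta` (named character) and
#'   `rejected_lines` (integer file line numbers).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines)
  meta <- character(0)
  if (length(meta_lines)) {
    kv <- sub("^#\\s*", "", lines[meta_lines])
    meta <- stats::setNames(sub("^[^:]+:\\s*", "", kv),
                            sub(":.*$", "", kv))
  }
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), meta_lines)],
                        stringsAsFactors = FALSE,
                        colClasses = c(station = "character",
                                       cruise = "character"))
  missing <- setdiff(.cell_table_cols, names(df))
  if (length(missing))
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("L_um", "W_um", "depth_m")) {
    if (!is.numeric(df[[col]]))
      stop("column ", col, " is not numeric")
    df[[col]] <- as.double(df[[col]])
  }
  header_line <- if (length(meta_lines)) max(meta_lines) + 1L else 1L
  bad <- !is.finite(df$L_um) | !is.finite(df$W_um) |
    df$W_um <= 0 | df$L_um < df$W_um
  rejected <- integer(0)
  if (any(bad)) {
    rejected <- header_line + which(bad)
    warning("rejected ", sum(bad), " row(s) with invalid dimensions ",
            "(file line(s) ", paste(rejected, collapse = ", "), ")")
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "meta") <- meta
  attr(df, "rejected_lines") <- rejected
  df
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown cruise labels are
#' rejected here, before any computation.
#'
#' @param cruises Cruise labels (subset of the built-in profiles, or of
#'   `profiles` when given).
#' @param n_cells Cells to simulate per cruise.
#' @param n_samples Station/depth samples per cruise (cells are split
#'   evenly among them).
#' @param seed Master seed; every stage derives its stream from it.
#' @param route `"direct"` (analyze the generated dimensions) or
#'   `"render"` (render micrographs, segment and measure them first).
#' @param n_fields_rendered Micrograph fields rendered per cruise on the
#'   render route.
#' @param field A [field_spec()].
#' @param carbon A [carbon_model()].
#' @param shannon_base Logarithm base for H'.
#' @param volume_mL Volume filtered per sample for the abundance counts.
#' @param profiles Optional named list of [community_profile()] objects
#'   replacing the built-ins.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cruises = names(builtin_cruise_profiles()),
                            n_cells = 2000, n_samples = 8, seed = 1L,
                            route = c("direct", "render"),
                            n_fields_rendered = 2L,
                            field = field_spec(),
                            carbon = carbon_model(),
                            shannon_base = 2,
                            volume_mL = 2,
                            profiles = NULL, out_dir = NULL) {
  route <- match.arg(route)
  profs <- profiles %||% builtin_cruise_profiles()
  unknown <- setdiff(cruises, names(profs))
  if (length(unknown))
    stop("unknown cruise(s): ", paste(unknown, collapse = ", "))
  stopifnot(n_cells > 0, n_samples >= 1,
            inherits(field, "field_spec"),
            inherits(carbon, "carbon_model"), volume_mL > 0)
  structure(list(cruises = cruises, n_cells = n_cells,
                 n_samples = n_samples, seed = as.integer(seed),
                 route = route, n_fields_rendered = n_fields_rendered,
                 field = field, carbon = carbon,
                 shannon_base = shannon_base, volume_mL = volume_mL,
                 profiles = profs, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads the scalar configuration keys (`cruises`, `n_cells`, `n_samples`,
#' `seed`, `route`, `shannon_base`, `volume_mL`, `out_dir`, and `field` /
#' `carbon` sub-maps matching the [field_spec()] / [carbon_model()]
#' arguments) and validates them through [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("cruises", "n_cells", "n_samples", "seed", "route",
                        "n_fields_rendered", "shannon_base", "volume_mL",
                        "out_dir"))]
  if (!is.null(y$field)) args$field <- do.call(field_spec, y$field)
  if (!is.null(y$carbon)) args$carbon <- do.call(carbon_model, y$carbon)
  do.call(pipeline_config, args)
}

# md5 of the serialized config (provenance stamp in every output); the
# output location does not alter the analysis, so it is excluded
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  config$out_dir <- NULL
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full morphometry pipeline
#'
#' Executes simulate -> (render -> measure | direct) -> classify ->
#' summarize -> statistics for each configured cruise. Cells are split
#' into per-station samples with matched environmental covariates;
#' abundance comes from simulated field counts at the cruise density. The
#' returned (and optionally written) artifacts are deterministic under the
#' configured seed.
#'
#' @param config A [pipeline_config()].
#' @return List with `cells` (per-cell traits), `summaries` (one row per
#'   sample), `env` (environmental records), `stats` (Kruskal-Wallis on
#'   VOL across cruises, per-cruise H' range, PCA of sample variables) and
#'   `meta` (seed, config hash, package version). If `config$out_dir` is
#'   set, writes `cells.csv`, `summary.csv` and `stats.json` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  meta <- list(package = "prokmorph",
               version = as.character(utils::packageVersion("prokmorph")),
               seed = config$seed, config_hash = hash)

  all_cells <- list(); all_sum <- list(); all_env <- list()
  for (ci in seq_along(config$cruises)) {
    cruise <- config$cruises[ci]
    prof <- config$profiles[[cruise]]
    seed_c <- config$seed + 1000L * ci
    cells <- sample_cells(prof, config$n_cells, seed = seed_c)

    if (config$route == "render") {
      cells <- .measure_via_render(cells, config, seed_c)
    }

    env <- sample_environment(cruise, config$n_samples, seed = seed_c + 1L)
    sample_id <- rep_len(seq_len(config$n_samples), nrow(cells))
    cells$station <- env$station[sample_id]
    cells$depth_m <- env$depth_m[sample_id]

    cells$morphotype_measured <- classify_morphotype_vec(
      cells$L_um, cells$W_um, cells$curvature_class)
    cells$VOL_um3 <- cell_volume(cells$L_um, cells$W_um)
    cells$CCC_fg <- cell_carbon(cells$VOL_um3, config$carbon)

    sums <- with_seed(seed_c + 2L, {
      lapply(seq_len(config$n_samples), function(s) {
        sub <- cells[sample_id == s, , drop = FALSE]
        if (!nrow(sub)) return(NULL)
        mean_count <- prof$density * config$volume_mL *
          .field_fraction(config$field)
        counts <- stats::rpois(20, mean_count)
        pa <- abundance_from_counts(
          counting_setup(counts, volume_mL = config$volume_mL))$PA
        tr <- data.frame(morphotype = sub$morphotype_measured,
                         VOL_um3 = sub$VOL_um3, CCC_fg = sub$CCC_fg)
        cbind(data.frame(cruise = cruise, station = env$station[s],
                         depth_m = env$depth_m[s],
                         stringsAsFactors = FALSE),
              summarize_sample(tr, pa, config$shannon_base))
      })
    })
    all_cells[[cruise]] <- cells
    all_sum[[cruise]] <- do.call(rbind, sums)
    all_env[[cruise]] <- env
  }
  cells <- do.call(rbind, all_cells); rownames(cells) <- NULL
  summaries <- do.call(rbind, all_sum); rownames(summaries) <- NULL
  env <- do.call(rbind, all_env); rownames(env) <- NULL

  stats_out <- list()
  if (length(config$cruises) >= 2) {
    groups <- split(cells$VOL_um3, cells$cruise)[config$cruises]
    kw <- kruskal_wallis(groups)
    stats_out$kruskal_wallis_VOL <- list(statistic = kw$statistic,
                                         p_value = kw$p_value, df = kw$df)
  }
  stats_out$shannon_by_cruise <- lapply(
    split(summaries$H_prime, summaries$cruise),
    function(h) list(min = min(h), max = max(h)))
  pca_vars <- c("PA", "PB", "mean_VOL", "T", "S", "DO", "FLUO",
                "NO3", "PO4", "SiO4", "depth_m")
  mat <- cbind(summaries[c("PA", "PB", "mean_VOL", "depth_m")],
               env[c("T", "S", "DO", "FLUO", "NO3", "PO4", "SiO4")])
  mat <- mat[, intersect(pca_vars, names(mat)), drop = FALSE]
  keep <- vapply(mat, function(v) stats::sd(v) > 0, TRUE)
  pca <- NULL
  if (nrow(mat) >= 3 && sum(keep) >= 2) {
    pca <- pca_ordination(mat[, keep, drop = FALSE])
    stats_out$pca <- list(
      variance_explained = as.list(pca$variance_explained[1:2]),
      variables = colnames(pca$loadings))
  }

  out <- list(cells = cells, summaries = summaries, env = env,
              stats = stats_out, pca = pca, meta = meta)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_table(cells, file.path(config$out_dir, "cells.csv"), meta)
    write_cell_table(summaries, file.path(config$out_dir, "summary.csv"), meta)
    jsonlite::write_json(c(meta, stats_out),
                         file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# fraction of the filtered sample deposited on one counting field
.field_fraction <- function(field) {
  field_area_mm2 <- field$width_px * field$height_px *
    (field$pixel_size * 1e-3)^2
  field_area_mm2 / 201.06
}

# render route: split cells over rendered fields, measure them with bead
# calibration, and return the measured dimensions in place of the truth
.measure_via_render <- function(cells, config, seed) {
  nf <- config$n_fields_rendered
  idx <- rep_len(seq_len(nf), nrow(cells))
  beads <- render_bead_field(20, field = config$field, seed = seed + 500L)
  calib <- calibrate_with_beads(beads$image,
                                pixel_size = config$field$pixel_size)
  out <- list()
  for (f in seq_len(nf)) {
    sub <- cells[idx == f, , drop = FALSE]
    ren <- render_micrograph(sub, config$field, seed = seed + 600L + f)
    meas <- measure_micrograph(ren$image, calib)
    matched <- match_measurements(ren$truth, meas)
    sub$L_um <- matched$L_um
    sub$W_um <- matched$W_um
    sub$curvature_class <- matched$curvature_class
    keep <- !is.na(sub$L_um)
    out[[f]] <- sub[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match measured regions to ground-truth cells by centroid
#'
#' Greedy nearest-centroid matching between a rendered truth table and
#' the measurement table of the same field.
#'
#' @param truth Placed truth table (from [render_micrograph()]).
#' @param measured Measurement table (from [measure_micrograph()]).
#' @param max_dist_px Maximum centroid distance for a match (default 15).
#' @return Data frame aligned with `truth` rows: measured `L_um`, `W_um`,
#'   `curvature_class` (NA where unmatched).
#' @export
match_measurements <- function(truth, measured, max_dist_px = 15) {
  n <- nrow(truth)
  out <- data.frame(L_um = rep(NA_real_, n), W_um = NA_real_,
                    curvature_class = NA_character_,
                    stringsAsFactors = FALSE)
  if (!nrow(measured)) return(out)
  used <- logical(nrow(measured))
  for (i in seq_len(n)) {
    d <- sqrt((measured$centroid_x_px - truth$centroid_x_px[i])^2 +
              (measured$centroid_y_px - truth$centroid_y_px[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= max_dist_px) {
      out$L_um[i] <- measured$L_um[j]
      out$W_um[i] <- measured$W_um[j]
      out$curvature_class[i] <- measured$curvature_class[j]
      used[j] <- TRUE
    }
  }
  out
}
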