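#' Shannon diversity index
#'
#' `H' = -sum p_i log_base(p_i)` over categories with positive count;
#' invariant to rescaling of the counts and bounded by `log_base(k)` with
#' equality at the uniform distribution. Computed through
#' [vegan::diversity()] and rebased.
#'
#' @param counts Named or unnamed non-negative counts (or abundances);
#'   must not be all zero.
#' @param base Logarithm base (default 2, i.e. bits).
#' @return H', a non-negative scalar.
#' @export
shannon_index <- function(counts, base = 2) {
  counts <- unlist(counts)
  stopifnot(all(is.finite(counts)), all(counts >= 0))
  if (sum(counts) <= 0) stop("all-zero counts")
  unname(vegan::diversity(counts, index = "shannon") / log(base))
}

#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric one-way comparison of two or more groups: tie-corrected
#' rank statistic H with a chi-square p-value on k - 1 degrees of freedom
#' (via [stats::kruskal.test()]).
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List of class `prok_stat` with `statistic`, `p_value`, `df`,
#'   `group_sizes` and `method`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(x, g)
  structure(
    list(statistic = unname(kt$statistic),
         p_value = min(max(kt$p.value, 0), 1),
         df = unname(kt$parameter),
         group_sizes = vapply(groups, length, 1L),
         method = "Kruskal-Wallis rank sum test"),
    class = "prok_stat"
  )
}

#' @export
print.prok_stat <- function(x, ...) {
  cat(x$method, ": H = ", format(x$statistic), ", df = ", x$df,
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' PCA ordination of (transformed) sample variables
#'
#' Principal component analysis of a samples-by-variables matrix after an
#' element-wise `log10(x + 1)` transform, as used for mixed-unit
#' microbiological and environmental variables. By default the correlation
#' matrix is used (`standardize = TRUE`). Rows with missing values are
#' dropped with a warning. Component signs are fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param x Numeric matrix or data frame, samples in rows (>= 3), variables
#'   in columns (>= 2).
#' @param transform `"log10p1"` (default) or `"none"`.
#' @param standardize Scale variables to unit variance (default TRUE).
#' @return List of class `prok_pca` with `loadings` (variables x
#'   components), `scores` (samples x components), `variance_explained`
#'   (percent per component, summing to 100), `cos2` (squared variable-
#'   component correlations scaled as squared coordinates) and
#'   `dropped_rows`.
#' @export
pca_ordination <- function(x, transform = c("log10p1", "none"),
                           standardize = TRUE) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  keep <- stats::complete.cases(x)
  dropped <- which(!keep)
  if (length(dropped)) {
    warning("dropping ", length(dropped), " row(s) with missing values")
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 3 || ncol(x) < 2)
    stop("need >= 3 complete samples and >= 2 variables")
  if (transform == "log10p1") {
    if (any(x < 0)) stop("log10(x+1) transform requires non-negative data")
    x <- log10(x + 1)
  }
  if (standardize && any(apply(x, 2, stats::sd) == 0))
    stop("constant column under standardization")
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  # deterministic sign: largest |loading| positive per component
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, "*")
  sco <- sweep(p$x, 2, flip, "*")
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  coord <- sweep(rot, 2, p$sdev, "*")   # variable coordinates
  structure(
    list(loadings = rot, scores = sco,
         variance_explained = stats::setNames(ve, colnames(rot)),
         cos2 = coord^2, center = p$center, scale = p$scale,
         dropped_rows = dropped),
    class = "prok_pca"
  )
}

#' Distribution summary with kernel density
#'
#' Mean, sd, median and a Gaussian-kernel density estimate on a regular
#' grid (the empirical-distribution view used alongside group means in
#' bean-style plots). The density integrates to 1 within ~1% (trapezoid
#' rule on the returned grid).
#'
#' @param values Non-empty numeric vector.
#' @param n_grid Number of density grid points (default 512).
#' @return List with `mean`, `sd`, `median`, `n`, and `density`
#'   (data frame with `x`, `y`).
#' @export
distribution_summary <- function(values, n_grid = 512) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("empty input")
  if (length(values) == 1 || stats::sd(values) == 0) {
    bw <- max(abs(values[1]) * 0.01, 1e-3)
    d <- stats::density(values, bw = bw, n = n_grid)
  } else {
    d <- stats::density(values, n = n_grid)
  }
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0,
       median = stats::median(values),
       n = length(values),
       density = data.frame(x = d$x, y = d$y))
}

#' Virus-to-prokaryote ratio
#'
#' @param VA Virus-like particle abundance, particles/mL.
#' @param PA Prokaryotic abundance, cells/mL (> 0).
#' @return VPR = VA / PA.
#' @export
virus_prokaryote_ratio <- function(VA, PA) {
  stopifnot(is.finite(VA), VA >= 0)
  if (!is.finite(PA) || PA <= 0) stop("PA must be > 0")
  VA / PA
}
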