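# Shared fixtures and independent oracles for the test suite.

# small, fast imaging field for unit tests
test_field <- function(psf_sigma = 0.05, noise = 0, width = 300, height = 300) {
  field_spec(width_px = width, height_px = height,
             psf_sigma = psf_sigma,
             background_level = if (noise > 0) 0.05 else 0.02,
             background_noise_sd = noise)
}

# community profile restricted to a single morphotype
single_morphotype_profile <- function(cruise, morphotype) {
  p <- builtin_cruise_profiles()[[cruise]]
  p$composition[] <- 0
  p$composition[morphotype] <- 1
  p
}

# Independent brute-force implementation of the operational morphotype
# rules, written directly from the verbal definitions (kept deliberately
# separate from classify_morphotype): filaments are cells longer than
# 4 um; S- and C-shaped cells are spirillae and vibrios; gently curved
# cells are curved rods; cells at least twice as long as wide are rods;
# cells whose two dimensions differ by less than 0.10 um are cocci; the
# rest are coccobacilli.
# Dimensions are compared in integer thousandths of a micrometre so the
# printed boundary values are exact.
oracle_classify <- function(L, W, curv) {
  l <- round(L * 1000); w <- round(W * 1000)
  if (l > 4000) return("filamentous")
  if (curv == "S") return("spirillae")
  if (curv == "C") return("vibrios")
  if (curv == "curved") return("curved_rods")
  if (l >= 2 * w) return("rods")
  if ((l - w) < 100) return("cocci")
  "coccobacilli"
}

# Independent Kruskal-Wallis statistic from the rank-sum definition with
# tie correction (no call to kruskal.test).
oracle_kw_statistic <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, 1L)
  idx <- rep(seq_along(groups), sizes)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation distribution of the KW statistic for tiny samples:
# every assignment of the observations to groups of the given sizes.
oracle_kw_permutation <- function(groups) {
  x <- unlist(groups)
  sizes <- vapply(groups, length, 1L)
  n <- length(x)
  stopifnot(n <= 9)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  P <- perms(seq_len(n))
  stats <- apply(P, 1, function(ord) {
    xs <- x[ord]
    g <- split(xs, rep(seq_along(sizes), sizes))
    oracle_kw_statistic(g)
  })
  stats
}
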