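test_that("shannon index matches hand values and its bounds", {
  expect_equal(shannon_index(rep(10, 7)), log2(7), tolerance = 1e-12)
  expect_equal(shannon_index(c(a = 5)), 0)
  expect_equal(shannon_index(c(4, 4, 8)), 1.5)
  # bounded by log2(k), equality only at uniformity; invariant to scale
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    cts <- rgamma(k, 2)
    h <- shannon_index(cts)
    expect_lte(h, log2(k) + 1e-12)
    expect_equal(h, shannon_index(cts * 1000), tolerance = 1e-12)
  }
  expect_lt(shannon_index(c(1, 1, 50)), log2(3))
  expect_equal(shannon_index(rep(3, 5), base = exp(1)), log(5),
               tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)))
})

test_that("kruskal-wallis matches hand computation and degenerate cases", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(kw$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kw$df, 1)
  expect_error(kruskal_wallis(list(1:3)))
  expect_error(kruskal_wallis(list(1:3, numeric(0))))
})

test_that("kruskal-wallis equals the exact-rank oracle on small samples", {
  set.seed(7)
  for (i in 1:15) {
    sizes <- sample(2:4, sample(2:3, 1), replace = TRUE)
    while (sum(sizes) > 9) sizes <- sizes[-1]
    if (length(sizes) < 2) next
    vals <- sample(1:6, sum(sizes), replace = TRUE)  # ties likely
    groups <- split(vals, rep(seq_along(sizes), sizes))
    expect_equal(kruskal_wallis(groups)$statistic,
                 oracle_kw_statistic(groups), tolerance = 1e-10)
  }
  # observed statistic sits inside the exact permutation distribution
  groups <- list(c(3, 9), c(1, 2), c(7, 8))
  perm <- oracle_kw_permutation(groups)
  obs <- kruskal_wallis(groups)$statistic
  expect_true(any(abs(perm - obs) < 1e-10))
  expect_gte(mean(perm >= obs - 1e-12), 0)
})

test_that("statistics are invariant to row order", {
  set.seed(3)
  g <- list(rnorm(20), rnorm(20, 1), rnorm(20, 2))
  shuffled <- lapply(g, sample)
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(shuffled)$statistic, tolerance = 1e-12)
  cts <- c(a = 3, b = 9, c = 1)
  expect_equal(shannon_index(cts), shannon_index(rev(cts)))
})

test_that("pca ordination decomposes and reconstructs the data", {
  set.seed(21)
  x <- matrix(rexp(12 * 5), 12, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  p <- pca_ordination(x)
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-9)
  expect_true(all(p$variance_explained >= 0))
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores x loadings' reproduces the transformed centered scaled matrix
  lx <- log10(x + 1)
  cs <- scale(lx, center = TRUE, scale = TRUE)
  expect_equal(p$scores %*% t(p$loadings), unclass(cs), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicated samples get identical scores
  x2 <- rbind(x, x[1, ])
  p2 <- pca_ordination(x2)
  expect_equal(p2$scores[1, ], p2$scores[nrow(x2), ], tolerance = 1e-10)
})

test_that("pca handles rank deficiency, missingness and degeneracy", {
  # perfectly correlated pair -> first component carries everything
  x <- cbind(a = 1:10, b = 2 * (1:10))
  p <- pca_ordination(x, transform = "none")
  expect_equal(unname(p$variance_explained[1]), 100, tolerance = 1e-9)
  xm <- matrix(runif(20), 5, 4)
  xm[2, 3] <- NA
  expect_warning(pm <- pca_ordination(xm), "missing")
  expect_equal(pm$dropped_rows, 2)
  xc <- cbind(matrix(runif(10), 5, 2), const = 1)
  expect_error(pca_ordination(xc), "constant")
  expect_error(pca_ordination(matrix(1:4, 2, 2)), ">= 3")
})

test_that("distribution summaries integrate and find modes", {
  set.seed(5)
  v <- rnorm(400, 3, 0.5)
  ds <- distribution_summary(v)
  expect_equal(ds$mean, mean(v))
  expect_equal(ds$sd, sd(v))
  expect_equal(ds$median, median(v))
  area <- sum(diff(ds$density$x) *
              (head(ds$density$y, -1) + tail(ds$density$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  # bimodal volume mixture shows two local maxima
  vm <- c(rnorm(300, 0.05, 0.01), rnorm(300, 0.25, 0.03))
  dm <- distribution_summary(vm)
  y <- dm$density$y
  peaks <- sum(diff(sign(diff(y))) == -2)
  expect_gte(peaks, 2)
  one <- distribution_summary(5)
  expect_equal(one$sd, 0)
  expect_equal(one$density$x[which.max(one$density$y)], 5, tolerance = 0.05)
  expect_error(distribution_summary(numeric(0)))
})

test_that("virus-prokaryote ratio reproduces reported values", {
  expect_equal(virus_prokaryote_ratio(5e5, 1e6), 0.5)
  expect_equal(virus_prokaryote_ratio(1e6, 1e6), 1.0)
  expect_equal(virus_prokaryote_ratio(1.4e6, 1e6), 1.4)
  expect_error(virus_prokaryote_ratio(1e5, 0))
})
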