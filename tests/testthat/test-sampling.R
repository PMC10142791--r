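test_that("truncated-lognormal matching recovers printed moments", {
  # closed-form moments invert the matched parameters
  fit <- match_truncated_lognormal(0.40, 0.09, 0.32, 0.95)
  expect_true(fit$ok)
  att <- truncated_lognormal_moments(fit$meanlog, fit$sdlog, 0.32, 0.95)
  expect_equal(unname(att["mean"]), 0.40, tolerance = 1e-3)
  expect_equal(unname(att["sd"]), 0.09, tolerance = 1e-3)
})

test_that("sampled cocci diameters match the winter profile moments", {
  nov_cocci <- single_morphotype_profile("NOVESAR-2013", "cocci")
  cells <- sample_cells(nov_cocci, 2e5, seed = 1)
  expect_equal(mean(cells$L_um), 0.40, tolerance = 0.01)
  expect_equal(sd(cells$L_um), 0.09, tolerance = 0.01)
  # cocci are a single diameter measure
  expect_identical(cells$L_um, cells$W_um)
})

test_that("sampling respects truncation bounds and orientation", {
  p <- builtin_cruise_profiles()
  for (cr in names(p)) {
    cells <- sample_cells(p[[cr]], 3000, seed = 7)
    expect_true(all(cells$L_um >= cells$W_um))
    for (m in unique(cells$morphotype)) {
      pr <- p[[cr]]$profiles[[m]]
      sub <- cells[cells$morphotype == m, ]
      expect_true(all(sub$L_um >= pr$L_min - 1e-12 &
                      sub$L_um <= pr$L_max + 1e-12),
                  label = paste(cr, m, "L within bounds"))
    }
  }
})

test_that("moment recovery holds within 3 standard errors for unconstrained draws", {
  # morphotypes whose printed W range lies below the L range, so the
  # L >= W orientation constraint never rejects a draw; where the two
  # ranges overlap the constraint necessarily modifies the marginals
  n <- 5e4
  cases <- list(c("BANSIC-2012", "spirillae"), c("NOVESAR-2013", "curved_rods"),
                c("BANSIC-2013", "cocci"))
  for (cs in cases) {
    pr <- builtin_cruise_profiles()[[cs[1]]]$profiles[[cs[2]]]
    prof <- single_morphotype_profile(cs[1], cs[2])
    cells <- sample_cells(prof, n, seed = 11, enforce_class = FALSE)
    se_mean <- pr$L_sd / sqrt(n)
    expect_lt(abs(mean(cells$L_um) - pr$L_mean), 3 * se_mean + 1e-3)
    expect_lt(abs(sd(cells$L_um) - pr$L_sd), 0.01)
  }
})

test_that("generated labels are consistent with the classifier by default", {
  p <- builtin_cruise_profiles()[["NOVESAR-2013"]]
  cells <- sample_cells(p, 5000, seed = 3)
  straight <- cells[cells$curvature_class == "straight", ]
  cls <- classify_morphotype_vec(straight$L_um, straight$W_um,
                                 straight$curvature_class)
  expect_gte(mean(cls == straight$morphotype), 0.99)
})

test_that("cell sampling is deterministic and validates inputs", {
  p <- builtin_cruise_profiles()[["BANSIC-2013"]]
  a <- sample_cells(p, 500, seed = 5)
  b <- sample_cells(p, 500, seed = 5)
  expect_identical(a, b)
  one <- sample_cells(p, 1, seed = 5)
  expect_equal(nrow(one), 1)
  expect_error(sample_cells(p, 0, seed = 1))
  bad <- p; bad$composition[] <- 0
  expect_error(sample_cells(bad, 10, seed = 1), "composition")
})

test_that("monte-carlo sphere volumes agree with the lognormal closed form", {
  # E[(pi/6) d^3] = (pi/6) mu^3 (1 + sd^2/mu^2)^3 for lognormal d
  mu <- 0.40; s <- 0.09
  cv2 <- (s / mu)^2
  meanlog <- log(mu) - log1p(cv2) / 2
  sdlog <- sqrt(log1p(cv2))
  set.seed(99)
  d <- rlnorm(1e6, meanlog, sdlog)
  mc <- mean(pi / 6 * d^3)
  closed <- pi / 6 * mu^3 * (1 + cv2)^3
  expect_equal(mc, closed, tolerance = 0.01)
})

test_that("environmental records stay in printed ranges with printed means", {
  env <- sample_environment("BANSIC-2012", 1000, seed = 7)
  expect_true(all(env$T >= 14.80 & env$T <= 26.90))
  expect_true(all(env$NO3 >= 0.13 & env$NO3 <= 1.62))
  nov <- sample_environment("NOVESAR-2013", 1000, seed = 7)
  expect_equal(mean(nov$T), 14.90, tolerance = 0.02)
  # degenerate phosphate range in BANSIC-2013 yields the constant mean
  b13 <- sample_environment("BANSIC-2013", 50, seed = 2)
  expect_true(all(b13$PO4 == 0.02))
  expect_equal(nrow(sample_environment("BANSIC-2012", 0)), 0)
  expect_error(sample_environment("NOSUCH", 10, seed = 1), "unknown cruise")
  expect_identical(sample_environment("BANSIC-2012", 20, seed = 4),
                   sample_environment("BANSIC-2012", 20, seed = 4))
})
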