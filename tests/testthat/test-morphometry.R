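test_that("classifier reproduces the documented examples", {
  expect_equal(classify_morphotype(0.51, 0.51, "straight"), "cocci")
  expect_equal(classify_morphotype(1.68, 0.41, "straight"), "rods")
  expect_equal(classify_morphotype(0.85, 0.58, "straight"), "coccobacilli")
  expect_equal(classify_morphotype(2.52, 0.40, "C"), "vibrios")
  expect_equal(classify_morphotype(2.90, 0.35, "S"), "spirillae")
  expect_equal(classify_morphotype(1.99, 0.38, "curved"), "curved_rods")
  expect_equal(classify_morphotype(5.0, 0.30, "straight"), "filamentous")
  expect_equal(classify_morphotype(1.00, 0.95, "straight"), "cocci")
})

test_that("classifier boundary conventions are exact", {
  # a difference of exactly 0.10 um is not 'less than 0.10' -> not cocci
  expect_equal(classify_morphotype(0.60, 0.50, "straight"), "coccobacilli")
  # exactly twice the width counts as 'at least two times' -> rods
  expect_equal(classify_morphotype(1.00, 0.50, "straight"), "rods")
  # exactly 4 um is not 'larger than 4 um' -> not filamentous
  expect_equal(classify_morphotype(4.00, 0.30, "straight"), "rods")
  expect_equal(classify_morphotype(4.0001, 0.30, "straight"), "filamentous")
  # filament rule precedes curvature
  expect_equal(classify_morphotype(5.0, 0.4, "C"), "filamentous")
})

test_that("classifier rejects invalid dimensions", {
  expect_error(classify_morphotype(0.5, 0.6))
  expect_error(classify_morphotype(-1, -2))
  expect_error(classify_morphotype(1, 0))
  expect_error(classify_morphotype(1, 0.5, "zigzag"))
})

test_that("cell_volume matches closed forms and is monotone", {
  expect_equal(cell_volume(0.40, 0.40), pi / 6 * 0.40^3, tolerance = 1e-12)
  expect_equal(cell_volume(0.40, 0.40), 0.03351, tolerance = 1e-4)
  expect_equal(cell_volume(1.68, 0.41), 0.2037, tolerance = 1e-3)
  expect_equal(cell_volume(1.00, 0.50), 0.16362, tolerance = 1e-4)
  # sphere limit exact at L = W over a range of diameters
  d <- seq(0.2, 2, by = 0.2)
  expect_equal(cell_volume(d, d), pi / 6 * d^3, tolerance = 1e-12)
  # strictly increasing in each argument, bounded by the full cylinder
  L <- seq(0.5, 4, by = 0.25)
  expect_true(all(diff(cell_volume(L, 0.4)) > 0))
  W <- seq(0.1, 1, by = 0.05)
  expect_true(all(diff(cell_volume(1.2, W)) > 0))
  expect_true(all(cell_volume(L, 0.4) <= pi / 4 * 0.4^2 * L))
  expect_error(cell_volume(0.3, 0.4))
})

test_that("carbon models convert volume as documented", {
  flat <- carbon_model("flat", flat_factor = 350)
  expect_equal(cell_carbon(0.039, flat), 13.65, tolerance = 1e-9)
  expect_equal(round(cell_carbon(0.039, flat)), 14)
  allo <- carbon_model("allometric", allo_a = 218, allo_b = 0.86)
  expect_equal(cell_carbon(1, allo), 218)
  # strictly increasing in V for both model kinds
  V <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(cell_carbon(V, flat)) > 0))
  expect_true(all(diff(cell_carbon(V, allo)) > 0))
  expect_error(cell_carbon(0, flat))
  expect_error(cell_carbon(-1, allo))
})

test_that("biomass closes units and is linear in abundance", {
  expect_equal(sample_biomass(1e6, 36.2), 36.2)
  expect_equal(sample_biomass(0, numeric(0)), 0)
  expect_equal(sample_biomass(2e6, c(30, 40)), 2 * sample_biomass(1e6, c(30, 40)))
  expect_error(sample_biomass(1e5, numeric(0)))
})

test_that("morphological index is the rods:cocci ratio", {
  expect_equal(morphological_index(c(rods = 90, cocci = 100)), 0.9)
  expect_equal(morphological_index(c(rods = 55, cocci = 55)), 1.0)
  expect_equal(morphological_index(c(rods = 0, cocci = 10)), 0.0)
  expect_true(is.na(morphological_index(c(rods = 5, cocci = 0))))
  expect_true(is.na(morphological_index(c(rods = 5))))
})

test_that("size-class spectra bin and normalize correctly", {
  h <- size_class_histogram(c(0.03, 0.04, 0.25), "volume")
  expect_equal(unname(h[2]), 2 / 3)
  expect_equal(unname(h[length(h)]), 1 / 3)
  expect_equal(sum(h), 1)
  # every value in one class
  h1 <- size_class_histogram(rep(0.1, 5), "volume")
  expect_equal(max(h1), 1)
  # length scheme uses 0.4 um classes
  hl <- size_class_histogram(c(0.5, 0.6, 1.0), "length")
  expect_equal(unname(hl[2]), 2 / 3)   # [0.4, 0.8)
  expect_equal(sum(hl), 1)
  set.seed(1)
  expect_equal(sum(size_class_histogram(rlnorm(500, -2, 1), "volume")), 1)
  expect_error(size_class_histogram(numeric(0), "volume"))
})

test_that("sample summary assembles the per-sample quantities", {
  set.seed(8)
  traits <- data.frame(
    morphotype = sample(c("cocci", "rods", "coccobacilli"), 300,
                        replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    VOL_um3 = rlnorm(300, -2.5, 0.6))
  traits$CCC_fg <- 350 * traits$VOL_um3
  s <- summarize_sample(traits, PA = 1e6)
  expect_equal(s$PB, 1e6 * mean(traits$CCC_fg) * 1e-6)
  expect_equal(s$M, sum(traits$morphotype == "rods") /
                 sum(traits$morphotype == "cocci"))
  fr <- unlist(s[grep("^frac_", names(s))])
  expect_equal(sum(fr), 1)
  sc <- unlist(s[grep("^volclass_", names(s))])
  expect_equal(sum(sc), 1)
  expect_gte(s$H_prime, 0)
})
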