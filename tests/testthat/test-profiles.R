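test_that("built-in cruise profiles carry the tabulated morphometry", {
  p <- builtin_cruise_profiles()
  expect_named(p, c("BANSIC-2012", "NOVESAR-2013", "BANSIC-2013"))

  nov <- p[["NOVESAR-2013"]]
  expect_equal(nov$profiles$cocci$L_mean, 0.40)
  expect_equal(nov$profiles$cocci$L_sd, 0.09)
  expect_equal(nov$profiles$cocci$L_min, 0.32)
  expect_equal(nov$profiles$cocci$L_max, 0.95)

  ban12 <- p[["BANSIC-2012"]]
  expect_equal(ban12$profiles$rods$L_mean, 1.68)
  expect_equal(ban12$profiles$rods$W_mean, 0.41)
  expect_equal(ban12$profiles$vibrios$L_mean, 2.52)

  # morphotypes not detected in winter carry zero fraction and none of
  # the cruises has a negative or unnormalized composition
  expect_equal(unname(nov$composition["vibrios"]), 0)
  expect_equal(unname(nov$composition["spirillae"]), 0)
  expect_equal(unname(nov$composition["filamentous"]), 0)
  for (cp in p) {
    expect_true(all(cp$composition >= 0))
    expect_equal(sum(cp$composition), 1, tolerance = 1e-12)
  }
})

test_that("default compositions reproduce the reported rod:cocci ratios", {
  p <- builtin_cruise_profiles()
  m <- vapply(p, function(cp)
    unname(cp$composition["rods"] / cp$composition["cocci"]), 1)
  expect_equal(unname(m["BANSIC-2012"]), 0.50, tolerance = 1e-9)
  expect_equal(unname(m["NOVESAR-2013"]), 0.90, tolerance = 1e-9)
  expect_equal(unname(m["BANSIC-2013"]), 0.44, tolerance = 1e-9)
  # cocci always dominate rods
  expect_true(all(m < 1))
})

test_that("profile constructors enforce their invariants", {
  expect_error(morphotype_profile("rods", 1, 0.1, 2, 3, 0.4, 0.1, 0.2, 0.6))
  expect_error(morphotype_profile("rods", 1, 0.1, 0.5, 3,
                                  W_mean = 2, W_sd = 0.1,
                                  W_min = 1.5, W_max = 2.5))
  expect_error(community_profile("X", c(cocci = 0.5, rods = 0.4),
                                 profiles = list()))
  expect_error(community_profile("X", c(cocci = 1),
                                 profiles = list()),
               "no dimension profile")
})
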