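test_that("rendering is deterministic and handles empty input", {
  fs <- test_field(noise = 0.03)
  p <- builtin_cruise_profiles()[["NOVESAR-2013"]]
  cells <- sample_cells(p, 10, seed = 2)
  a <- render_micrograph(cells, fs, seed = 5)
  b <- render_micrograph(cells, fs, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$centroid_x_px, b$truth$centroid_x_px)

  empty <- render_micrograph(cells[0, ], fs, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  # background-only: nothing above background + a few noise sd
  expect_lt(max(empty$image),
            fs$background_level + 6 * fs$background_noise_sd)
})

test_that("a single round cell renders as one bright component", {
  fs <- test_field()
  cells <- data.frame(cell_id = 1, cruise = "x", morphotype = "cocci",
                      L_um = 0.5, W_um = 0.5,
                      curvature_class = "straight", arc_turning_deg = 0)
  ren <- render_micrograph(cells, fs, seed = 3)
  seg <- segment_cells(ren$image)
  expect_equal(sum(seg$regions$retained), 1)
})

test_that("a bead-sized disc has the expected pixel diameter", {
  # 2.13 um at 0.106 um/px is a disc of ~20.1 px
  fs <- test_field(psf_sigma = 0)
  ren <- render_bead_field(1, diameter_um = 2.13, field = fs, seed = 4)
  seg <- segment_cells(ren$image)
  id <- seg$regions$region_id[seg$regions$retained][1]
  area <- seg$regions$area_px[id]
  d_eq <- 2 * sqrt(area / pi)
  expect_equal(d_eq, 2.13 / 0.106, tolerance = 0.05)
})

test_that("placement avoids overlap, borders and crowding failures", {
  fs <- test_field(width = 400, height = 400)
  p <- builtin_cruise_profiles()[["BANSIC-2012"]]
  cells <- sample_cells(p, 25, seed = 6)
  placed <- place_cells(cells, fs, seed = 7)
  lines <- attr(placed, "centerlines")
  r <- placed$W_um / 2 / fs$pixel_size
  for (i in seq_len(nrow(placed))) {
    pts <- lines[[i]]
    expect_true(all(pts[, 1] > fs$border_margin &
                    pts[, 1] < fs$width_px - fs$border_margin))
    for (j in seq_len(i - 1)) {
      d <- min(sqrt(outer(pts[, 1], lines[[j]][, 1], "-")^2 +
                    outer(pts[, 2], lines[[j]][, 2], "-")^2))
      expect_gt(d, r[i] + r[j])
    }
  }
  # a field too small for the population errors out
  tiny <- field_spec(width_px = 40, height_px = 40, border_margin = 10)
  big <- sample_cells(p, 5, seed = 1)
  big$L_um <- 6; big$W_um <- 0.5
  expect_error(place_cells(big, tiny, seed = 1), "too small|too crowded")
})

test_that("micrographs survive a 16-bit TIFF round trip", {
  skip_if_not_installed("tiff")
  fs <- test_field(width = 120, height = 100)
  cells <- sample_cells(builtin_cruise_profiles()[[1]], 3, seed = 8)
  ren <- render_micrograph(cells, fs, seed = 8)
  path <- tempfile(fileext = ".tif")
  write_micrograph(ren$image, path)
  back <- read_micrograph(path)
  expect_equal(dim(back), dim(ren$image))
  expect_lt(max(abs(back - ren$image)), 2 / 65535)
  unlink(path)
})
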