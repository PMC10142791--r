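test_that("segmentation finds exactly the rendered cells", {
  fs <- test_field(width = 500, height = 500)
  p <- builtin_cruise_profiles()[["BANSIC-2012"]]
  cells <- sample_cells(p, 10, seed = 12)
  ren <- render_micrograph(cells, fs, seed = 13)
  seg <- segment_cells(ren$image)
  expect_equal(sum(seg$regions$retained), 10)
})

test_that("blank images give zero regions, not an error", {
  blank <- matrix(0.05, 100, 100)
  seg <- segment_cells(blank)
  expect_equal(nrow(seg$regions), 0)
})

test_that("border-touching regions are flagged and excluded", {
  img <- matrix(0.02, 120, 120)
  img[1:10, 50:56] <- 0.6      # touches the x = 1 border
  img[60:70, 60:66] <- 0.6     # interior
  seg <- segment_cells(img)
  expect_equal(nrow(seg$regions), 2)
  expect_equal(sum(seg$regions$retained), 1)
  expect_equal(sum(seg$regions$touches_border), 1)
})

test_that("sub-minimum regions are excluded", {
  img <- matrix(0.02, 80, 80)
  img[40, 40] <- 0.6           # single pixel
  img[10:20, 10:14] <- 0.6
  seg <- segment_cells(img, min_area_px = 4)
  expect_equal(sum(seg$regions$retained), 1)
})

test_that("measurement recovers bead and capsule dimensions within 2 px", {
  tol <- 2 * 0.106
  fs <- test_field(psf_sigma = 0.05)
  ren <- render_bead_field(6, field = fs, seed = 21)
  meas <- measure_micrograph(ren$image, calibration())
  expect_equal(nrow(meas), 6)
  expect_lt(abs(mean(meas$L_um) - 2.13), tol)
  expect_lt(abs(mean(meas$W_um) - 2.13), tol)

  rods <- data.frame(cell_id = 1:12, cruise = "x", morphotype = "rods",
                     L_um = 1.68, W_um = 0.41,
                     curvature_class = "straight", arc_turning_deg = 0)
  ren2 <- render_micrograph(rods, fs, seed = 22)
  cal <- calibration(psf_fwhm_px = 2.355 * fs$psf_sigma / fs$pixel_size)
  meas2 <- measure_micrograph(ren2$image, cal)
  expect_lt(abs(mean(meas2$L_um) - 1.68), tol)
  expect_lt(abs(mean(meas2$W_um) - 0.41), tol)
  expect_true(all(meas2$L_um >= meas2$W_um))
})

test_that("measure_region enforces the L >= W convention on blocks", {
  img <- matrix(0.02, 60, 60)
  img[20:30, 25:35] <- 0.6     # square block
  seg <- segment_cells(img)
  m <- measure_region(seg$labels, 1, calibration(), image = img)
  expect_gte(m$L_um, m$W_um)
  expect_equal(m$L_um / m$W_um, 1, tolerance = 0.2)
})

test_that("curvature classification follows the operational thresholds", {
  expect_equal(classify_curvature(0, 0), "straight")
  expect_equal(classify_curvature(10, 0), "straight")
  expect_equal(classify_curvature(40, 0), "curved")
  expect_equal(classify_curvature(90, 0), "curved")
  expect_equal(classify_curvature(160, 0), "C")
  expect_equal(classify_curvature(120, 1), "S")
  expect_equal(classify_curvature(10, 1), "straight")
  expect_error(classify_curvature(-5, 0))
})

test_that("rendered arcs are read back as their curvature class", {
  fs <- test_field(width = 400, height = 400)
  cal <- calibration(psf_fwhm_px = 2.355 * fs$psf_sigma / fs$pixel_size)
  arcs <- data.frame(
    cell_id = 1:3, cruise = "x",
    morphotype = c("vibrios", "spirillae", "curved_rods"),
    L_um = c(2.5, 2.9, 2.0), W_um = c(0.40, 0.35, 0.38),
    curvature_class = c("C", "S", "curved"),
    arc_turning_deg = c(160, 160, 55))
  ren <- render_micrograph(arcs, fs, seed = 31)
  meas <- measure_micrograph(ren$image, cal)
  m <- match_measurements(ren$truth, meas)
  expect_equal(m$curvature_class, c("C", "S", "curved"))
})

test_that("bead calibration anchors scales and corrects blur bias", {
  fs <- test_field(psf_sigma = 0)
  ren <- render_bead_field(12, field = fs, seed = 41)
  cal <- calibrate_with_beads(ren$image, pixel_size = fs$pixel_size)
  expect_equal(cal$length_scale, 1, tolerance = 0.02)
  expect_equal(cal$width_scale, 1, tolerance = 0.02)
  # strong blur biases the uncalibrated half-max measurement (the
  # half-max contour of a blurred mid-size disc contracts); the bead
  # calibration senses and removes that bias on an independent field
  fsb <- test_field(psf_sigma = 0.3)
  renb <- render_bead_field(12, field = fsb, seed = 41)
  calb <- calibrate_with_beads(renb$image, pixel_size = fsb$pixel_size)
  raw <- measure_micrograph(renb$image, calibration())
  expect_gt(abs(mean(raw$W_um) - 2.13), 0.05)
  fresh <- render_bead_field(10, field = fsb, seed = 99)
  corr <- measure_micrograph(fresh$image, calb)
  expect_equal(mean(corr$W_um), 2.13, tolerance = 2 * 0.106 / 2.13)
  expect_error(calibrate_with_beads(matrix(0.05, 50, 50)), "beads")
})

test_that("abundance follows the counting formula exactly", {
  setup <- counting_setup(rep(40, 20), volume_mL = 2)
  pa <- abundance_from_counts(setup)
  expect_equal(pa$PA, 40 * (201.06 / (1300 * 1030 * 0.106^2 * 1e-6)) / 2,
               tolerance = 1e-9)
  expect_equal(pa$PA, 2.672e5, tolerance = 0.001)
  expect_equal(pa$SE, 0)
  zero <- abundance_from_counts(counting_setup(rep(0, 20)))
  expect_equal(zero$PA, 0)
  # exactly linear in mean count, inverse-linear in volume
  s1 <- counting_setup(c(10, 20, 30), volume_mL = 1,
                       replicate_slides = 2)
  s2 <- counting_setup(2 * c(10, 20, 30), volume_mL = 1,
                       replicate_slides = 2)
  s3 <- counting_setup(c(10, 20, 30), volume_mL = 2,
                       replicate_slides = 2)
  expect_warning(a1 <- abundance_from_counts(s1), "fewer than 20")
  expect_warning(a2 <- abundance_from_counts(s2), "fewer than 20")
  expect_warning(a3 <- abundance_from_counts(s3), "fewer than 20")
  expect_equal(a2$PA, 2 * a1$PA)
  expect_equal(a3$PA, a1$PA / 2)
  expect_error(counting_setup(c(5, 5), volume_mL = 0))
  expect_error(counting_setup(integer(0)))
})
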