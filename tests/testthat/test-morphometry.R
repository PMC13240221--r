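# Stereological formulas against closed-form oracles and invariants.

test_that("corrected fiber count allows half-integers and guards inputs", {
  expect_equal(corrected_fiber_count(100, 20), 90)
  expect_equal(corrected_fiber_count(97, 13), 90.5)
  expect_equal(corrected_fiber_count(0, 0), 0)
  expect_error(corrected_fiber_count(5, 6), "exceeds")
})

test_that("mean fiber area and endomysium area follow their definitions", {
  expect_equal(mean_fiber_area(450000, 90), 5000)
  expect_equal(mean_fiber_area(0, 5), 0)
  expect_error(mean_fiber_area(100, 0), "positive")
  expect_equal(total_endomysium_area(1188100, 1000000), 188100)
  expect_equal(total_endomysium_area(7, 7), 0)
  expect_equal(total_endomysium_area(7, 0), 7)
  expect_error(total_endomysium_area(5, 6), "exceeds")
})

test_that("thickness formula matches the grid oracle and flags degeneracy", {
  # 10x10 grid: A_e = 188100, P_f = 40000, P_ROI = 4360
  expect_equal(mean_endomysium_thickness(188100, 40000, 4360),
               188100 / 15640)
  expect_equal(mean_endomysium_thickness(0, 4000, 100), 0)
  # 2x2 toy grid: P_f/2 < P_ROI -> undefined
  expect_warning(res <- mean_endomysium_thickness(4100, 1600, 840),
                 "undefined")
  expect_true(is.na(res))
})

test_that("square-perimeter estimate is 4*sqrt(area)*count", {
  expect_equal(square_perimeter_estimate(2500, 10), 2000)
  expect_equal(square_perimeter_estimate(0, 10), 0)
})

test_that("grid-mosaic ground truth reproduces the closed-form morphometry", {
  m <- grid_mosaic()  # flush 10x10 grid, side 100, gap 10, L = 1090
  fibers <- data.frame(area_um2 = m$fiber_areas_um2,
                       perimeter_um = m$fiber_perimeters_um,
                       trimmed = m$trimmed_flags)
  sm <- section_morphometry(m$roi, fibers = fibers,
                            variant = "boundary_stain")
  expect_equal(sm$n_fibers_total, 100)
  expect_equal(sm$n_trimmed, 0)
  expect_equal(sm$total_fiber_area_um2, 1e6)
  expect_equal(sm$mean_fiber_area_um2, 10000)
  expect_equal(sm$total_endomysium_area_um2, 188100)
  expect_equal(sm$total_fiber_perimeter_um, 40000)
  expect_equal(sm$mean_endomysium_thickness_um, 188100 / 15640)
})

test_that("margin-grid segmentation is exact end to end", {
  # same squares inside a 1100 x 1100 ROI: 5 um margin, no border contact
  m <- cached("grid_margin", generate_mosaic(mosaic_config(
    roi_width_um = 1100, roi_height_um = 1100, pixel_size_um = 0.5,
    target_mean_fiber_area_um2 = 10000, fiber_area_cv = 0,
    endomysium_thickness_um = 10, lattice = "square", noise_sd = 0,
    seed = 1)))
  seg <- segment_boundary_stain(m$boundary_image, m$roi)
  sm <- section_morphometry(m$roi, fibers = seg$fibers,
                            variant = "boundary_stain")
  expect_equal(sm$n_fibers_total, 100)
  expect_equal(sm$n_trimmed, 0)
  expect_equal(sm$total_fiber_area_um2, 1e6)
  expect_equal(sm$mean_fiber_area_um2, 10000)
  expect_equal(sm$total_endomysium_area_um2, 210000)
  # pixel-aligned squares: hull + half-pixel expansion is exact
  expect_equal(sm$total_fiber_perimeter_um, 40000)
  expect_equal(sm$mean_endomysium_thickness_um, 210000 / 15600)
})

test_that("section morphometry satisfies its algebraic identity and scaling", {
  m <- small_mosaic(seed = 1)
  seg <- segment_boundary_stain(m$boundary_image, m$roi)
  sm <- section_morphometry(m$roi, fibers = seg$fibers,
                            variant = "boundary_stain")
  expect_equal(sm$endo_area_per_fiber_um2,
               sm$endo_to_fiber_area_ratio * sm$mean_fiber_area_um2)
  # scale all lengths by c: areas x c^2, thickness x c, ratio invariant
  c0 <- 2.5
  fib2 <- seg$fibers
  fib2$area_um2 <- fib2$area_um2 * c0^2
  fib2$perimeter_um <- fib2$perimeter_um * c0
  roi2 <- roi_geometry(m$roi$width_um * c0, m$roi$height_um * c0,
                       m$roi$pixel_size_um * c0)
  sm2 <- section_morphometry(roi2, fibers = fib2, variant = "boundary_stain")
  expect_equal(sm2$mean_fiber_area_um2, sm$mean_fiber_area_um2 * c0^2)
  expect_equal(sm2$mean_endomysium_thickness_um,
               sm$mean_endomysium_thickness_um * c0)
  expect_equal(sm2$endo_to_fiber_area_ratio, sm$endo_to_fiber_area_ratio)
})

test_that("estimated thickness increases strictly with the generative band", {
  for (s in 1:2) {
    est <- sapply(c(2, 3, 4), function(t) {
      m <- small_mosaic(seed = s, t = t)
      seg <- segment_boundary_stain(m$boundary_image, m$roi)
      section_morphometry(m$roi, fibers = seg$fibers,
                          variant = "boundary_stain")$mean_endomysium_thickness_um
    })
    expect_true(all(diff(est) > 0))
  }
})

test_that("an all-fiber section reports zero endomysium everywhere", {
  roi <- roi_geometry(100, 100, 1)
  fibers <- data.frame(area_um2 = rep(2500, 4),
                       perimeter_um = rep(200, 4),
                       trimmed = rep(FALSE, 4))
  sm <- section_morphometry(roi, fibers = fibers, variant = "boundary_stain")
  expect_equal(sm$total_endomysium_area_um2, 0)
  expect_equal(sm$mean_endomysium_thickness_um, 0)
  expect_equal(sm$endo_to_fiber_area_ratio, 0)
})

test_that("fill variant needs the manual counts and matches the boundary
           variant on the same mosaic", {
  m <- small_mosaic(seed = 1)
  bc <- binarize_fill_stain(m$fill_image, m$roi)
  expect_error(section_morphometry(m$roi, counts = bc,
                                   variant = "fill_square_approx"),
               "manual")
  seg <- segment_boundary_stain(m$boundary_image, m$roi)
  mc <- count_fibers_manual_emulation(seg$label_image)
  sm_f <- section_morphometry(m$roi, counts = bc, n_total = mc$n_total,
                              n_trimmed = mc$n_trimmed,
                              variant = "fill_square_approx")
  sm_b <- section_morphometry(m$roi, fibers = seg$fibers,
                              variant = "boundary_stain")
  expect_lt(abs(sm_f$mean_fiber_area_um2 / sm_b$mean_fiber_area_um2 - 1),
            0.05)
})
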