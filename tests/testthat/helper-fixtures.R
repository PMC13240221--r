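# Shared fixtures. Mosaics are expensive, so they are built once per test
# run and cached; small ROIs (~30 fibers at 1 um/px) keep the default suite
# fast, while the acceptance tests build full-size ROIs themselves.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_mosaic_config <- function(seed = 1L, t = 3, cv = 0.25, noise = 0,
                                lattice = "hex") {
  mosaic_config(roi_width_um = 300, roi_height_um = 300, pixel_size_um = 1,
                target_mean_fiber_area_um2 = 2500, fiber_area_cv = cv,
                endomysium_thickness_um = t, noise_sd = noise,
                lattice = lattice, seed = seed)
}

small_mosaic <- function(seed = 1L, t = 3) {
  cached(sprintf("mosaic_s%d_t%g", seed, t),
         generate_mosaic(small_mosaic_config(seed = seed, t = t)))
}

# the closed-form grid mosaic: 10 x 10 squares of side 100 um with 10 um
# gaps, flush with a 1090 x 1090 um ROI
grid_mosaic <- function(pixel = 0.5) {
  cached(sprintf("grid_%g", pixel),
         generate_mosaic(mosaic_config(
           roi_width_um = 1090, roi_height_um = 1090,
           pixel_size_um = pixel, target_mean_fiber_area_um2 = 10000,
           fiber_area_cv = 0, endomysium_thickness_um = 10,
           lattice = "square", noise_sd = 0, seed = 1)))
}

cohort_fixture <- function() cached("cohort", load_cohort_table())
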