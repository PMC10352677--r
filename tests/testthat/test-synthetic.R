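test_that("vegetation endmember carries the canonical VNIR features", {
  wl <- reduced_wavelengths()
  expect_equal(length(wl), 100L)
  expect_equal(mean(diff(wl)), 5.94, tolerance = 0.005)
  sp <- vegetation_spectrum(0.8, wl)
  win <- which(wl >= 640 & wl <= 700)
  expect_equal(wl[win][which.min(sp[win])], wl[band_index(672)])
  # green peak exceeds red absorption for all but near-zero chlorophyll
  for (lev in seq(0.2, 1, by = 0.1)) {
    s <- vegetation_spectrum(lev, wl)
    expect_gt(s[band_index(559)], s[band_index(678)])
  }
  # chlorophyll -> 0: red edge contrast vanishes
  contrast <- function(lev) {
    s <- vegetation_spectrum(lev, wl)
    s[band_index(750)] - s[band_index(680)]
  }
  expect_lt(contrast(0.01), 0.1 * contrast(0.8))
  expect_error(vegetation_spectrum(0.8, numeric(0)), "empty")
  expect_error(vegetation_spectrum(0), "chlorophyll")
})

test_that("fluorescence endmember peaks at 690 and 732 nm with weak blue/green", {
  wl <- reduced_wavelengths()
  em <- fluorescence_spectrum(wl)
  red <- which(wl > 660 & wl < 712)
  expect_equal(wl[red][which.max(em[red])], wl[band_index(690)])
  farred <- which(wl >= 712 & wl < 770)
  expect_equal(wl[farred][which.max(em[farred])], wl[band_index(732)])
  # both are true local maxima separated by a valley
  expect_lt(em[band_index(712)], em[band_index(690)])
  expect_lt(em[band_index(712)], em[band_index(732)])
  expect_lt(em[band_index(450)], 0.25 * em[band_index(690)])
  expect_lt(em[band_index(530)], 0.25 * em[band_index(690)])
  expect_equal(fluorescence_spectrum(wl, c(blue = 0, green = 0, red690 = 0,
                                           red732 = 0)),
               rep(0, 100))
  expect_error(fluorescence_spectrum(seq(500, 600, 10)), "span")
})

test_that("scene rendering is seed-deterministic with exact ground truth", {
  s1 <- render_scene(phantom_spec(seed = 4))
  s2 <- render_scene(phantom_spec(seed = 4))
  expect_identical(s1$reflectance$data, s2$reflectance$data)
  expect_identical(s1$fluorescence$data, s2$fluorescence$data)
  s3 <- render_scene(phantom_spec(seed = 5))
  expect_false(identical(s1$reflectance$data, s3$reflectance$data))
  # truth counts equal the class-map counts, which partition the scene
  cm <- s1$truth$class_map
  expect_equal(sum(s1$truth$leaf_counts),
               sum(cm == s1$truth$classes[["leaf"]]))
  expect_equal(length(cm), prod(dim(s1$reflectance$data)[1:2]))
  expect_true(all(cm %in% s1$truth$classes))
  expect_error(phantom_spec(pot_size = 200), "layout")
})

test_that("raw variants reproduce the reduced cube through the pipeline", {
  sc <- render_scene(phantom_spec(seed = 6), raw = TRUE)
  raw <- sc$raw_reflectance
  expect_equal(dim(raw), c(96L, 384L, 300L))
  expect_true(all(raw$data >= 0 & raw$data <= 4095))
  expect_equal(raw$data, round(raw$data))
  binned <- bin_cube(raw, 3, 4)
  expect_equal(dim(binned), c(96L, 96L, 100L))
  ref <- extract_panel_reference(binned, list(y = c(1, 12), x = c(1, 96)))
  refl <- flat_field_correct(binned, ref)
  # flat-fielded raw intensities agree with the directly rendered
  # reflectance cube on leaf pixels (up to detector noise)
  gt <- truth_leaf_mask(sc$truth)
  direct <- summarize_spectra(sc$reflectance, gt)$table$mean
  via_raw <- summarize_spectra(refl, gt)$table$mean
  expect_lt(median(abs(via_raw - direct) / direct), 0.05)
})

test_that("stronger drought effects strengthen the red-edge ratio correlation", {
  wl <- reduced_wavelengths()
  rs <- sapply(c(1.0, 1.1, 1.25), function(eff) {
    lc <- ld <- NULL
    for (d in 0:1) {
      scc <- render_scene(drought_tray_spec("control", seed = 300 + d,
                                            drought_effect = eff))
      scd <- render_scene(drought_tray_spec("drought", seed = 400 + d,
                                            drought_effect = eff))
      lc <- rbind(lc, truth_roi_spectra(scc$reflectance, scc$truth,
                                        classes = "leaf", n = 250,
                                        seed = 500 + d)$spectra)
      ld <- rbind(ld, truth_roi_spectra(scd$reflectance, scd$truth,
                                        classes = "leaf", n = 250,
                                        seed = 600 + d)$spectra)
    }
    ratio <- c(lc[, band_index(690)] / lc[, band_index(702)],
               ld[, band_index(690)] / ld[, band_index(702)])
    abs(cor(ratio, rep(1:2, each = nrow(lc))))
  })
  expect_true(all(diff(rs) > 0))
  expect_lt(rs[1], 0.15)   # no effect, no correlation
})

test_that("a noise-free, unshifted phantom segments exactly", {
  spec <- phantom_spec(seed = 8, chlorophyll_sd = 0, nir_structure_sd = 0,
                       soil_slope_sd = 0, mult_noise_sd = 0,
                       add_noise_sd = 0, pot_chl_sd = 0, pot_nir_sd = 0,
                       pot_gain_sd = 0, pot_band_shift_sd = 0,
                       margin_mix_max = 0, shift = c(0L, 0L))
  sc <- render_scene(spec)
  mask <- otsu_mask(ratio_image(sc$reflectance, 559, 678), "above")
  expect_identical(unname(mask$mask), unname(truth_leaf_mask(sc$truth)))
  # zero shift estimated as zero
  reg <- register_pair(sc$reflectance, sc$fluorescence)
  expect_equal(reg$result$shift, c(0L, 0L))
})
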