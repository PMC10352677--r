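test_that("masked spectral summaries recover known statistics", {
  cc <- tiny_cube(6, 6, 4, seed = 71)
  cc$data[] <- 5
  mask <- matrix(FALSE, 6, 6); mask[2:4, 2:4] <- TRUE
  s <- summarize_spectra(cc, mask)
  expect_equal(s$n, 9L)
  expect_equal(s$table$mean, rep(5, 4))
  expect_equal(s$table$sd, rep(0, 4))
  expect_error(summarize_spectra(cc, matrix(FALSE, 6, 6)), "empty mask")
  # sampling check against a known per-band Gaussian
  set.seed(73)
  mu <- c(10, 20, 30, 40)
  big <- hypercube(array(rnorm(40 * 40 * 4, rep(mu, each = 1600), 2),
                         dim = c(40, 40, 4)), c(1, 2, 3, 4))
  s2 <- summarize_spectra(big, matrix(TRUE, 40, 40))
  se <- 2 / sqrt(1600)
  expect_true(all(abs(s2$table$mean - mu) < 4 * se))
  expect_true(all(abs(s2$table$sd - 2) < 0.2))
})

test_that("fluorescence phantom spectra peak at the red emission bands", {
  sc <- cached_scene("single", seed = 2)
  reg <- register_pair(sc$reflectance, sc$fluorescence)
  s <- summarize_spectra(reg$cube, truth_leaf_mask(sc$truth))
  wl <- s$table$wavelength
  m <- s$table$mean
  red <- which(wl > 660 & wl < 715)
  expect_equal(wl[red][which.max(m[red])], wl[band_index(690)])
  far_red <- which(wl > 715 & wl < 760)
  expect_equal(wl[far_red][which.max(m[far_red])], wl[band_index(732)])
})

test_that("leaf areas count mask pixels and track phantom ground truth", {
  zero <- matrix(FALSE, 8, 8)
  square <- matrix(FALSE, 20, 20); square[6:15, 3:12] <- TRUE
  la <- leaf_area(list(zero, square), day = c(1, 2), tray = 1,
                  treatment = "control")
  expect_equal(la$pixels, c(0L, 100L))
  sc <- cached_scene("single", seed = 2)
  mask <- otsu_mask(ratio_image(sc$reflectance, 559, 678), "above")
  truth_area <- sum(sc$truth$leaf_counts)
  expect_lt(abs(sum(mask$mask) - truth_area) / truth_area, 0.10)
})

test_that("leaf-area testing recovers a planted deficit and calibrates under the null", {
  expect_equal(leaf_area_test(c(5, 5, 5), c(5, 5, 5))$t, 0)
  expect_equal(leaf_area_test(c(5, 5, 5), c(5, 5, 5))$percent_difference, 0)
  set.seed(79)
  control <- rnorm(6, 2000, 60)
  drought <- rnorm(6, 2000 * 0.71, 60)    # planted 29% deficit
  res <- leaf_area_test(control, drought)
  expect_lt(res$p_value, 0.001)
  expect_lt(abs(res$percent_difference - 29), 5)
  # permutation null: p-values roughly uniform
  set.seed(83)
  pool <- rnorm(12, 1500, 100)
  pvals <- replicate(400, {
    pick <- sample(12, 6)
    leaf_area_test(pool[pick], pool[-pick])$p_value
  })
  expect_gt(mean(pvals), 0.35); expect_lt(mean(pvals), 0.65)
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_error(leaf_area_test(c(1), c(2, 3)), "at least 2")
})

test_that("band normalization pins the reference band and ignores scale", {
  set.seed(89)
  wl <- seq(540, 740, by = 10)
  sp <- matrix(runif(3 * length(wl), 5, 50), 3)
  out <- normalize_at_band(sp, wl, 702)
  b <- which.min(abs(wl - 702))
  expect_equal(out[, b], rep(1, 3))
  expect_equal(normalize_at_band(sp * 7, wl, 702), out, tolerance = 1e-12)
  v <- normalize_at_band(sp[1, ], wl, 702)
  expect_equal(v[b], 1)
  zero <- sp; zero[2, b] <- 0
  expect_error(normalize_at_band(zero, wl, 702), "zero")
})

test_that("drought phantoms show the elevated red-edge shoulder at 690 nm", {
  scc <- cached_scene("control", seed = 1)
  scd <- cached_scene("drought", seed = 1001)
  wl <- scc$reflectance$wavelengths
  mc <- colMeans(truth_roi_spectra(scc$reflectance, scc$truth,
                                   classes = "leaf", n = 500, seed = 1)$spectra)
  md <- colMeans(truth_roi_spectra(scd$reflectance, scd$truth,
                                   classes = "leaf", n = 500, seed = 2)$spectra)
  nc <- normalize_at_band(mc, wl, 702)
  nd <- normalize_at_band(md, wl, 702)
  expect_gt(nd[band_index(690)], nc[band_index(690)])
})

test_that("window filter applies the outlier rule with exact accounting", {
  wl <- seq(700, 930, length.out = 24)
  set.seed(97)
  cube <- hypercube(array(runif(18 * 18 * 24, 49, 51), dim = c(18, 18, 24)),
                    wl)
  mask <- matrix(FALSE, 18, 18); mask[4:12, 5:13] <- TRUE  # 9x9 block
  wf <- window_filter(cube, mask, band_nm = 815)
  expect_equal(wf$counts$n_kept + wf$counts$n_removed, 9L)
  expect_equal(wf$counts$n_partial, 0L)
  # pixel accounting conservation
  expect_equal(wf$counts$n_kept * 9 + wf$counts$masked_pixels_removed +
                 wf$counts$masked_pixels_partial +
                 wf$counts$masked_pixels_outside_tiling,
               wf$counts$masked_pixels_total)
  # bounded uniform noise cannot exceed the 3-SD fence -> nothing removed
  expect_equal(wf$counts$n_removed, 0L)
  # retained spectra are the window means
  b815 <- band_index(815, wl)
  first <- wf$window_info[wf$window_info$status == "kept", ][1, ]
  yy <- first$y0:(first$y0 + 2); xx <- first$x0:(first$x0 + 2)
  expect_equal(unname(wf$spectra[1, b815]), mean(cube$data[yy, xx, b815]),
               tolerance = 1e-12)
  # one pixel at M + 10 SD removes exactly its window
  cube2 <- cube
  vals <- band_image(cube2, 815)[mask]
  cube2$data[5, 6, b815] <- mean(vals) + 10 * sd(vals)
  wf2 <- window_filter(cube2, mask, band_nm = 815)
  expect_equal(wf2$counts$n_removed, 1L)
  removed <- wf2$window_info[wf2$window_info$status == "removed", ]
  expect_true(removed$y0 <= 5 && 5 <= removed$y0 + 2)
  expect_true(removed$x0 <= 6 && 6 <= removed$x0 + 2)
})

test_that("window filter limits: infinite fence keeps all, zero fence removes all", {
  wl <- seq(700, 930, length.out = 10)
  set.seed(101)
  cube <- hypercube(array(runif(12 * 12 * 10, 49, 51), dim = c(12, 12, 10)), wl)
  mask <- matrix(TRUE, 12, 12)
  wf_inf <- window_filter(cube, mask, band_nm = 815, k_sd = Inf)
  expect_equal(wf_inf$counts$n_removed, 0L)
  # k_sd = 0: every window containing any pixel != M is removed
  wf0 <- window_filter(cube, mask, band_nm = 815, k_sd = 0)
  expect_equal(wf0$counts$n_kept, 0L)
  # uniform image: zero windows removed even at k_sd = 0
  cu <- cube; cu$data[] <- 3
  wfu <- window_filter(cu, mask, band_nm = 815, k_sd = 0)
  expect_equal(wfu$counts$n_removed, 0L)
  expect_equal(wfu$counts$n_kept, 16L)
  # when nothing is removed and tiling is exact, the filter's grand mean
  # equals the plain masked mean
  s <- summarize_spectra(cube, mask)
  expect_equal(colMeans(wf_inf$spectra), s$table$mean,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("partial windows are excluded but counted", {
  wl <- seq(700, 930, length.out = 6)
  cube <- hypercube(array(5, dim = c(10, 10, 6)), wl)
  mask <- matrix(FALSE, 10, 10)
  mask[2:7, 2:7] <- TRUE        # 6x6 block tiles exactly into 4 windows
  mask[2, 2] <- FALSE           # knock out one corner -> one partial window
  wf <- window_filter(cube, mask, band_nm = 815)
  expect_equal(wf$counts$n_kept, 3L)
  expect_equal(wf$counts$n_partial, 1L)
  expect_equal(wf$counts$masked_pixels_partial, 8L)
  expect_equal(wf$counts$n_kept * 9 + wf$counts$masked_pixels_removed +
                 wf$counts$masked_pixels_partial +
                 wf$counts$masked_pixels_outside_tiling,
               wf$counts$masked_pixels_total)
})

test_that("pseudo-RGB rendering is stretch-invariant and color-consistent", {
  cube <- tiny_cube(8, 8, 40, seed = 103)
  cube$wavelengths <- seq(420, 810, by = 10)
  rgb1 <- pseudo_rgb(cube)
  expect_equal(dim(rgb1), c(8, 8, 3))
  expect_true(all(rgb1 >= 0 & rgb1 <= 1))
  cube2 <- cube; cube2$data <- cube$data * 2
  expect_equal(pseudo_rgb(cube2), rgb1, tolerance = 1e-12)
  # grayscale cube -> equal channels
  gray <- cube
  for (b in seq_along(gray$wavelengths)) gray$data[, , b] <- cube$data[, , 1]
  rgbg <- pseudo_rgb(gray)
  expect_equal(rgbg[, , 1], rgbg[, , 2], tolerance = 1e-12)
  expect_equal(rgbg[, , 2], rgbg[, , 3], tolerance = 1e-12)
  expect_error(pseudo_rgb(cube, rgb_nm = c(1200, 550, 460)), "outside")
  # leaf phantom: green channel dominates on leaf pixels
  sc <- cached_scene("single", seed = 2)
  rgb <- pseudo_rgb(sc$reflectance)
  gt <- truth_leaf_mask(sc$truth)
  expect_gt(mean(rgb[, , 2][gt]), mean(rgb[, , 1][gt]))
  expect_gt(mean(rgb[, , 2][gt]), mean(rgb[, , 3][gt]))
})
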