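test_that("tight-VOI SBR matches brute-force voxel summation on a toy grid", {
  vois <- toy_voi_set()
  set.seed(5)
  counts <- array(runif(125, 10, 100), c(5, 5, 5))
  vol <- count_volume(counts, 2)
  rec <- small_voi_sbr(vol, vois)
  ref <- mean(counts[vois$labels == 5L])
  for (i in seq_len(nrow(rec))) {
    codes <- switch(rec$structure[i],
                    caudate = if (rec$side[i] == "left") 1L else 2L,
                    putamen = if (rec$side[i] == "left") 3L else 4L,
                    striatum = if (rec$side[i] == "left") c(1L, 3L) else c(2L, 4L))
    expect_equal(rec$measured_sbr[i],
                 (mean(counts[vois$labels %in% codes]) - ref) / ref,
                 tolerance = 1e-12)
  }
})

test_that("tight-VOI arithmetic: uniform gives 0, 3x reference gives 2", {
  vois <- toy_voi_set()
  uniform <- count_volume(array(7, c(5, 5, 5)), 2)
  expect_true(all(small_voi_sbr(uniform, vois)$measured_sbr == 0))
  counts <- array(10, c(5, 5, 5))
  counts[vois$labels %in% 1:4] <- 30
  rec <- small_voi_sbr(count_volume(counts, 2), vois)
  expect_true(all(rec$measured_sbr == 2))
})

test_that("quantification guards fire", {
  vois <- toy_voi_set()
  expect_error(small_voi_sbr(count_volume(array(0, c(5, 5, 5)), 2), vois),
               "reference mean")
  expect_error(small_voi_sbr(count_volume(array(1, c(4, 4, 4)), 2), vois),
               "aligned")
  g <- tiny_geometry()
  lv <- large_voi_set(g, margin_mm = 16)
  zero <- count_volume(array(0, g$grid_shape), g$voxel_size)
  expect_error(large_voi_sbr(zero, lv), "reference concentration")
})

test_that("large-VOI SBR is exact on an unblurred phantom", {
  g <- tiny_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(3, 3),
                       background_concentration = 100, geometry = g)
  vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = 0), seed = 1,
                        noise = FALSE, filter = FALSE)
  nominal <- sum(geometry_masks(g)$striatum_right) * g$voxel_size^3 / 1000
  rec <- large_voi_sbr(vol, large_voi_set(g, margin_mm = 8),
                       nominal_striatal_volume = nominal)
  expect_equal(rec$measured_sbr, c(3, 3), tolerance = 1e-6)
})

test_that("large-VOI SBR absorbs a 12 mm blur to within 5%", {
  g <- study_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(5, 5),
                       background_concentration = 200, geometry = g)
  vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = 12), seed = 1,
                        noise = FALSE)
  nominal <- sum(geometry_masks(g)$striatum_right) * g$voxel_size^3 / 1000
  rec <- large_voi_sbr(vol, large_voi_set(g, margin_mm = 36),
                       nominal_striatal_volume = nominal)
  expect_equal(rec$measured_sbr, c(5, 5), tolerance = 0.05)
})

test_that("both SBRs increase strictly with true contrast", {
  g <- tiny_geometry()
  sv <- small_voi_set(g)
  lv <- large_voi_set(g, margin_mm = 16)
  small <- large <- numeric(0)
  for (sbr in c(1, 3, 6)) {
    spec <- phantom_spec(true_sbr = sbr_vector(sbr, sbr),
                         background_concentration = 100, geometry = g)
    vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = 8), seed = 1,
                          noise = FALSE)
    small <- c(small, small_voi_sbr(vol, sv)$measured_sbr[3])
    large <- c(large, large_voi_sbr(vol, lv)$measured_sbr[1])
  }
  expect_true(all(diff(small) > 0))
  expect_true(all(diff(large) > 0))
})

test_that("partial volume: tight-VOI SBR falls with FWHM, large-VOI holds", {
  g <- study_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(5, 5),
                       background_concentration = 200, geometry = g)
  sv <- small_voi_set(g)
  nominal <- sum(geometry_masks(g)$striatum_right) * g$voxel_size^3 / 1000
  small <- large <- numeric(0)
  for (f in c(6, 8, 10, 12)) {
    vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = f), seed = 1,
                          noise = FALSE, filter = FALSE)
    small <- c(small, small_voi_sbr(vol, sv)$measured_sbr[3])
    lv <- large_voi_set(g, margin_mm = 2 * f)
    large <- c(large, large_voi_sbr(vol, lv,
                                    nominal_striatal_volume = nominal)$measured_sbr[1])
  }
  expect_true(all(diff(small) < 0))
  expect_lt(diff(range(large)) / mean(large), 0.05)
})

test_that("growing the large-VOI margin beyond 2 x FWHM changes SBR < 1%", {
  g <- study_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(5, 5),
                       background_concentration = 200, geometry = g)
  vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = 12), seed = 1,
                        noise = FALSE, filter = FALSE)
  nominal <- sum(geometry_masks(g)$striatum_right) * g$voxel_size^3 / 1000
  sbrs <- vapply(c(24, 30, 36, 45), function(m)
    large_voi_sbr(vol, large_voi_set(g, margin_mm = m,
                                     reference_erode_mm = 15),
                  nominal_striatal_volume = nominal)$measured_sbr[1], 0)
  expect_lt(diff(range(sbrs)) / mean(sbrs), 0.01)
})

test_that("ACSC with a vanishing PSF recovers the true SBR within 1%", {
  g <- tiny_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(4, 4),
                       background_concentration = 100, geometry = g)
  vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = 0), seed = 1,
                        noise = FALSE, filter = FALSE)
  rec <- small_voi_sbr(vol, small_voi_set(g))
  expect_equal(rec$measured_sbr, rep(4, 6), tolerance = 0.01)
})

test_that("uncorrected modes are biased on noiseless phantoms", {
  g <- tiny_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(5, 5),
                       background_concentration = 100, geometry = g)
  vol <- render_phantom(spec, recon_model("IRNC", psf_fwhm = 8), seed = 1,
                        noise = FALSE)
  lv <- large_voi_set(g, margin_mm = 16)
  expect_lt(max(large_voi_sbr(vol, lv)$measured_sbr), 4.5)
})

test_that("an asymmetric cavity in the background shifts only large-VOI SBR", {
  g <- study_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(4, 4),
                       background_concentration = 100, geometry = g)
  vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = 0), seed = 1,
                        noise = FALSE, filter = FALSE)
  # zero-activity ball (dilated-ventricle analogue) in the left brain
  # background: outside the tight VOIs and the occipital reference, inside
  # the left large VOI's background accounting
  cav <- ellipsoid_mask(c(-40, 20, -20), c(9, 9, 9), g$grid_shape,
                        g$voxel_size)
  vol2 <- vol
  vol2$data[cav] <- 0
  sv <- small_voi_set(g)
  lv <- large_voi_set(g, margin_mm = 20)
  expect_identical(small_voi_sbr(vol2, sv), small_voi_sbr(vol, sv))
  l1 <- large_voi_sbr(vol, lv)$measured_sbr
  l2 <- large_voi_sbr(vol2, lv)$measured_sbr
  expect_gt(max(abs(l2 - l1)), 0.01)
})
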