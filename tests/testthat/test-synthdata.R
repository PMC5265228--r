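# ---- geometry ---------------------------------------------------------------

test_that("geometry invariants hold: disjoint, inside brain, mirror-symmetric", {
  g <- tiny_geometry()
  m <- geometry_masks(g)
  expect_false(any(m$caudate_left & m$putamen_left))
  expect_false(any(m$caudate_right & m$putamen_right))
  expect_false(any((m$striatum_left | m$striatum_right) & !m$brain))
  # mirroring about the mid-sagittal plane flips the first array index
  flip_x <- function(a) a[rev(seq_len(dim(a)[1])), , ]
  expect_identical(m$caudate_left, flip_x(m$caudate_right))
  expect_identical(m$putamen_left, flip_x(m$putamen_right))
  expect_identical(m$striatum_left, m$caudate_left | m$putamen_left)
})

test_that("invalid geometries are rejected", {
  expect_error(striatal_geometry(caudate_radii = c(-1, 5, 5)), "radii")
  expect_error(striatal_geometry(brain_center = c(5, 0, 0)), "mid-sagittal")
  expect_error(striatal_geometry(caudate_center = c(-10, 22, 6)), "right side")
  # caudate dragged onto the putamen
  expect_error(striatal_geometry(caudate_center = c(26, -2, 0)), "overlap")
  # putamen pushed outside the brain
  expect_error(striatal_geometry(putamen_center = c(60, -4, 0),
                                 brain_radii = c(65, 85, 60)), "outside")
})

# ---- reconstruction model ---------------------------------------------------

test_that("recon_model enforces its mode invariants", {
  expect_error(recon_model("ACSC", scatter_fraction = 0.2), "corrections")
  expect_error(recon_model("ACSC", septal_offset = 0.1), "variability")
  expect_error(recon_model("IRNC", scatter_fraction = 0), "uncorrected")
  expect_error(recon_model("IRNC", allow_negative = TRUE), "FBP")
  expect_false(recon_model("IRNC")$allow_negative)
  expect_true(recon_model("FBP")$allow_negative)
})

test_that("Butterworth gain anchors: unity at DC, one half at the cutoff", {
  expect_equal(butterworth_gain(0), 1)
  expect_equal(butterworth_gain(0.55, cutoff = 0.55, power = 10), 0.5)
  expect_lt(butterworth_gain(1.1, cutoff = 0.55, power = 10), 1e-5)
  # the filter conserves total counts (DC gain 1)
  arr <- array(runif(16^3), c(16, 16, 16))
  expect_equal(sum(butterworth_filter(arr, 0.55, 10, 4)), sum(arr),
               tolerance = 1e-12)
})

# ---- rendering --------------------------------------------------------------

test_that("identity pipeline reproduces the activity map exactly", {
  g <- tiny_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(caudate = c(2, 3), putamen = 4),
                       background_concentration = 50, geometry = g)
  rec <- recon_model("ACSC", psf_fwhm = 0)
  vol <- render_phantom(spec, rec, seed = 1, noise = FALSE, filter = FALSE)
  # oracle: build the piecewise-constant map directly from the masks
  m <- geometry_masks(g)
  expected <- array(0, g$grid_shape)
  expected[m$brain] <- 50
  expected[m$caudate_left] <- 50 * 3; expected[m$caudate_right] <- 50 * 4
  expected[m$putamen_left] <- 50 * 5; expected[m$putamen_right] <- 50 * 5
  expect_equal(vol$data, expected, tolerance = 1e-12)
})

test_that("zero-contrast phantom yields SBR about zero despite noise", {
  g <- tiny_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(0, 0),
                       background_concentration = 200, geometry = g)
  vol <- render_phantom(spec, recon_model("ACSC", psf_fwhm = 8), seed = 3)
  rec <- small_voi_sbr(vol, small_voi_set(g))
  expect_true(all(abs(rec$measured_sbr) < 0.05))
})

test_that("rendering is a pure function of (spec, recon, seed)", {
  g <- tiny_geometry()
  spec <- phantom_spec(geometry = g)
  rec <- recon_model("FBP", psf_fwhm = 8)
  v1 <- render_phantom(spec, rec, seed = 7)
  v2 <- render_phantom(spec, rec, seed = 7)
  v3 <- render_phantom(spec, rec, seed = 8)
  expect_identical(v1$data, v2$data)
  expect_false(identical(v1$data, v3$data))
})

test_that("blur and scatter redistribution conserve attenuated counts", {
  g <- tiny_geometry()
  spec <- phantom_spec(true_sbr = sbr_vector(5, 5),
                       background_concentration = 80, geometry = g)
  rec <- recon_model("IRNC", psf_fwhm = 8, scatter_fraction = 0.3,
                     attenuation_scale = 0.5)
  vol <- render_phantom(spec, rec, seed = 1, noise = FALSE, filter = FALSE)
  m <- geometry_masks(g)
  act_sum <- 80 * (sum(m$brain) + 5 * sum(m$striatum_left | m$striatum_right))
  expect_equal(sum(vol$data), act_sum * 0.5, tolerance = 1e-6)
})

test_that("a too-small grid for the blur margin is a geometry error", {
  g <- striatal_geometry(brain_radii = c(60, 60, 55), voxel_size = 4,
                         grid_shape = c(32L, 32L, 32L))
  spec <- phantom_spec(geometry = g)
  expect_error(render_phantom(spec, recon_model("ACSC", psf_fwhm = 12),
                              seed = 1), "grid too small")
})

test_that("phantom validation rejects negative concentrations", {
  expect_error(phantom_spec(background_concentration = 0), "> 0")
  expect_error(phantom_spec(true_sbr = sbr_vector(-1, 2)), "non-negative")
})

# ---- subjects and cohorts ---------------------------------------------------

test_that("putamen-first loss renders lower putaminal than caudate contrast", {
  g <- tiny_geometry()
  s <- subject_spec("S1", 60, "abnormal",
                    true_sbr = sbr_vector(caudate = 6, putamen = 6 * 0.4))
  vol <- render_subject(s, recon_model("ACSC", psf_fwhm = 8), g, seed = 2,
                        noise = FALSE)
  rec <- small_voi_sbr(vol, small_voi_set(g))
  put <- rec$measured_sbr[rec$structure == "putamen"]
  cau <- rec$measured_sbr[rec$structure == "caudate"]
  expect_true(all(put < cau))
})

test_that("seeds change the noise realisation, not the noiseless mean", {
  g <- tiny_geometry()
  s <- subject_spec("S1", 55, "normal", true_sbr = sbr_vector(5, 5))
  rec <- recon_model("ACSC", psf_fwhm = 8)
  n1 <- render_subject(s, rec, g, seed = 1)
  n2 <- render_subject(s, rec, g, seed = 2)
  expect_false(identical(n1$data, n2$data))
  m1 <- render_subject(s, rec, g, seed = 1, noise = FALSE)
  m2 <- render_subject(s, rec, g, seed = 2, noise = FALSE)
  expect_identical(m1$data, m2$data)
})

test_that("cohort sizes, age line and determinism behave as specified", {
  p <- cohort_params(n_normal = 34, n_abnormal = 43, random_seed = 9L)
  cohort <- generate_cohort(p)
  expect_length(cohort, 77)
  status <- vapply(cohort, `[[`, "", "disease_status")
  expect_identical(sum(status == "abnormal"), 43L)
  expect_identical(sum(status == "normal"), 34L)
  # zero scatter collapses every normal subject onto the age line exactly
  p0 <- cohort_params(n_normal = 10, n_abnormal = 0, between_subject_sd = 0,
                      healthy_intercept = 10, healthy_slope = -0.05,
                      random_seed = 4L)
  for (s in generate_cohort(p0))
    expect_equal(unname(s$true_sbr), rep(10 - 0.05 * s$age, 4))
  # pure function of the params
  expect_identical(generate_cohort(p), generate_cohort(p))
})

test_that("abnormal subjects always have a putamen below the healthy line", {
  p <- cohort_params(n_normal = 0, n_abnormal = 60, random_seed = 21L)
  for (s in generate_cohort(p)) {
    line <- p$healthy_intercept + p$healthy_slope * s$age
    expect_lt(min(s$true_sbr[c("putamen_left", "putamen_right")]), line)
  }
})

test_that("normal subjects scatter around the healthy age line", {
  p <- cohort_params(n_normal = 250, n_abnormal = 0, between_subject_sd = 0.5,
                     random_seed = 31L)
  cohort <- generate_cohort(p)
  resid <- vapply(cohort, function(s)
    s$true_sbr[["putamen_left"]] -
      (p$healthy_intercept + p$healthy_slope * s$age), 0)
  expect_lt(abs(mean(resid)), 3 * 0.5 / sqrt(250))
  expect_equal(sd(resid), 0.5, tolerance = 0.15)
})

# ---- closed-form surrogate --------------------------------------------------

test_that("closed-form measured SBR is the stated linear map", {
  expect_equal(closed_form_measured_sbr(4.2), 4.2)
  expect_equal(closed_form_measured_sbr(6.0, a = 0.5, b = 0.1), 3.1)
  expect_error(closed_form_measured_sbr(1, a = 0), "> 0")
  expect_error(closed_form_measured_sbr(1, noise_sd = 0.1), "seed")
  draws <- closed_form_measured_sbr(rep(5, 10000), a = 1, b = 0,
                                    noise_sd = 0.2, seed = 12)
  expect_equal(sd(draws), 0.2, tolerance = 0.05 * 0.2)
})
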