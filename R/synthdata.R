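#' Per-structure true specific binding ratios
#'
#' Helper building the named SBR vector used by phantom and subject specs
#' (`caudate_left`, `caudate_right`, `putamen_left`, `putamen_right`).
#'
#' @param caudate,putamen scalar SBR applied to both sides, or length-2
#'   `c(left, right)`.
#' @return named numeric vector of length 4.
#' @export
sbr_vector <- function(caudate, putamen) {
  expand <- function(x) if (length(x) == 1L) c(x, x) else x[1:2]
  ca <- expand(caudate); pu <- expand(putamen)
  c(caudate_left = ca[1], caudate_right = ca[2],
    putamen_left = pu[1], putamen_right = pu[2])
}

.sbr_names <- c("caudate_left", "caudate_right",
                "putamen_left", "putamen_right")

check_sbr_vector <- function(true_sbr) {
  if (is.null(names(true_sbr)) || !all(.sbr_names %in% names(true_sbr)))
    stop("true_sbr must be named: ", paste(.sbr_names, collapse = ", "),
         call. = FALSE)
  v <- true_sbr[.sbr_names]
  if (anyNA(v) || any(v < 0))
    stop("true SBRs must be non-negative and finite", call. = FALSE)
  v
}

#' Phantom specification
#'
#' A digital analogue of the anthropomorphic striatal calibration phantom:
#' known uptake ratios in the striatal compartments over a uniform
#' background compartment filling the brain.
#'
#' @param true_sbr named SBR vector, see [sbr_vector()].
#' @param background_concentration mean background counts per voxel (> 0).
#' @param geometry a [striatal_geometry()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_sbr = sbr_vector(caudate = 5, putamen = 5),
                         background_concentration = 60,
                         geometry = striatal_geometry()) {
  true_sbr <- check_sbr_vector(true_sbr)
  if (background_concentration <= 0)
    stop("background_concentration must be > 0", call. = FALSE)
  stopifnot(inherits(geometry, "striatal_geometry"))
  structure(list(true_sbr = true_sbr,
                 background_concentration = background_concentration,
                 geometry = geometry),
            class = "phantom_spec")
}

#' Subject specification
#'
#' Ground truth for one synthetic subject: age, disease status, per-side
#' per-structure true SBRs and the scanner the subject is imaged on.
#'
#' @param subject_id character id.
#' @param age age in years.
#' @param disease_status `"normal"` or `"abnormal"`.
#' @param true_sbr named SBR vector, see [sbr_vector()].
#' @param scanner_id character scanner id.
#' @param age_range plausibility bounds for `age`.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, age,
                         disease_status = c("normal", "abnormal"),
                         true_sbr, scanner_id = "scanner1",
                         age_range = c(18, 95)) {
  disease_status <- match.arg(disease_status)
  if (age < age_range[1] || age > age_range[2])
    stop("age ", age, " outside plausible range [",
         age_range[1], ", ", age_range[2], "]", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), age = as.numeric(age),
                 disease_status = disease_status,
                 true_sbr = check_sbr_vector(true_sbr),
                 scanner_id = as.character(scanner_id)),
            class = "subject_spec")
}

#' Cohort generation parameters
#'
#' The stated world of the synthetic cohorts: healthy striatal SBR declines
#' linearly with age (`healthy_intercept + healthy_slope * age`) with
#' between-subject Gaussian scatter; abnormal subjects additionally lose
#' putaminal (and to a lesser degree caudate) binding asymmetrically,
#' putamen-first, as in nigrostriatal degeneration.
#'
#' @param n_normal,n_abnormal cohort sizes (>= 0).
#' @param age_range uniform age sampling range, years.
#' @param healthy_intercept healthy striatal SBR extrapolated to age 0.
#' @param healthy_slope SBR change per year (< 0).
#' @param between_subject_sd SD of the healthy scatter around the age line.
#' @param putamen_loss_range multiplicative loss factor range (worse side)
#'   for abnormal putamina, in (0, 1].
#' @param caudate_loss_range as above for the caudate.
#' @param asymmetry_range range of the relative left/right difference of the
#'   loss factors (the better side keeps up to this much more binding).
#' @param random_seed integer seed; cohorts are pure functions of the params.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_normal = 34, n_abnormal = 43,
                          age_range = c(20, 83),
                          healthy_intercept = 10, healthy_slope = -0.05,
                          between_subject_sd = 1.0,
                          putamen_loss_range = c(0.2, 0.7),
                          caudate_loss_range = c(0.5, 1.0),
                          asymmetry_range = c(0, 0.3),
                          random_seed = 1L) {
  if (n_normal < 0 || n_abnormal < 0)
    stop("cohort sizes must be >= 0", call. = FALSE)
  if (length(age_range) != 2L || diff(age_range) <= 0)
    stop("age_range must be an increasing length-2 interval", call. = FALSE)
  if (healthy_slope >= 0) stop("healthy_slope must be < 0", call. = FALSE)
  for (r in list(putamen_loss_range, caudate_loss_range))
    if (any(r <= 0) || any(r > 1) || diff(r) < 0)
      stop("loss factor ranges must be increasing intervals in (0, 1]",
           call. = FALSE)
  if (any(asymmetry_range < 0) || diff(asymmetry_range) < 0)
    stop("asymmetry_range must be an increasing non-negative interval",
         call. = FALSE)
  structure(list(n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 age_range = as.numeric(age_range),
                 healthy_intercept = healthy_intercept,
                 healthy_slope = healthy_slope,
                 between_subject_sd = between_subject_sd,
                 putamen_loss_range = as.numeric(putamen_loss_range),
                 caudate_loss_range = as.numeric(caudate_loss_range),
                 asymmetry_range = as.numeric(asymmetry_range),
                 random_seed = as.integer(random_seed)),
            class = "cohort_params")
}

# ---- rendering --------------------------------------------------------------

check_blur_margin <- function(geometry, psf_fwhm) {
  fov <- geometry$grid_shape * geometry$voxel_size
  extent <- 2 * geometry$brain_radii +
    abs(geometry$brain_center) * 2 + 2 * psf_fwhm
  if (any(extent > fov))
    stop("grid too small: brain plus 2 x FWHM margin (",
         paste(round(extent), collapse = "/"), " mm) exceeds the field of ",
         "view (", paste(fov, collapse = "/"), " mm)", call. = FALSE)
  invisible(TRUE)
}

#' Render a striatal phantom volume
#'
#' Builds a piecewise-constant activity map (structure concentration =
#' background x (1 + true SBR), uniform background over the brain), then
#' applies the image-space reconstruction model: attenuation scaling, PSF
#' blur, scatter redistribution (a fraction of total counts spread over the
#' brain mask blurred at twice the PSF), voxelwise Poisson noise (plus
#' zero-mean Gaussian noise in FBP mode), Butterworth post-filtering, and
#' clipping of negative values unless the mode allows them.
#'
#' @param spec a [phantom_spec()].
#' @param recon a [recon_model()].
#' @param seed integer seed; rendering is a pure function of
#'   `(spec, recon, seed)`.
#' @param noise apply Poisson (and FBP Gaussian) noise; disable for
#'   analytic tests.
#' @param filter apply the Butterworth post-filter.
#' @param subject_variability draw this render's scatter fraction,
#'   attenuation scale and septal-penetration offset from the model's
#'   between-subject distributions (anatomy-dependent uncorrected effects).
#'   Off by default: a physical calibration phantom is the same object in
#'   every scan session.
#' @return A [count_volume()].
#' @export
render_phantom <- function(spec, recon, seed, noise = TRUE, filter = TRUE,
                           subject_variability = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(recon, "recon_model"))
  g <- spec$geometry
  check_blur_margin(g, recon$psf_fwhm)
  m <- geometry_masks(g)
  seed <- as.integer(seed)

  scatter_fraction <- recon$scatter_fraction
  attenuation_scale <- recon$attenuation_scale
  septal_offset <- recon$septal_offset
  if (subject_variability) {
    jit <- withr::with_seed(seed, stats::rnorm(3))
    scatter_fraction <- min(max(
      scatter_fraction + jit[1] * recon$scatter_fraction_sd, 0), 0.9)
    attenuation_scale <- min(max(
      attenuation_scale + jit[2] * recon$attenuation_scale_sd, 0.05), 1)
    septal_offset <- max(septal_offset + jit[3] * recon$septal_offset_sd, 0)
  }

  bg <- spec$background_concentration
  act <- array(0, dim = g$grid_shape)
  act[m$brain] <- bg
  sbr <- spec$true_sbr
  act[m$caudate_left]  <- bg * (1 + sbr[["caudate_left"]])
  act[m$caudate_right] <- bg * (1 + sbr[["caudate_right"]])
  act[m$putamen_left]  <- bg * (1 + sbr[["putamen_left"]])
  act[m$putamen_right] <- bg * (1 + sbr[["putamen_right"]])

  img <- act * attenuation_scale
  img <- gaussian_blur(img, recon$psf_fwhm, g$voxel_size)
  if (scatter_fraction > 0 || septal_offset > 0) {
    field <- gaussian_blur(m$brain + 0, 2 * recon$psf_fwhm, g$voxel_size)
    norm_field <- field / sum(field)
    if (scatter_fraction > 0)
      img <- (1 - scatter_fraction) * img +
        scatter_fraction * sum(img) * norm_field
    if (septal_offset > 0)
      img <- img + septal_offset * bg * attenuation_scale *
        field / max(field)
  }
  if (noise) {
    # Poisson statistics are those of the physically detected counts: draw
    # at mean * count_scale and rescale, so a corrected image (restored
    # mean) keeps the noise of its attenuated acquisition.
    cs <- recon$count_scale
    img <- withr::with_seed(seed + 1L, {
      out <- array(stats::rpois(length(img), pmax(img * cs, 0)) / cs,
                   dim = dim(img))
      if (recon$fbp_noise_sd > 0)
        out <- out + stats::rnorm(length(out), sd = recon$fbp_noise_sd)
      out
    })
  }
  if (filter)
    img <- butterworth_filter(img, recon$butterworth_cutoff,
                              recon$butterworth_power, g$voxel_size)
  if (!recon$allow_negative) img[img < 0] <- 0
  count_volume(img, g$voxel_size)
}

#' Render a subject volume
#'
#' Renders a subject scan by reusing the phantom renderer with the
#' subject's per-side true SBRs placed in the given geometry.
#'
#' @param spec a [subject_spec()].
#' @param recon a [recon_model()].
#' @param geometry a [striatal_geometry()].
#' @param seed integer seed.
#' @param background_concentration mean background counts per voxel.
#' @param ... passed to [render_phantom()] (`noise`, `filter`).
#' @return A [count_volume()].
#' @export
render_subject <- function(spec, recon, geometry, seed,
                           background_concentration = 60, ...) {
  stopifnot(inherits(spec, "subject_spec"))
  ph <- phantom_spec(true_sbr = spec$true_sbr,
                     background_concentration = background_concentration,
                     geometry = geometry)
  render_phantom(ph, recon, seed = seed, ...)
}

#' Generate a synthetic cohort
#'
#' Draws `n_normal + n_abnormal` subject specifications. Ages are uniform in
#' `age_range`; the healthy true striatal SBR is
#' `healthy_intercept + healthy_slope * age + N(0, between_subject_sd)`,
#' applied symmetrically to caudate and putamen. Abnormal subjects multiply
#' the putamen (and caudate) SBR by loss factors drawn from the configured
#' ranges; the worse side is chosen at random and the better side retains up
#' to `asymmetry_range` relatively more binding. Abnormal draws are rejected
#' (and redrawn) until at least one putaminal SBR lies below the healthy age
#' line, the defining property of an expected-abnormal scan.
#'
#' @param params a [cohort_params()].
#' @param scanner_ids character vector; subjects are assigned round-robin.
#' @return list of [subject_spec()] objects (normals first).
#' @export
generate_cohort <- function(params, scanner_ids = "scanner1") {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_normal + params$n_abnormal
  status <- rep(c("normal", "abnormal"), c(params$n_normal, params$n_abnormal))
  withr::with_seed(params$random_seed, {
    ages <- stats::runif(n, params$age_range[1], params$age_range[2])
    lapply(seq_len(n), function(i) {
      base <- params$healthy_intercept + params$healthy_slope * ages[i] +
        stats::rnorm(1, 0, params$between_subject_sd)
      base <- max(base, 0.05)
      sbr <- sbr_vector(caudate = base, putamen = base)
      if (status[i] == "abnormal") {
        line <- params$healthy_intercept + params$healthy_slope * ages[i]
        for (attempt in 1:100) {
          worse_left <- stats::runif(1) < 0.5
          f_put <- stats::runif(1, params$putamen_loss_range[1],
                                params$putamen_loss_range[2])
          f_cau <- stats::runif(1, params$caudate_loss_range[1],
                                params$caudate_loss_range[2])
          asym <- stats::runif(2, params$asymmetry_range[1],
                               params$asymmetry_range[2])
          put <- c(f_put, min(f_put * (1 + asym[1]), 1))
          cau <- c(f_cau, min(f_cau * (1 + asym[2]), 1))
          if (!worse_left) { put <- rev(put); cau <- rev(cau) }
          cand <- sbr_vector(caudate = base * cau, putamen = base * put)
          if (min(cand[c("putamen_left", "putamen_right")]) < line) break
        }
        sbr <- cand
      }
      subject_spec(subject_id = sprintf("S%03d", i), age = ages[i],
                   disease_status = status[i], true_sbr = sbr,
                   scanner_id = scanner_ids[(i - 1L) %% length(scanner_ids) + 1L],
                   age_range = params$age_range + c(-1, 1))
    })
  })
}

#' Cohort ground truth as a table
#'
#' Long-format truth table (one row per subject-side-structure), the layout
#' used for the cohort CSV export.
#'
#' @param cohort list of [subject_spec()] objects.
#' @return data.frame with columns `subject_id`, `age`, `disease_status`,
#'   `scanner_id`, `side`, `structure`, `true_sbr`.
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    key <- strsplit(.sbr_names, "_", fixed = TRUE)
    data.frame(subject_id = s$subject_id, age = s$age,
               disease_status = s$disease_status, scanner_id = s$scanner_id,
               side = vapply(key, `[`, "", 2L),
               structure = vapply(key, `[`, "", 1L),
               true_sbr = unname(s$true_sbr[.sbr_names]),
               stringsAsFactors = FALSE)
  }))
}

#' Closed-form measured SBR surrogate
#'
#' Fast image-free surrogate for the measurement process: the measured SBR
#' is `a * true + b + N(0, noise_sd)`, the same linear form the phantom
#' calibration assumes. Used where rendering full volumes is unnecessary.
#'
#' @param true_sbr true SBR value(s).
#' @param a,b linear bias coefficients (`a > 0`).
#' @param noise_sd measurement noise SD.
#' @param seed integer seed; required when `noise_sd > 0`.
#' @return numeric vector of measured SBRs.
#' @export
closed_form_measured_sbr <- function(true_sbr, a = 1, b = 0, noise_sd = 0,
                                     seed = NULL) {
  if (a <= 0) stop("slope a must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  base <- a * true_sbr + b
  if (noise_sd == 0) return(base)
  if (is.null(seed)) stop("a seed is required when noise_sd > 0", call. = FALSE)
  withr::with_seed(as.integer(seed),
                   base + stats::rnorm(length(base), sd = noise_sd))
}
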