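# Shared fixtures: everything is generated in code at test time.

# Coarse, fast geometry for rendering tests (~32k voxels, 4 mm).
tiny_geometry <- function() {
  striatal_geometry(brain_radii = c(60, 68, 52),
                    voxel_size = 4,
                    grid_shape = c(40L, 44L, 36L))
}

# A hand-sized VOI set on a 5x5x5 grid: target = 8-voxel corner cube,
# reference = 8-voxel opposite corner.
toy_voi_set <- function() {
  labels <- array(0L, c(5, 5, 5))
  labels[1:2, 1:2, 1:2] <- 1L   # caudate left
  labels[4:5, 1:2, 1:2] <- 2L   # caudate right
  labels[1:2, 4:5, 1:2] <- 3L   # putamen left
  labels[4:5, 4:5, 1:2] <- 4L   # putamen right
  labels[2:4, 2:4, 4:5] <- 5L   # reference
  codes <- data.frame(
    code = 1:5,
    side = c("left", "right", "left", "right", "both"),
    structure = c("caudate", "caudate", "putamen", "putamen", "occipital"),
    role = c(rep("target", 4), "reference"),
    stringsAsFactors = FALSE)
  voi_set(labels, codes, voxel_size = 2)
}

# Exhaustive pair-counting AUC oracle (ties count one half), independent of
# the rank-based implementation under test. Lower score = abnormal.
brute_force_auc <- function(scores, labels) {
  pos <- -scores[labels]; neg <- -scores[!labels]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Closed-form OLS oracle used against the calibration and normal-range fits.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Small study configuration: full grid, desk-second scale.
mini_study_config <- function(seed = 11L) {
  study_config(
    geometry = tiny_geometry(),
    scanners = list(
      scannerA = list(psf_fwhm = 10, scatter_fraction = 0.25,
                      attenuation_scale = 0.55, fbp_noise_sd = 8,
                      scatter_fraction_sd = 0.05, attenuation_scale_sd = 0.04,
                      septal_offset = 0.08, septal_offset_sd = 0.05),
      scannerB = list(psf_fwhm = 12, scatter_fraction = 0.35,
                      attenuation_scale = 0.45, fbp_noise_sd = 12,
                      scatter_fraction_sd = 0.05, attenuation_scale_sd = 0.04,
                      septal_offset = 0.08, septal_offset_sd = 0.05)),
    modes = c("ACSC", "IRNC"),
    phantom_true_sbrs = c(1, 4, 8),
    normal_cohort = cohort_params(n_normal = 24, n_abnormal = 0,
                                  random_seed = 5L),
    followup_cohort = cohort_params(n_normal = 8, n_abnormal = 10,
                                    age_range = c(25, 84), random_seed = 6L),
    seed = seed)
}
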