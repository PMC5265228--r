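#' Study configuration
#'
#' A single configuration drives the full study grid: synthetic phantom
#' calibration per scanner and reconstruction, normal-database construction
#' on a healthy cohort, classification of a follow-up cohort, and paired
#' diagnostic evaluation for every reconstruction x quantifier x
#' calibration x rule cell.
#'
#' @param geometry a [striatal_geometry()]; the default is the desk-scale
#'   [study_geometry()] (64^3 voxels at 3 mm).
#' @param scanners named list; each scanner is a list with `psf_fwhm` (mm),
#'   `scatter_fraction`, `attenuation_scale` and `fbp_noise_sd` describing
#'   its uncorrected behaviour. Modes are derived per scanner: ACSC keeps
#'   only the PSF (corrections applied), IRNC adds scatter and attenuation
#'   losses, FBP additionally allows negatives and adds Gaussian noise.
#' @param modes reconstruction modes to run.
#' @param phantom_true_sbrs true striatal SBR levels of the calibration
#'   phantom set (config-driven; the physical calibration protocol's levels
#'   are not prescribed here).
#' @param phantom_background phantom background concentration, counts/voxel.
#' @param subject_background subject background concentration, counts/voxel.
#' @param normal_cohort a [cohort_params()] for the normal database
#'   (healthy subjects only).
#' @param followup_cohort a [cohort_params()] for the mixed follow-up
#'   cohort.
#' @param followup_scanners scanner ids used by the follow-up cohort
#'   (a subset of `names(scanners)`, like the two clinical sites).
#' @param rules scan rules to evaluate; tight-VOI rules pair with the
#'   small-VOI quantifier, `southampton_striatal` with the large-VOI one.
#' @param bound_multiplier normal-range half width in SE units.
#' @param prediction_interval use the individual-level (prediction) form of
#'   the normal-range SE rather than the SE of the predicted mean. The
#'   study default is `TRUE`: with a database of a hundred-plus subjects
#'   the mean-SE band collapses to a sliver that misclassifies nearly half
#'   of healthy individuals, while classification of single scans against a
#'   normal range is inherently an individual-level statement.
#' @param tight_erode_voxels erosion of the tight target VOIs.
#' @param large_margin_factor large-VOI dilation margin as a multiple of
#'   the scanner's effective resolution ([effective_fwhm()]: PSF plus
#'   Butterworth filter in quadrature).
#' @param seed master seed; every random draw in the study derives from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(geometry = study_geometry(),
                         scanners = default_scanners(),
                         modes = c("ACSC", "IRNC", "FBP"),
                         phantom_true_sbrs = c(1, 3, 5, 8),
                         phantom_background = 200,
                         subject_background = 60,
                         normal_cohort = cohort_params(
                           n_normal = 123, n_abnormal = 0, random_seed = 1L),
                         followup_cohort = cohort_params(
                           n_normal = 34, n_abnormal = 43,
                           age_range = c(25, 84), random_seed = 2L),
                         followup_scanners = NULL,
                         rules = c("striatum_either_side",
                                   "putamen_either_side",
                                   "southampton_striatal"),
                         bound_multiplier = 2,
                         prediction_interval = TRUE,
                         tight_erode_voxels = 1L,
                         large_margin_factor = 2,
                         seed = 1L) {
  stopifnot(inherits(geometry, "striatal_geometry"),
            inherits(normal_cohort, "cohort_params"),
            inherits(followup_cohort, "cohort_params"))
  modes <- match.arg(modes, c("ACSC", "IRNC", "FBP"), several.ok = TRUE)
  bad <- setdiff(rules, names(.scan_rules))
  if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(names(scanners)) || any(names(scanners) == ""))
    stop("scanners must be a named list", call. = FALSE)
  if (is.null(followup_scanners))
    followup_scanners <- utils::head(names(scanners), 2L)
  if (!all(followup_scanners %in% names(scanners)))
    stop("followup_scanners must be a subset of the configured scanners",
         call. = FALSE)
  if (length(phantom_true_sbrs) < 2L)
    stop("need at least 2 phantom SBR levels to calibrate", call. = FALSE)
  structure(list(geometry = geometry, scanners = scanners, modes = modes,
                 phantom_true_sbrs = phantom_true_sbrs,
                 phantom_background = phantom_background,
                 subject_background = subject_background,
                 normal_cohort = normal_cohort,
                 followup_cohort = followup_cohort,
                 followup_scanners = followup_scanners,
                 rules = rules, bound_multiplier = bound_multiplier,
                 prediction_interval = isTRUE(prediction_interval),
                 tight_erode_voxels = as.integer(tight_erode_voxels),
                 large_margin_factor = large_margin_factor,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Default scanner fleet
#'
#' Three scanners spanning a realistic range of SPECT system behaviour:
#' post-filter resolution 10-12 mm FWHM (modern systems are similar once
#' clinical radii of rotation and typical filters are applied), 25-35%
#' scatter/septal-penetration background and roughly half the signal lost
#' to attenuation when uncorrected, with FBP noise growing with the scatter
#' burden. The `*_sd` entries are between-subject SDs of the uncorrected
#' effects (anatomy-dependent attenuation and septal penetration), which
#' only IRNC and FBP renders see; `septal_offset` is the mean extra-brain
#' septal background as a fraction of the background concentration.
#'
#' @return named list of scanner descriptions for [study_config()].
#' @export
default_scanners <- function() {
  list(
    scanner1 = list(psf_fwhm = 10, scatter_fraction = 0.25,
                    attenuation_scale = 0.55, fbp_noise_sd = 8,
                    scatter_fraction_sd = 0.05, attenuation_scale_sd = 0.04,
                    septal_offset = 0.08, septal_offset_sd = 0.05),
    scanner2 = list(psf_fwhm = 11, scatter_fraction = 0.30,
                    attenuation_scale = 0.50, fbp_noise_sd = 10,
                    scatter_fraction_sd = 0.05, attenuation_scale_sd = 0.04,
                    septal_offset = 0.08, septal_offset_sd = 0.05),
    scanner3 = list(psf_fwhm = 12, scatter_fraction = 0.35,
                    attenuation_scale = 0.45, fbp_noise_sd = 12,
                    scatter_fraction_sd = 0.05, attenuation_scale_sd = 0.04,
                    septal_offset = 0.08, septal_offset_sd = 0.05))
}

#' Reconstruction model of a scanner under a given mode
#'
#' @param scanner one element of [default_scanners()].
#' @param mode `"ACSC"`, `"IRNC"` or `"FBP"`.
#' @return A [recon_model()].
#' @export
scanner_recon <- function(scanner, mode) {
  v <- function(f) scanner[[f]] %||% 0
  switch(mode,
    ACSC = recon_model("ACSC", psf_fwhm = scanner$psf_fwhm,
                       count_scale = scanner$attenuation_scale),
    IRNC = recon_model("IRNC", psf_fwhm = scanner$psf_fwhm,
                       scatter_fraction = scanner$scatter_fraction,
                       attenuation_scale = scanner$attenuation_scale,
                       scatter_fraction_sd = v("scatter_fraction_sd"),
                       attenuation_scale_sd = v("attenuation_scale_sd"),
                       septal_offset = v("septal_offset"),
                       septal_offset_sd = v("septal_offset_sd")),
    FBP = recon_model("FBP", psf_fwhm = scanner$psf_fwhm,
                      scatter_fraction = scanner$scatter_fraction,
                      attenuation_scale = scanner$attenuation_scale,
                      fbp_noise_sd = scanner$fbp_noise_sd,
                      scatter_fraction_sd = v("scatter_fraction_sd"),
                      attenuation_scale_sd = v("attenuation_scale_sd"),
                      septal_offset = v("septal_offset"),
                      septal_offset_sd = v("septal_offset_sd")),
    stop("unknown mode: ", mode, call. = FALSE))
}

rule_quantifier <- function(rule) {
  if (rule == "southampton_striatal") "large_voi" else "small_voi"
}

# Deterministic sub-seed stream: every random call site in the study takes
# the next sub-seed, all derived from the master seed.
make_seed_stream <- function(master_seed, n = 20000L) {
  seeds <- withr::with_seed(master_seed,
                            sample.int(.Machine$integer.max - 1L, n))
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > n) stop("seed stream exhausted", call. = FALSE)
    seeds[i]
  }
}

quantify_both <- function(volume, small_vois, large_vois, nominal_ml, meta) {
  rbind(small_voi_sbr(volume, small_vois, meta = meta),
        large_voi_sbr(volume, large_vois,
                      nominal_striatal_volume = nominal_ml, meta = meta))
}

#' Run the full synthetic study
#'
#' Executes the complete pipeline for every cell of the study grid:
#' \enumerate{
#'   \item renders calibration phantoms for each scanner x reconstruction,
#'     quantifies them with both quantifiers and fits measured-vs-true
#'     calibration lines per structure;
#'   \item renders the healthy cohort under every reconstruction, quantifies
#'     it, and fits age-dependent normal ranges per (mode, quantifier,
#'     calibrated flag, structure, side) from calibrated and raw values;
#'   \item renders and quantifies the follow-up cohort, converts SBRs via
#'     the calibration lines (or passes them through raw), classifies every
#'     scan under each rule against the matching normal range, and
#'   \item evaluates each cell: FP/FN counts, sensitivity, specificity and
#'     DeLong ROC AUC of the age-unadjusted scan scores.
#' }
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, the report grid, the
#'   per-subject discordance matrix, the SBR tables (CSV), the calibration
#'   lines and normal-range models (JSON) are written there.
#' @param progress print per-stage progress lines.
#' @return list of class `study_result` with elements `report` (one row per
#'   rule x mode x calibration cell), `discordance` (subject x cell verdict
#'   matrix), `calibration` (the [calibration_set()]), `normal_models`,
#'   `normal_records`, `followup_records` and `truth`.
#' @export
run_study <- function(config, out_dir = NULL, progress = interactive()) {
  stopifnot(inherits(config, "study_config"))
  g <- config$geometry
  next_seed <- make_seed_stream(config$seed)
  say <- function(...) if (progress) message(sprintf(...))

  nominal_ml <- 4 / 3 * pi * (prod(g$caudate_radii) + prod(g$putamen_radii)) / 1000
  small_vois <- small_voi_set(g, erode_voxels = config$tight_erode_voxels)
  large_vois_by_scanner <- lapply(config$scanners, function(sc) {
    eff <- effective_fwhm(scanner_recon(sc, config$modes[1]))
    large_voi_set(g, margin_mm = config$large_margin_factor * eff)
  })

  # ---- stage 1: phantom calibration ---------------------------------------
  say("calibration: %d scanners x %d modes x %d phantom levels",
      length(config$scanners), length(config$modes),
      length(config$phantom_true_sbrs))
  cal_records <- list()
  for (sid in names(config$scanners)) {
    sc <- config$scanners[[sid]]
    for (mode in config$modes) {
      recon <- scanner_recon(sc, mode)
      for (lev in config$phantom_true_sbrs) {
        ph <- phantom_spec(true_sbr = sbr_vector(caudate = lev, putamen = lev),
                           background_concentration = config$phantom_background,
                           geometry = g)
        vol <- render_phantom(ph, recon, seed = next_seed())
        rec <- quantify_both(vol, small_vois, large_vois_by_scanner[[sid]],
                             nominal_ml,
                             meta = list(subject_id = sprintf("phantom_%g", lev),
                                         scanner_id = sid, mode = mode))
        rec$true_sbr <- lev
        cal_records[[length(cal_records) + 1L]] <- rec
      }
    }
  }
  cal_records <- do.call(rbind, cal_records)
  cal_lines <- list()
  for (key in unique(with(cal_records,
                          paste(scanner_id, mode, quantifier, structure,
                                sep = "|")))) {
    part <- strsplit(key, "|", fixed = TRUE)[[1]]
    sel <- cal_records$scanner_id == part[1] & cal_records$mode == part[2] &
      cal_records$quantifier == part[3] & cal_records$structure == part[4]
    sub <- cal_records[sel, ]
    # pool both sides of the phantom into one scanner line
    cal_lines[[key]] <- fit_calibration(sub$measured_sbr, sub$true_sbr,
                                        scanner_id = part[1], mode = part[2],
                                        quantifier = part[3],
                                        structure = part[4])
  }
  cal_set <- calibration_set(unname(cal_lines))

  # ---- stage 2: cohorts ---------------------------------------------------
  render_cohort <- function(cohort, label) {
    recs <- vector("list", length(cohort) * length(config$modes))
    k <- 0L
    for (s in cohort) {
      sc <- config$scanners[[s$scanner_id]]
      for (mode in config$modes) {
        recon <- scanner_recon(sc, mode)
        vol <- render_subject(s, recon, g, seed = next_seed(),
                              background_concentration = config$subject_background,
                              subject_variability = TRUE)
        k <- k + 1L
        recs[[k]] <- quantify_both(
          vol, small_vois, large_vois_by_scanner[[s$scanner_id]], nominal_ml,
          meta = list(subject_id = s$subject_id, age = s$age,
                      scanner_id = s$scanner_id, mode = mode))
      }
    }
    say("%s cohort: %d subjects rendered under %d modes", label,
        length(cohort), length(config$modes))
    do.call(rbind, recs)
  }

  normal_cohort <- generate_cohort(config$normal_cohort,
                                   scanner_ids = names(config$scanners))
  followup_cohort <- generate_cohort(config$followup_cohort,
                                     scanner_ids = config$followup_scanners)
  normal_records <- render_cohort(normal_cohort, "normal-database")
  followup_records <- render_cohort(followup_cohort, "follow-up")

  truth <- stats::setNames(
    vapply(followup_cohort, function(s) s$disease_status == "abnormal", TRUE),
    vapply(followup_cohort, `[[`, "", "subject_id"))
  ages <- stats::setNames(vapply(followup_cohort, `[[`, 0, "age"),
                          names(truth))

  # ---- stage 3: normal ranges ---------------------------------------------
  normal_models <- list()
  for (calibrated in c(TRUE, FALSE)) {
    pooled <- pool_calibrated(normal_records, cal_set,
                              passthrough = !calibrated)
    for (mode in config$modes)
      for (quant in c("small_voi", "large_voi"))
        for (side in c("left", "right")) {
          structs <- if (quant == "large_voi") "striatum"
          else c("caudate", "putamen", "striatum")
          for (structure in structs) {
            sel <- pooled$mode == mode & pooled$quantifier == quant &
              pooled$side == side & pooled$structure == structure
            sub <- pooled[sel, ]
            key <- paste(mode, quant, calibrated, structure, side, sep = "|")
            normal_models[[key]] <- suppressWarnings(fit_normal_range(
              sub$age, sub$calibrated_sbr,
              bound_multiplier = config$bound_multiplier,
              prediction_interval = config$prediction_interval,
              meta = list(quantifier = quant, mode = mode,
                          calibrated = calibrated, structure = structure,
                          side = side)))
          }
        }
  }
  say("normal ranges: %d models fitted", length(normal_models))

  # ---- stage 4: classification + evaluation -------------------------------
  report <- list()
  discordance <- list()
  for (calibrated in c(TRUE, FALSE)) {
    followup <- pool_calibrated(followup_records, cal_set,
                                passthrough = !calibrated)
    for (mode in config$modes)
      for (rule in config$rules) {
        quant <- rule_quantifier(rule)
        cell <- sprintf("%s_%s_%s", rule, mode,
                        if (calibrated) "cal" else "raw")
        verdicts <- list()
        scores <- numeric(0)
        for (sid in names(truth)) {
          sel <- followup$subject_id == sid & followup$mode == mode &
            followup$quantifier == quant
          sub <- followup[sel, ]
          need <- rule_regions(rule)
          flags <- data.frame(side = sub$side, structure = sub$structure,
                              abnormal = NA)
          for (i in seq_len(nrow(sub))) {
            key <- paste(mode, quant, calibrated, sub$structure[i],
                         sub$side[i], sep = "|")
            model <- normal_models[[key]]
            if (is.null(model))
              stop("no normal-range model for cell ", key, call. = FALSE)
            flags$abnormal[i] <- classify_region(sub$calibrated_sbr[i],
                                                 model, ages[[sid]])
          }
          verdicts[[sid]] <- classify_scan(flags, rule = rule,
                                           subject_id = sid)
          scores[sid] <- scan_score(sub, rule)
        }
        ct <- confusion(verdicts, truth)
        roc <- roc_auc(scores[names(truth)], unname(truth))
        report[[cell]] <- data.frame(
          rule = rule, quantifier = quant, mode = mode,
          calibrated = calibrated,
          auc = roc$auc, auc_lo = roc$ci[1], auc_hi = roc$ci[2],
          sensitivity = sensitivity(ct), specificity = specificity(ct),
          fp = ct$fp, fn = ct$fn, stringsAsFactors = FALSE)
        discordance[[cell]] <-
          vapply(verdicts, `[[`, TRUE, "scan_abnormal")[names(truth)]
        say("cell %-40s sens %5.1f  spec %5.1f  AUC %.3f", cell,
            report[[cell]]$sensitivity, report[[cell]]$specificity, roc$auc)
      }
  }
  report <- do.call(rbind, c(report, make.row.names = FALSE))
  discordance <- as.data.frame(discordance, check.names = FALSE)
  discordance <- cbind(subject_id = names(truth),
                       truth_abnormal = unname(truth), discordance)
  rownames(discordance) <- NULL

  result <- structure(list(report = report, discordance = discordance,
                           calibration = cal_set,
                           normal_models = normal_models,
                           normal_records = normal_records,
                           followup_records = followup_records,
                           truth = truth, config = config),
                      class = "study_result")
  if (!is.null(out_dir)) write_study_result(result, out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$report[, c("rule", "mode", "calibrated", "auc",
                     "sensitivity", "specificity", "fp", "fn")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study result to disk
#'
#' Writes the report grid and the discordance matrix as CSV, the SBR tables
#' as CSV, and the calibration lines and normal-range models as JSON.
#'
#' @param result a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sbr_table(result$normal_records,
                  file.path(out_dir, "normal_sbr.csv"))
  write_sbr_table(result$followup_records,
                  file.path(out_dir, "followup_sbr.csv"))
  utils::write.csv(result$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$discordance, file.path(out_dir, "discordance.csv"),
                   row.names = FALSE)
  write_calibration_json(result$calibration,
                         file.path(out_dir, "calibration.json"))
  write_normal_models_json(result$normal_models,
                           file.path(out_dir, "normal_models.json"))
  invisible(out_dir)
}
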