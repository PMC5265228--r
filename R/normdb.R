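#' Fit an age-dependent normal range
#'
#' Assumes a negative linear relationship between healthy striatal SBR and
#' age and fits it by ordinary least squares. The normal range around the
#' fit is `fit(x) +/- bound_multiplier * SE_pred(x)` where, by default,
#' `SE_pred(x) = s * sqrt(1/n + (x - mean_age)^2 / Sxx)` is the standard
#' error of the predicted mean at age `x` (`s` the residual standard error,
#' `Sxx` the sum of squared age deviations). The lower bound acts as the
#' threshold of normality. Setting `prediction_interval = TRUE` adds 1 under
#' the square root, giving the wider single-observation interval.
#'
#' @param ages ages in years (n >= 3, not all equal).
#' @param sbrs corresponding healthy SBRs.
#' @param bound_multiplier half-width of the range in SE units (default 2,
#'   approximately a 95% confidence band of the mean).
#' @param prediction_interval use the prediction-interval form of SE.
#' @param meta optional named list (`quantifier`, `mode`, `calibrated`,
#'   `structure`, `side`) carried on the model.
#' @return An object of class `normal_range_model`.
#' @export
fit_normal_range <- function(ages, sbrs, bound_multiplier = 2,
                             prediction_interval = FALSE, meta = list()) {
  if (length(ages) != length(sbrs))
    stop("ages and sbrs must have equal length", call. = FALSE)
  n <- length(ages)
  if (n < 3L) stop("normal-range fit needs at least 3 subjects", call. = FALSE)
  if (stats::sd(ages) == 0)
    stop("degenerate ages: all subjects have the same age", call. = FALSE)
  if (bound_multiplier < 0)
    stop("bound_multiplier must be >= 0", call. = FALSE)

  mean_age <- mean(ages)
  sxx <- sum((ages - mean_age)^2)
  slope <- sum((ages - mean_age) * (sbrs - mean(sbrs))) / sxx
  intercept <- mean(sbrs) - slope * mean_age
  resid <- sbrs - (intercept + slope * ages)
  s <- sqrt(sum(resid^2) / (n - 2))
  if (slope >= 0)
    warning("fitted age slope is non-negative (", signif(slope, 3),
            "); healthy SBR is expected to decline with age", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, n = n,
                 mean_age = mean_age, sxx = sxx, residual_se = s,
                 bound_multiplier = bound_multiplier,
                 prediction_interval = prediction_interval,
                 quantifier = meta$quantifier %||% NA_character_,
                 mode = meta$mode %||% NA_character_,
                 calibrated = meta$calibrated %||% NA,
                 structure = meta$structure %||% NA_character_,
                 side = meta$side %||% NA_character_),
            class = "normal_range_model")
}

#' @export
print.normal_range_model <- function(x, ...) {
  cat(sprintf(
    "<normal_range_model> SBR = %.4g %+.4g * age (n=%d, s=%.3g, bound %gxSE%s)\n",
    x$intercept, x$slope, x$n, x$residual_se, x$bound_multiplier,
    if (x$prediction_interval) ", prediction interval" else ""))
  invisible(x)
}

se_pred <- function(model, age) {
  extra <- if (isTRUE(model$prediction_interval)) 1 else 0
  model$residual_se *
    sqrt(extra + 1 / model$n + (age - model$mean_age)^2 / model$sxx)
}

#' Normal-range bounds at a given age
#'
#' `lower_limit()` returns `fit(age) - bound_multiplier * SE_pred(age)`, the
#' threshold of normality; `upper_limit()` the symmetric upper bound.
#'
#' @param model a [fit_normal_range()] model.
#' @param age age(s) in years.
#' @return numeric SBR bound(s).
#' @export
lower_limit <- function(model, age) {
  stopifnot(inherits(model, "normal_range_model"))
  (model$intercept + model$slope * age) -
    model$bound_multiplier * se_pred(model, age)
}

#' @rdname lower_limit
#' @export
upper_limit <- function(model, age) {
  stopifnot(inherits(model, "normal_range_model"))
  (model$intercept + model$slope * age) +
    model$bound_multiplier * se_pred(model, age)
}

#' Classify a single region measurement
#'
#' A region is abnormal iff its SBR lies strictly below the age-dependent
#' lower limit; a value exactly on the limit is classified normal
#' (borderline cases get the benefit of the doubt).
#'
#' @param sbr measured or calibrated SBR (finite).
#' @param model a [fit_normal_range()] model.
#' @param age subject age in years.
#' @return logical: `TRUE` if abnormal. Vectorised over `sbr`/`age`.
#' @export
classify_region <- function(sbr, model, age) {
  if (any(!is.finite(sbr)))
    stop("non-finite SBR cannot be classified", call. = FALSE)
  sbr < lower_limit(model, age)
}

.scan_rules <- list(
  striatum_either_side = list(side = c("left", "right"),
                              structure = c("striatum", "striatum")),
  putamen_either_side = list(side = c("left", "right"),
                             structure = c("putamen", "putamen")),
  southampton_striatal = list(side = c("left", "right"),
                              structure = c("striatum", "striatum")))

#' Regions inspected by a scan rule
#'
#' @param rule one of `"striatum_either_side"`, `"putamen_either_side"`,
#'   `"southampton_striatal"`.
#' @return data.frame with columns `side`, `structure`.
#' @export
rule_regions <- function(rule) {
  spec <- .scan_rules[[rule]]
  if (is.null(spec)) stop("unknown scan rule: ", rule, call. = FALSE)
  data.frame(side = spec$side, structure = spec$structure,
             stringsAsFactors = FALSE)
}

#' Classify a scan from per-region verdicts
#'
#' Applies the either-side rule: a scan is abnormal iff at least one of the
#' regions the rule inspects is abnormal. `striatum_either_side` and
#' `putamen_either_side` are the tight-VOI rules; `southampton_striatal`
#' uses the per-side large-VOI striatal SBRs only.
#'
#' @param per_region data.frame with columns `side`, `structure`,
#'   `abnormal` (logical).
#' @param rule rule id, see [rule_regions()].
#' @param subject_id optional id carried on the verdict.
#' @return An object of class `scan_verdict`: fields `subject_id`, `rule`,
#'   `regions` (the inspected rows) and `scan_abnormal`.
#' @export
classify_scan <- function(per_region, rule = names(.scan_rules),
                          subject_id = NA_character_) {
  rule <- match.arg(rule)
  need <- rule_regions(rule)
  flags <- logical(nrow(need))
  for (i in seq_len(nrow(need))) {
    hit <- per_region$side == need$side[i] &
      per_region$structure == need$structure[i]
    if (!any(hit))
      stop("rule ", rule, " needs region ", need$side[i], "/",
           need$structure[i], " but it is missing", call. = FALSE)
    flags[i] <- any(per_region$abnormal[hit])
  }
  structure(list(subject_id = subject_id, rule = rule,
                 regions = cbind(need, abnormal = flags),
                 scan_abnormal = any(flags)),
            class = "scan_verdict")
}

#' @export
print.scan_verdict <- function(x, ...) {
  cat(sprintf("<scan_verdict> %s [%s]: %s\n", x$subject_id, x$rule,
              if (x$scan_abnormal) "ABNORMAL" else "normal"))
  invisible(x)
}

#' Serialise / deserialise normal-range models as JSON
#'
#' @param models list of [fit_normal_range()] models.
#' @param path JSON file path.
#' @return `path` (write) or list of models (read).
#' @export
write_normal_models_json <- function(models, path) {
  payload <- lapply(models, function(m) unclass(m))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_normal_models_json
#' @export
read_normal_models_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(m) {
    m$n <- as.integer(m$n)
    m$calibrated <- if (is.null(m$calibrated)) NA else m$calibrated
    structure(m, class = "normal_range_model")
  })
  names(out) <- names(payload)
  out
}
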