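#' Fit a measured-vs-true calibration line
#'
#' Ordinary least squares of measured phantom SBR on true phantom SBR,
#' characterising one scanner under one reconstruction and quantification
#' strategy. The regression direction is measured-on-true (phantom truth is
#' noise free by construction); the line is inverted at application time.
#'
#' @param measured measured SBRs.
#' @param true_values corresponding true phantom SBRs.
#' @param scanner_id,mode,quantifier,structure identifying metadata.
#' @return An object of class `calibration_line` with fields `slope`,
#'   `intercept`, `n_points`, `residual_sd` and the metadata.
#' @export
fit_calibration <- function(measured, true_values, scanner_id = NA_character_,
                            mode = NA_character_, quantifier = NA_character_,
                            structure = NA_character_) {
  if (length(measured) != length(true_values))
    stop("measured and true_values must have equal length", call. = FALSE)
  n <- length(measured)
  if (n < 2L) stop("calibration needs at least 2 phantom points", call. = FALSE)
  if (stats::sd(true_values) == 0)
    stop("true phantom SBRs are all identical; cannot calibrate",
         call. = FALSE)
  fit <- stats::lm(measured ~ true_values)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("fitted calibration slope is not positive (", signif(slope, 4),
         "); scanner characterisation unusable", call. = FALSE)
  residual_sd <- if (n > 2L) stats::sigma(fit) else 0
  structure(list(scanner_id = scanner_id, mode = mode,
                 quantifier = quantifier, structure = structure,
                 slope = slope, intercept = intercept,
                 n_points = n, residual_sd = residual_sd),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "<calibration_line> %s/%s/%s/%s: measured = %.4g * true + %.4g (n=%d, s=%.3g)\n",
    x$scanner_id, x$mode, x$quantifier, x$structure,
    x$slope, x$intercept, x$n_points, x$residual_sd))
  invisible(x)
}

#' Convert a measured SBR to a calibrated ("true") SBR
#'
#' Inverts the calibration line: `(measured - intercept) / slope`.
#'
#' @param measured_sbr measured SBR value(s).
#' @param line a [fit_calibration()] result.
#' @return calibrated SBR value(s).
#' @export
apply_calibration <- function(measured_sbr, line) {
  stopifnot(inherits(line, "calibration_line"))
  if (!is.finite(line$slope) || line$slope <= 0)
    stop("calibration line slope must be > 0", call. = FALSE)
  (measured_sbr - line$intercept) / line$slope
}

calibration_key <- function(scanner_id, mode, quantifier, structure,
                            share_structures = FALSE) {
  s <- if (share_structures) "any" else structure
  paste(scanner_id, mode, quantifier, s, sep = "|")
}

#' Assemble a calibration set
#'
#' @param lines list of [fit_calibration()] results.
#' @return list of class `calibration_set`, keyed by
#'   scanner/mode/quantifier/structure.
#' @export
calibration_set <- function(lines) {
  stopifnot(all(vapply(lines, inherits, TRUE, "calibration_line")))
  keys <- vapply(lines, function(l)
    calibration_key(l$scanner_id, l$mode, l$quantifier, l$structure), "")
  if (anyDuplicated(keys))
    stop("duplicate calibration lines for ",
         paste(keys[duplicated(keys)], collapse = ", "), call. = FALSE)
  structure(stats::setNames(lines, keys), class = "calibration_set")
}

#' Calibrate (or pass through) a table of SBR records
#'
#' Fills `calibrated_sbr` for every record using the matching calibration
#' line for its (scanner, mode, quantifier, structure). In pass-through mode
#' the raw measured values are copied unchanged, i.e. the quantification
#' output is used "as is" without scanner characterisation.
#'
#' @param records SBR record data.frame (see [small_voi_sbr()]).
#' @param lines a [calibration_set()] (ignored in pass-through mode).
#' @param passthrough if `TRUE`, copy `measured_sbr` into `calibrated_sbr`.
#' @param share_structures if `TRUE`, one line per scanner/mode/quantifier
#'   is applied to all structures (fit with `structure = "any"`).
#' @return `records` with `calibrated_sbr` filled.
#' @export
pool_calibrated <- function(records, lines = NULL, passthrough = FALSE,
                            share_structures = FALSE) {
  if (passthrough) {
    records$calibrated_sbr <- records$measured_sbr
    return(records)
  }
  stopifnot(inherits(lines, "calibration_set"))
  keys <- calibration_key(records$scanner_id, records$mode,
                          records$quantifier, records$structure,
                          share_structures = share_structures)
  missing <- setdiff(unique(keys), names(lines))
  if (length(missing))
    stop("no calibration line for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  records$calibrated_sbr <- vapply(seq_along(keys), function(i)
    apply_calibration(records$measured_sbr[i], lines[[keys[i]]]), 0)
  records
}

#' Serialise / deserialise calibration sets as JSON
#'
#' @param lines a [calibration_set()].
#' @param path JSON file path.
#' @return `path` (write) or a [calibration_set()] (read).
#' @export
write_calibration_json <- function(lines, path) {
  stopifnot(inherits(lines, "calibration_set"))
  payload <- lapply(unname(lines), function(l) l[c(
    "scanner_id", "mode", "quantifier", "structure",
    "slope", "intercept", "n_points", "residual_sd")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @param path JSON file path.
#' @export
read_calibration_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  calibration_set(lapply(payload, function(l) {
    structure(list(scanner_id = l$scanner_id, mode = l$mode,
                   quantifier = l$quantifier, structure = l$structure,
                   slope = l$slope, intercept = l$intercept,
                   n_points = as.integer(l$n_points),
                   residual_sd = l$residual_sd),
              class = "calibration_line")
  }))
}
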