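#' Tight-VOI (count-density ratio) SBR quantification
#'
#' The classical specific binding ratio from tight target VOIs: for each
#' side and structure (caudate, putamen, and their union as the striatum),
#' `SBR = (mean target counts - mean reference counts) / mean reference
#' counts`, with an occipital-like reference region. Tight VOIs make this
#' estimate sensitive to partial-volume losses, which is the behaviour the
#' calibration layer corrects.
#'
#' @param volume a [count_volume()].
#' @param vois a [small_voi_set()].
#' @param meta optional named list merged into every record (e.g.
#'   `subject_id`, `age`, `scanner_id`, `mode`).
#' @return data.frame of SBR records with columns `subject_id`, `age`,
#'   `scanner_id`, `mode`, `quantifier`, `side`, `structure`,
#'   `measured_sbr`, `calibrated_sbr` (NA until calibration).
#' @export
small_voi_sbr <- function(volume, vois, meta = list()) {
  stopifnot(inherits(volume, "count_volume"), inherits(vois, "voi_set"))
  if (!identical(dim(volume$data), dim(vois$labels)))
    stop("VOI set is not aligned to the volume", call. = FALSE)
  counts <- volume$data
  ref_row <- vois$codes[vois$codes$role == "reference", ]
  ref_mask <- vois$labels == ref_row$code[1]
  if (!any(ref_mask)) stop("empty reference VOI", call. = FALSE)
  ref_mean <- mean(counts[ref_mask])
  if (ref_mean <= 0)
    stop("reference mean must be > 0 (got ", signif(ref_mean, 4), ")",
         call. = FALSE)

  rows <- list()
  for (side in c("left", "right")) {
    masks <- list(caudate = voi_mask(vois, side, "caudate"),
                  putamen = voi_mask(vois, side, "putamen"))
    masks$striatum <- masks$caudate | masks$putamen
    for (structure in names(masks)) {
      mask <- masks[[structure]]
      if (!any(mask)) stop("empty VOI: ", side, " ", structure, call. = FALSE)
      sbr <- (mean(counts[mask]) - ref_mean) / ref_mean
      rows[[length(rows) + 1L]] <- list(side = side, structure = structure,
                                        measured_sbr = sbr)
    }
  }
  build_sbr_records(rows, quantifier = "small_voi", meta = meta)
}

#' Large-VOI (total-count) SBR quantification
#'
#' Partial-volume-robust quantification: per side, all counts inside a
#' generous striatal VOI are summed over the axial slab spanning the VOI,
#' the expected background contribution (reference concentration times VOI
#' volume) is subtracted, and the specific counts are normalised by the
#' counts a nominal striatal volume at reference concentration would
#' contain:
#' `SBR = (total - ref_conc * n_vox) / (ref_conc * nominal_volume_vox)`.
#' Because the large VOI captures essentially all blurred striatal counts,
#' this estimate is insensitive to resolution losses.
#'
#' @param volume a [count_volume()].
#' @param vois a [large_voi_set()].
#' @param nominal_striatal_volume nominal per-side striatal volume in mL
#'   used as the normalising denominator; `NULL` uses the analytic ellipsoid
#'   volume of the default geometry's caudate + putamen (about 11 mL).
#' @param meta optional named list merged into every record.
#' @return data.frame of SBR records (structure `"striatum"`, one row per
#'   side), same columns as [small_voi_sbr()].
#' @export
large_voi_sbr <- function(volume, vois, nominal_striatal_volume = NULL,
                          meta = list()) {
  stopifnot(inherits(volume, "count_volume"), inherits(vois, "voi_set"))
  if (!identical(dim(volume$data), dim(vois$labels)))
    stop("VOI set is not aligned to the volume", call. = FALSE)
  counts <- volume$data
  voxel_vol <- volume$voxel_size^3  # mm^3

  if (is.null(nominal_striatal_volume)) {
    g <- striatal_geometry()
    nominal_striatal_volume <-
      4 / 3 * pi * (prod(g$caudate_radii) + prod(g$putamen_radii)) / 1000
  }
  nominal_vox <- nominal_striatal_volume * 1000 / voxel_vol

  ref_row <- vois$codes[vois$codes$role == "reference", ]
  ref_mask <- vois$labels == ref_row$code[1]
  ref_conc <- mean(counts[ref_mask])
  if (ref_conc <= 0)
    stop("reference concentration must be > 0 (got ", signif(ref_conc, 4),
         ")", call. = FALSE)

  rows <- list()
  for (side in c("left", "right")) {
    mask <- voi_mask(vois, side, "large_striatal")
    if (!any(mask)) stop("empty large VOI: ", side, call. = FALSE)
    if (mask_touches_boundary(mask))
      warning("large VOI (", side, ") touches the volume boundary; ",
              "spill-out counts may be lost", call. = FALSE)
    # axial slab spanning the VOI (3D sum over the slab == 3D sum over the
    # VOI restricted to those slices; identical to the full-3D computation)
    zs <- which(apply(mask, 3, any))
    slab_mask <- mask[, , zs, drop = FALSE]
    slab_counts <- counts[, , zs, drop = FALSE]
    total <- sum(slab_counts[slab_mask])
    specific <- total - ref_conc * sum(slab_mask)
    sbr <- specific / (ref_conc * nominal_vox)
    rows[[length(rows) + 1L]] <- list(side = side, structure = "striatum",
                                      measured_sbr = sbr)
  }
  build_sbr_records(rows, quantifier = "large_voi", meta = meta)
}

mask_touches_boundary <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
}

build_sbr_records <- function(rows, quantifier, meta) {
  df <- do.call(rbind, lapply(rows, as.data.frame,
                              stringsAsFactors = FALSE))
  out <- data.frame(
    subject_id = meta$subject_id %||% NA_character_,
    age = meta$age %||% NA_real_,
    scanner_id = meta$scanner_id %||% NA_character_,
    mode = meta$mode %||% NA_character_,
    quantifier = quantifier,
    side = df$side, structure = df$structure,
    measured_sbr = df$measured_sbr,
    calibrated_sbr = NA_real_,
    stringsAsFactors = FALSE)
  if (any(!is.finite(out$measured_sbr)))
    stop("non-finite measured SBR produced", call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
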