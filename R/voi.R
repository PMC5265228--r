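#' VOI set container
#'
#' A labelled region set aligned to a count volume: an integer label array
#' plus a code table mapping codes to (side, structure, role). Two flavours
#' are built from a geometry: tight target VOIs with a small occipital-like
#' reference (the small-VOI, count-density philosophy) and generous per-side
#' striatal VOIs with a whole-brain-minus-targets reference (the large-VOI,
#' total-count philosophy).
#'
#' @param labels integer 3D array (0 = unlabelled).
#' @param codes data.frame with columns `code`, `side`, `structure`, `role`.
#' @param voxel_size voxel size, mm.
#' @return An object of class `voi_set`.
#' @export
voi_set <- function(labels, codes, voxel_size) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  need <- c("code", "side", "structure", "role")
  if (!all(need %in% names(codes)))
    stop("code table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% codes$code))
    stop("label array contains codes missing from the code table",
         call. = FALSE)
  structure(list(labels = labels, codes = codes,
                 voxel_size = as.numeric(voxel_size)),
            class = "voi_set")
}

voi_mask <- function(vois, side, structure) {
  row <- vois$codes[vois$codes$side == side & vois$codes$structure == structure, ]
  if (nrow(row) == 0L)
    stop("no VOI for side=", side, " structure=", structure, call. = FALSE)
  vois$labels == row$code[1]
}

# binary erosion with a 6-connected structuring element, n iterations
erode_mask <- function(mask, iterations = 1L) {
  shift1 <- function(m, axis, by) {
    d <- dim(m); out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else        { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (i in seq_len(iterations)) {
    mask <- mask &
      shift1(mask, 1, 1) & shift1(mask, 1, -1) &
      shift1(mask, 2, 1) & shift1(mask, 2, -1) &
      shift1(mask, 3, 1) & shift1(mask, 3, -1)
  }
  mask
}

#' Tight-VOI set
#'
#' Tight caudate/putamen target VOIs (the anatomical masks eroded by
#' `erode_voxels` to keep them inside the structures) plus an occipital-like
#' posterior reference region inside the brain. Striatal values are computed
#' downstream as the caudate-plus-putamen voxel union.
#'
#' @param geometry a [striatal_geometry()].
#' @param erode_voxels erosion iterations applied to the target masks.
#' @param reference_fraction how far back the posterior reference starts, as
#'   a fraction of the brain's anterior-posterior semi-axis.
#' @param reference_erode_mm how far the reference region stays away from
#'   the brain surface, mm. Voxels near the surface lose counts to blur
#'   spill-out, which would bias the reference concentration low; staying
#'   about one PSF FWHM inside the brain avoids that shell.
#' @return A [voi_set()].
#' @export
small_voi_set <- function(geometry, erode_voxels = 1L,
                          reference_fraction = 0.55,
                          reference_erode_mm = 10) {
  m <- geometry_masks(geometry)
  er <- function(mask) if (erode_voxels > 0) erode_mask(mask, erode_voxels) else mask
  tgt <- list(caudate_left = er(m$caudate_left),
              caudate_right = er(m$caudate_right),
              putamen_left = er(m$putamen_left),
              putamen_right = er(m$putamen_right))
  if (any(vapply(tgt, sum, 0L) == 0L))
    stop("erosion emptied a target VOI; reduce erode_voxels", call. = FALSE)

  ny <- geometry$grid_shape[2]
  y <- axis_coords(ny, geometry$voxel_size)
  y_cut <- geometry$brain_center[2] - reference_fraction * geometry$brain_radii[2]
  post <- array(rep(y < y_cut, each = geometry$grid_shape[1]),
                dim = geometry$grid_shape)
  interior <- ellipsoid_mask(geometry$brain_center,
                             pmax(geometry$brain_radii - reference_erode_mm,
                                  geometry$voxel_size),
                             geometry$grid_shape, geometry$voxel_size)
  ref <- m$brain & interior & post
  for (t in tgt) ref <- ref & !t
  if (!any(ref)) stop("empty reference region", call. = FALSE)

  labels <- array(0L, geometry$grid_shape)
  labels[tgt$caudate_left] <- 1L; labels[tgt$caudate_right] <- 2L
  labels[tgt$putamen_left] <- 3L; labels[tgt$putamen_right] <- 4L
  labels[ref] <- 5L
  codes <- data.frame(
    code = 1:5,
    side = c("left", "right", "left", "right", "both"),
    structure = c("caudate", "caudate", "putamen", "putamen", "occipital"),
    role = c(rep("target", 4), "reference"),
    stringsAsFactors = FALSE)
  voi_set(labels, codes, geometry$voxel_size)
}

#' Large-VOI set
#'
#' Per-side large striatal VOIs: the caudate and putamen ellipsoids dilated
#' by `margin_mm` (clipped at the mid-sagittal plane so the two sides stay
#' disjoint), with the reference region comprising all remaining brain
#' voxels. Designed so that, for margins of at least twice the PSF FWHM,
#' essentially all blurred striatal counts fall inside the VOI.
#'
#' @param geometry a [striatal_geometry()].
#' @param margin_mm dilation margin in mm (typically 2 x PSF FWHM).
#' @param reference_erode_mm how far the reference region stays away from
#'   the brain surface, mm (see [small_voi_set()]); defaults to about two
#'   thirds of the VOI margin (roughly 1.3 x the effective resolution for
#'   the recommended 2 x FWHM margin), bounded to [10, 18] mm so the
#'   reference neither grazes the spill-out shell nor collapses.
#' @return A [voi_set()].
#' @export
large_voi_set <- function(geometry, margin_mm,
                          reference_erode_mm = min(max(margin_mm * 0.65, 10), 18)) {
  if (margin_mm < 0) stop("margin_mm must be >= 0", call. = FALSE)
  g <- geometry
  grown <- function(center, radii)
    ellipsoid_mask(center, radii + margin_mm, g$grid_shape, g$voxel_size)
  nx <- g$grid_shape[1]
  x <- axis_coords(nx, g$voxel_size)
  right_half <- array(x > 0, dim = g$grid_shape)
  left_half <- array(x < 0, dim = g$grid_shape)

  # Both the VOIs and the reference live in the brain interior, away from
  # the surface shell where blur spill-out depresses the local background:
  # a VOI voxel outside uniform background would subtract a full reference
  # concentration it does not contain, biasing the specific counts.
  interior <- ellipsoid_mask(g$brain_center,
                             pmax(g$brain_radii - reference_erode_mm,
                                  g$voxel_size),
                             g$grid_shape, g$voxel_size)
  lr <- (grown(g$caudate_center, g$caudate_radii) |
           grown(g$putamen_center, g$putamen_radii)) & right_half & interior
  ll <- (grown(mirror_x(g$caudate_center), g$caudate_radii) |
           grown(mirror_x(g$putamen_center), g$putamen_radii)) & left_half &
    interior
  m <- geometry_masks(g)
  ref <- m$brain & interior & !lr & !ll
  if (!any(ref)) stop("empty large-VOI reference region", call. = FALSE)

  labels <- array(0L, g$grid_shape)
  labels[ll] <- 6L; labels[lr] <- 7L; labels[ref] <- 8L
  codes <- data.frame(
    code = 6:8,
    side = c("left", "right", "both"),
    structure = c("large_striatal", "large_striatal", "brain_background"),
    role = c("target", "target", "reference"),
    stringsAsFactors = FALSE)
  voi_set(labels, codes, g$voxel_size)
}
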