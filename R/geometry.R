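#' Striatal phantom geometry
#'
#' Describes the digital striatal phantom: ellipsoidal caudate and putamen
#' per hemisphere inside an ellipsoidal brain, on an isotropic voxel grid.
#' Coordinates are in mm with the origin at the grid centre; +x is subject
#' right, +y anterior, +z superior, so the mid-sagittal plane is x = 0 and
#' left-side structures are the mirror image of the right-side parameters.
#'
#' @param caudate_center right-caudate centre, mm `c(x, y, z)` with x > 0.
#' @param caudate_radii caudate ellipsoid semi-axes, mm.
#' @param putamen_center right-putamen centre, mm with x > 0.
#' @param putamen_radii putamen ellipsoid semi-axes, mm.
#' @param brain_center brain ellipsoid centre, mm (x must be 0 for symmetry).
#' @param brain_radii brain ellipsoid semi-axes, mm.
#' @param voxel_size isotropic voxel size, mm.
#' @param grid_shape integer vector of voxels per axis.
#' @return An object of class `striatal_geometry`.
#' @details
#' Structure volumes default to roughly 5 mL (caudate) and 6 mL (putamen)
#' per side, literature-typical for the adult striatum. Validation checks
#' that the voxelised caudate and putamen masks are disjoint, lie inside the
#' brain, and that mirrored structures stay on their side of the midline.
#' @export
striatal_geometry <- function(caudate_center = c(10, 22, 6),
                              caudate_radii = c(8, 17.5, 8.5),
                              putamen_center = c(28, -4, 0),
                              putamen_radii = c(9, 16, 10),
                              brain_center = c(0, 0, 0),
                              brain_radii = c(70, 85, 60),
                              voxel_size = 2,
                              grid_shape = c(128L, 128L, 128L)) {
  g <- structure(
    list(caudate_center = as.numeric(caudate_center),
         caudate_radii = as.numeric(caudate_radii),
         putamen_center = as.numeric(putamen_center),
         putamen_radii = as.numeric(putamen_radii),
         brain_center = as.numeric(brain_center),
         brain_radii = as.numeric(brain_radii),
         voxel_size = as.numeric(voxel_size),
         grid_shape = as.integer(grid_shape)),
    class = "striatal_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  for (f in c("caudate_center", "caudate_radii", "putamen_center",
              "putamen_radii", "brain_center", "brain_radii"))
    if (length(g[[f]]) != 3L || anyNA(g[[f]]))
      stop("geometry field `", f, "` must be length-3 numeric", call. = FALSE)
  if (any(c(g$caudate_radii, g$putamen_radii, g$brain_radii) <= 0))
    stop("all geometry radii must be > 0", call. = FALSE)
  if (g$voxel_size <= 0) stop("voxel_size must be > 0", call. = FALSE)
  if (length(g$grid_shape) != 3L || any(g$grid_shape < 8L))
    stop("grid_shape must be 3 axes of at least 8 voxels", call. = FALSE)
  if (abs(g$brain_center[1]) > 1e-9)
    stop("brain must be centred on the mid-sagittal plane (x = 0)",
         call. = FALSE)
  if (g$caudate_center[1] <= 0 || g$putamen_center[1] <= 0)
    stop("structure centres are given for the right side (x > 0)",
         call. = FALSE)

  m <- geometry_masks(g)
  if (any(m$caudate_right & m$putamen_right) ||
      any(m$caudate_left & m$putamen_left))
    stop("caudate and putamen ellipsoids overlap; adjust centres/radii",
         call. = FALSE)
  strio <- m$caudate_left | m$caudate_right | m$putamen_left | m$putamen_right
  if (any(strio & !m$brain))
    stop("striatal structures extend outside the brain ellipsoid",
         call. = FALSE)
  invisible(g)
}

#' @export
print.striatal_geometry <- function(x, ...) {
  cat(sprintf("<striatal_geometry> %s voxels @ %g mm (FOV %s mm)\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size,
              paste(x$grid_shape * x$voxel_size, collapse = "x")))
  vol <- function(r) 4 / 3 * pi * prod(r) / 1000
  cat(sprintf("  caudate %.1f mL, putamen %.1f mL per side; brain radii %s mm\n",
              vol(x$caudate_radii), vol(x$putamen_radii),
              paste(x$brain_radii, collapse = "/")))
  invisible(x)
}

# Voxel-centre coordinates along each axis, mm, origin at grid centre.
axis_coords <- function(n, voxel_size) (seq_len(n) - (n + 1) / 2) * voxel_size

#' Voxelise an ellipsoid
#'
#' Logical mask of voxels whose centres fall inside the ellipsoid
#' `sum(((p - center) / radii)^2) <= 1`.
#'
#' @param center,radii ellipsoid centre and semi-axes, mm.
#' @param grid_shape,voxel_size grid definition (see [striatal_geometry()]).
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(center, radii, grid_shape, voxel_size) {
  cx <- axis_coords(grid_shape[1], voxel_size)
  cy <- axis_coords(grid_shape[2], voxel_size)
  cz <- axis_coords(grid_shape[3], voxel_size)
  qx <- ((cx - center[1]) / radii[1])^2
  qy <- ((cy - center[2]) / radii[2])^2
  qz <- ((cz - center[3]) / radii[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  array(q <= 1, dim = grid_shape)
}

mirror_x <- function(v) c(-v[1], v[2], v[3])

#' Structure masks for a geometry
#'
#' Voxelises all phantom structures. Striatum masks are the union of the
#' caudate and putamen masks per side.
#'
#' @param g a [striatal_geometry()].
#' @return named list of logical arrays: `brain`, `caudate_left/right`,
#'   `putamen_left/right`, `striatum_left/right`.
#' @export
geometry_masks <- function(g) {
  em <- function(center, radii)
    ellipsoid_mask(center, radii, g$grid_shape, g$voxel_size)
  cr <- em(g$caudate_center, g$caudate_radii)
  cl <- em(mirror_x(g$caudate_center), g$caudate_radii)
  pr <- em(g$putamen_center, g$putamen_radii)
  pl <- em(mirror_x(g$putamen_center), g$putamen_radii)
  list(brain = em(g$brain_center, g$brain_radii),
       caudate_left = cl, caudate_right = cr,
       putamen_left = pl, putamen_right = pr,
       striatum_left = cl | pl, striatum_right = cr | pr)
}

#' Default study-scale geometry
#'
#' A smaller grid (64^3 voxels at 3 mm) with anatomically unchanged
#' structure sizes, used by the end-to-end study driver so that hundreds of
#' renders fit a desk-scale compute budget. The brain is slightly smaller
#' than the [striatal_geometry()] default so the blur margin fits the
#' 192 mm field of view.
#'
#' @return A [striatal_geometry()].
#' @export
study_geometry <- function() {
  striatal_geometry(brain_radii = c(68, 78, 58),
                    voxel_size = 3,
                    grid_shape = c(64L, 64L, 64L))
}
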