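#' Binary label volume on a regular anisotropic grid
#'
#' A `label_volume` holds one structure's binary occupancy together with the
#' physical geometry of its grid: voxel edge lengths (`spacing`, mm) and the
#' world-space offset of the grid corner (`origin`, mm). The centre of voxel
#' `(i, j, k)` (0-based) sits at `origin + (index + 0.5) * spacing` per axis.
#' All geometric quantities downstream (volumes, Hausdorff distances) are in
#' physical millimetres, so anisotropic grids — e.g. 1 x 1 mm in plane with
#' 3 mm slices, typical of pelvic MR — are handled correctly.
#'
#' @param voxels 3D array of 0/1 occupancy (logical or numeric accepted;
#'   stored as integer).
#' @param spacing Numeric length-3, voxel edge lengths in mm; all > 0.
#' @param origin Numeric length-3, world offset of the grid corner in mm.
#' @return An object of class `label_volume`.
#' @examples
#' v <- label_volume(array(1L, c(4, 4, 4)), spacing = c(2, 2, 2))
#' volume_mm3(v)
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array; got ", length(dim(voxels)), " dimensions (not a 3D volume)")
  }
  vox <- voxels
  storage.mode(vox) <- "integer"
  bad <- !(vox == 0L | vox == 1L)
  if (anyNA(vox) || any(bad)) {
    stop("`voxels` must be strictly binary (0/1)")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)")
  }
  structure(
    list(voxels = vox, spacing = spacing, origin = origin),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels, spacing %s mm, %d foreground (%.1f mm^3)\n",
    d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
    sum(x$voxels), volume_mm3(x)
  ))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

is_label_volume <- function(x) inherits(x, "label_volume")

stopifnot_label_volume <- function(x, arg = deparse(substitute(x))) {
  if (!is_label_volume(x)) stop("`", arg, "` must be a label_volume")
  invisible(x)
}

#' Physical volume of a mask
#'
#' Foreground voxel count times the voxel volume (product of the spacing
#' components), in cubic millimetres.
#'
#' @param v A [label_volume()].
#' @return Scalar volume in mm^3 (0 for an empty mask).
#' @export
volume_mm3 <- function(v) {
  stopifnot_label_volume(v)
  sum(v$voxels) * prod(v$spacing)
}

#' World coordinates of boundary voxel centres
#'
#' The boundary of a mask is the set of foreground voxels with at least one
#' 6-connected neighbour that is background or outside the grid. These voxel
#' centres are the point sets fed to the Hausdorff distances; using the
#' 6-connectivity surface rather than all foreground voxels keeps the point
#' sets small and matches common practice for the 95% Hausdorff distance.
#'
#' @param v A [label_volume()].
#' @param surface If `FALSE`, return all foreground voxel centres instead of
#'   only the boundary shell (the alternative convention some studies use).
#' @return A numeric matrix with one row per point and columns x, y, z (mm).
#'   Zero rows for an empty mask.
#' @export
boundary_points <- function(v, surface = TRUE) {
  stopifnot_label_volume(v)
  keep <- if (surface) {
    cpp_boundary6(as.integer(v$voxels), dim(v$voxels))
  } else {
    as.logical(v$voxels)
  }
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  ijk <- arrayInd(idx, dim(v$voxels)) - 1L
  pts <- sweep(sweep(ijk + 0.5, 2, v$spacing, `*`), 2, v$origin, `+`)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# logical index of boundary voxels (internal, grid-path metrics)
boundary_mask <- function(v, surface = TRUE) {
  if (surface) {
    array(cpp_boundary6(as.integer(v$voxels), dim(v$voxels)), dim(v$voxels))
  } else {
    array(as.logical(v$voxels), dim(v$voxels))
  }
}

#' Check that two label volumes live on the same grid
#'
#' Metrics between masks are only meaningful when both masks come from
#' co-registered images sharing one grid. This passes silently iff spacing,
#' origin and grid shape agree elementwise (1e-6 relative tolerance for the
#' real-valued fields) and otherwise raises an error naming the offending
#' field — the symptom of comparing masks from unregistered images.
#'
#' @param a,b [label_volume()] objects.
#' @return Invisibly `TRUE` on success.
#' @export
validate_comparable <- function(a, b) {
  stopifnot_label_volume(a)
  stopifnot_label_volume(b)
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop(sprintf(
      "grid mismatch in grid_shape: %s vs %s",
      paste(dim(a$voxels), collapse = "x"), paste(dim(b$voxels), collapse = "x")
    ))
  }
  rel_ok <- function(x, y) all(abs(x - y) <= 1e-6 * pmax(abs(x), abs(y), 1))
  if (!rel_ok(a$spacing, b$spacing)) {
    stop(sprintf(
      "grid mismatch in spacing: (%s) vs (%s)",
      paste(format(a$spacing), collapse = ","), paste(format(b$spacing), collapse = ",")
    ))
  }
  if (!rel_ok(a$origin, b$origin)) {
    stop(sprintf(
      "grid mismatch in origin: (%s) vs (%s)",
      paste(format(a$origin), collapse = ","), paste(format(b$origin), collapse = ",")
    ))
  }
  invisible(TRUE)
}
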