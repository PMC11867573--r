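#' Read a binary mask from a NIfTI file
#'
#' Loads a 3D NIfTI image and binarizes it at `value > 0.5`, which tolerates
#' masks stored as floats. Voxel spacing is taken from the header `pixdim`;
#' the world origin from the sform/qform translation when the transform is
#' axis-aligned with positive scales. Oblique or flipped orientation matrices
#' are rejected rather than silently reinterpreted: within one patient all
#' masks are expected to share a single axis-aligned grid, and anything else
#' signals an upstream registration problem.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [label_volume()].
#' @export
load_label_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("'", path, "' is not a 3D volume (", length(d), " dimensions)")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'", path, "': header spacing must be positive, got (",
         paste(spacing, collapse = ","), ")")
  }
  xf <- RNifti::xform(img)
  origin <- c(0, 0, 0)
  code <- attr(xf, "code")
  if (!is.null(code) && code > 0) {
    rot <- xf[1:3, 1:3]
    if (any(abs(rot - diag(diag(rot))) > 1e-4 * max(abs(rot))) ||
        any(diag(rot) <= 0)) {
      stop("'", path, "': unsupported orientation (only axis-aligned, ",
           "positive-scale transforms are handled)")
    }
    # NIfTI maps index 0 to the translation column; our origin is the grid
    # corner, half a voxel before the first centre
    origin <- xf[1:3, 4] - 0.5 * spacing
  }
  vox <- as.array(img)
  label_volume((vox > 0.5) * 1L, spacing = spacing, origin = origin)
}

#' Write a binary mask to a NIfTI file
#'
#' Writes the occupancy as integer data with spacing in `pixdim` and an
#' axis-aligned sform/qform encoding the origin, so that
#' `load_label_volume(write_label_volume(v, f))` round-trips occupancy,
#' spacing and origin exactly.
#'
#' @param v A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(v, path) {
  stopifnot_label_volume(v)
  img <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin + 0.5 * v$spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
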