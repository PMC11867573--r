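#' Parameters of the synthetic pelvic phantom
#'
#' Defines the geometry of a five-structure pelvic phantom on an anisotropic
#' grid: an ellipsoidal bladder anteriorly, a curved rectal tube and a short
#' anal-canal tube stacked along the inferior–superior axis posteriorly, and
#' two lateral spherical femoral heads. Sizes are loosely modelled on pelvic
#' anatomy but scaled to fit a compact grid; what matters for validating
#' agreement metrics is realistic *shape relationships* (disjoint organs,
#' curved tubes, anisotropic 3 mm slices), not absolute organ volumes.
#'
#' Axes follow the grid: x = left–right, y = anterior–posterior,
#' z = inferior–superior.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param spacing Voxel edge lengths in mm; default `c(1, 1, 3)` reproduces
#'   typical in-plane resolution with 3 mm slices.
#' @param bladder_semiaxes Ellipsoid semi-axes in mm (x, y, z).
#' @param bladder_center World centre of the bladder, mm.
#' @param rectum_radius,rectum_z,rectum_center_xy,rectum_curve Rectal tube:
#'   radius (mm), inferior/superior extent (mm), centreline x/y position
#'   (mm) and lateral sinusoidal curve amplitude (mm).
#' @param anal_radius,anal_z Anal-canal tube radius and z extent (mm); must
#'   sit below the rectum with a gap.
#' @param femoral_radius Femoral head sphere radius, mm.
#' @param femoral_centers Two-row matrix of sphere centres (left, right), mm.
#' @param size_jitter Relative per-patient, per-structure size variation
#'   (uniform in `±size_jitter`).
#' @param center_jitter Per-patient random shift of each structure centre,
#'   mm (uniform per axis).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(96L, 96L, 48L),
                           spacing = c(1, 1, 3),
                           bladder_semiaxes = c(20, 18, 16),
                           bladder_center = c(48, 26, 96),
                           rectum_radius = 11,
                           rectum_z = c(66, 132),
                           rectum_center_xy = c(48, 66),
                           rectum_curve = 3,
                           anal_radius = 8,
                           anal_z = c(24, 54),
                           femoral_radius = 13,
                           femoral_centers = rbind(c(18, 50, 84),
                                                   c(78, 50, 84)),
                           size_jitter = 0.1,
                           center_jitter = 1.5) {
  p <- list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    bladder_semiaxes = bladder_semiaxes, bladder_center = bladder_center,
    rectum_radius = rectum_radius, rectum_z = rectum_z,
    rectum_center_xy = rectum_center_xy, rectum_curve = rectum_curve,
    anal_radius = anal_radius, anal_z = anal_z,
    femoral_radius = femoral_radius, femoral_centers = femoral_centers,
    size_jitter = size_jitter, center_jitter = center_jitter
  )
  stopifnot(
    length(p$grid_shape) == 3, all(p$grid_shape > 0),
    length(p$spacing) == 3, all(p$spacing > 0),
    all(p$bladder_semiaxes > 0), p$rectum_radius > 0, p$anal_radius > 0,
    p$femoral_radius > 0, p$size_jitter >= 0, p$center_jitter >= 0,
    p$anal_z[2] < p$rectum_z[1]
  )
  class(p) <- "phantom_params"
  p
}

# world coordinates of all voxel centres, as three arrays
grid_coords <- function(grid_shape, spacing, origin = c(0, 0, 0)) {
  ax <- function(i) origin[i] + (seq_len(grid_shape[i]) - 0.5) * spacing[i]
  list(
    x = array(rep(ax(1), times = grid_shape[2] * grid_shape[3]), grid_shape),
    y = array(rep(rep(ax(2), each = grid_shape[1]), times = grid_shape[3]),
              grid_shape),
    z = array(rep(ax(3), each = grid_shape[1] * grid_shape[2]), grid_shape)
  )
}

rasterize <- function(inside, grid_shape, spacing) {
  label_volume(array(as.integer(inside), grid_shape), spacing = spacing)
}

#' Generate one patient's ground-truth contour set
#'
#' Builds the five phantom structures deterministically from
#' `patient_seed`, applying per-patient size jitter (±`size_jitter`
#' relative) and small centre shifts so that patients differ while the
#' anatomy stays valid. The five masks are checked to be pairwise disjoint
#' and fully inside the grid; violated geometry (e.g. oversized structures)
#' raises an error rather than returning clipped anatomy.
#'
#' @param params A [phantom_params()].
#' @param patient_seed Integer seed; the same seed reproduces identical
#'   voxel arrays.
#' @param patient_id Identifier stored in the returned set.
#' @return A [contour_set()] with observer `"GT"`, sequence `"T1WI"` (the
#'   ground truth is sequence-agnostic; the label is nominal).
#' @export
generate_base_patient <- function(params = phantom_params(), patient_seed = 1L,
                                  patient_id = "P01") {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(patient_seed, {
    jit <- function() 1 + stats::runif(1, -params$size_jitter, params$size_jitter)
    shift <- function() stats::runif(3, -params$center_jitter, params$center_jitter)

    g <- grid_coords(params$grid_shape, params$spacing)
    masks <- list()

    bc <- params$bladder_center + shift()
    bs <- params$bladder_semiaxes * jit()
    masks$bladder <- ((g$x - bc[1]) / bs[1])^2 + ((g$y - bc[2]) / bs[2])^2 +
      ((g$z - bc[3]) / bs[3])^2 <= 1

    rs <- shift()
    rr <- params$rectum_radius * jit()
    rz <- params$rectum_z + rs[3]
    span <- diff(params$rectum_z)
    cx <- params$rectum_center_xy[1] + rs[1] +
      params$rectum_curve * sin(2 * pi * (g$z - rz[1]) / span)
    cy <- params$rectum_center_xy[2] + rs[2]
    masks$rectum <- (g$x - cx)^2 + (g$y - cy)^2 <= rr^2 &
      g$z >= rz[1] & g$z <= rz[2]

    as_ <- shift()
    ar <- params$anal_radius * jit()
    az <- params$anal_z + as_[3]
    masks$anal_canal <- (g$x - (params$rectum_center_xy[1] + as_[1]))^2 +
      (g$y - (params$rectum_center_xy[2] + as_[2]))^2 <= ar^2 &
      g$z >= az[1] & g$z <= az[2]

    for (side in 1:2) {
      fc <- params$femoral_centers[side, ] + shift()
      fr <- params$femoral_radius * jit()
      nm <- c("femoral_head_L", "femoral_head_R")[side]
      masks[[nm]] <- (g$x - fc[1])^2 + (g$y - fc[2])^2 + (g$z - fc[3])^2 <= fr^2
    }

    total <- Reduce(`+`, masks)
    if (any(total > 1)) stop("phantom structures overlap; shrink the geometry")
    for (nm in names(masks)) {
      m <- masks[[nm]]
      if (!any(m)) stop("phantom structure '", nm, "' is empty on this grid")
      d <- params$grid_shape
      if (any(m[1, , ]) || any(m[d[1], , ]) || any(m[, 1, ]) ||
          any(m[, d[2], ]) || any(m[, , 1]) || any(m[, , d[3]])) {
        stop("phantom structure '", nm, "' exceeds the grid")
      }
    }
    vols <- lapply(masks, rasterize, grid_shape = params$grid_shape,
                   spacing = params$spacing)
    contour_set(patient_id, "GT", "T1WI", vols)
  })
}
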