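#' @useDynLib bodyatlas, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats median mad qnorm pt sd quantile setNames rnorm runif
#'   p.adjust optim
#' @importFrom utils read.csv write.csv head modifyList
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Virtual base for grid-aware objects
#'
#' Shares the physical-grid description (voxel spacing and origin, both in
#' mm) between scalar volumes and vector fields.  The physical coordinate of
#' voxel \code{(i, j, k)} (1-based) is \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @slot spacing numeric(3), mm per voxel along each axis, strictly positive.
#' @slot origin numeric(3), physical position (mm) of the first voxel.
#' @keywords internal
#' @export
setClass("Gridded", representation("VIRTUAL",
  spacing = "numeric",
  origin = "numeric"
))

#' 3D scalar volume on a regular grid
#'
#' The basic image container: a 3D array of intensities (or probabilities,
#' masks, Jacobian determinants, ...) with physical spacing and origin.
#' Axis order follows the array index order; the \code{axisTag} records the
#' convention used when the volume was read from or written to disk.
#'
#' @slot data 3D numeric array.
#' @slot axisTag single string naming the axis-order convention.
#' @export
setClass("BodyVolume", contains = "Gridded", representation(
  data = "array",
  axisTag = "character"
))

setValidity("BodyVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Integer label volume
#'
#' A [BodyVolume] whose voxels are non-negative integer structure ids, with a
#' dictionary mapping each id to a structure name.  Id 0 is background and is
#' always present in the dictionary.
#'
#' @slot labels named character vector; names are integer ids as strings.
#' @export
setClass("LabelVolume", contains = "BodyVolume", representation(
  labels = "character"
))

setValidity("LabelVolume", function(object) {
  msg <- character()
  vals <- unique(as.vector(object@data))
  if (any(vals < 0) || any(vals != round(vals)))
    msg <- c(msg, "label data must be non-negative integers")
  ids <- suppressWarnings(as.integer(names(object@labels)))
  if (any(is.na(ids)))
    msg <- c(msg, "label dictionary names must be integer ids")
  else if (!all(vals %in% ids))
    msg <- c(msg, "every voxel value must appear in the label dictionary")
  if (length(msg)) msg else TRUE
})

#' Dense displacement field
#'
#' A 3-component vector field on the fixed grid, components in mm, mapping
#' fixed-space points \code{x} to moving-space points \code{x + u(x)}
#' (pull-back convention: resampling a moving image at these points produces
#' an image on the fixed grid).
#'
#' @slot data 4D numeric array with dims \code{c(grid, 3)}.
#' @slot convention single string, always \code{"pullback"} for fields
#'   produced by this package.
#' @export
setClass("DisplacementField", contains = "Gridded", representation(
  data = "array",
  convention = "character"
))

setValidity("DisplacementField", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "data must be a 4D array with 3 components")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "all components must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(msg)) msg else TRUE
})

#' Affine transform in physical coordinates
#'
#' Maps fixed-space physical points to moving-space points,
#' \code{y = L x + t}, with \code{L} the 3x3 linear part and \code{t} the
#' translation in mm.  Used under the same pull-back convention as
#' [DisplacementField].
#'
#' @slot linear 3x3 invertible matrix.
#' @slot translation numeric(3), mm.
#' @export
setClass("AffineTransform3D", representation(
  linear = "matrix",
  translation = "numeric"
))

setValidity("AffineTransform3D", function(object) {
  msg <- character()
  if (!all(dim(object@linear) == c(3L, 3L)))
    msg <- c(msg, "linear part must be 3x3")
  else if (abs(det(object@linear)) < .Machine$double.eps * 100)
    msg <- c(msg, "linear part must be invertible")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' B-spline control-point lattice of a stationary velocity field
#'
#' Parameters of the deformable transform: cubic B-spline coefficients of a
#' stationary velocity field (mm) on a regular control-point lattice covering
#' the fixed image domain with one boundary ring of control points on each
#' side.  Control point \code{m} (1-based) along an axis sits at voxel
#' coordinate \code{(m - 2) * delta} where \code{delta} is the control
#' spacing in voxels.
#'
#' @slot coef 4D array \code{c(lattice dims, 3)} of velocity coefficients, mm.
#' @slot cpSpacing numeric(3), control-point spacing in mm.
#' @slot gridDim integer(3), dims of the covered image grid.
#' @slot spacing,origin grid geometry of the covered image (see [Gridded]).
#' @export
setClass("VelocityLattice", contains = "Gridded", representation(
  coef = "array",
  cpSpacing = "numeric",
  gridDim = "integer"
))

setValidity("VelocityLattice", function(object) {
  msg <- character()
  cd <- dim(object@coef)
  if (length(cd) != 4L || cd[4] != 3L)
    msg <- c(msg, "coef must be a 4D array with 3 components")
  delta <- object@cpSpacing / object@spacing
  need <- floor((object@gridDim - 1) / delta) + 4
  if (length(cd) == 4L && any(cd[1:3] < need))
    msg <- c(msg, "lattice does not cover the image domain with one boundary ring")
  if (length(msg)) msg else TRUE
})

#' Binary body mask with provenance
#'
#' Foreground support of the body, produced by [bodyMask()]: Otsu threshold,
#' largest 6-connected component, morphological closing and hole filling.
#'
#' @slot provenance list recording the threshold and components kept.
#' @export
setClass("BodyMask", contains = "BodyVolume", representation(
  provenance = "list"
))

#' Population atlas
#'
#' The anatomical average volume in reference space together with
#' per-structure probability volumes, the coverage map (fraction of subjects
#' with in-domain samples per voxel) and provenance.
#'
#' @slot anatomy [BodyVolume], the anatomical average.
#' @slot probability named list of [BodyVolume] probability maps, one per
#'   structure.
#' @slot coverage [BodyVolume] in \code{[0, 1]}.
#' @slot nSubjects integer, number of averaged subjects.
#' @slot provenance list: reference id, unbiased flag, config hash, ...
#' @export
setClass("BodyAtlas", representation(
  anatomy = "BodyVolume",
  probability = "list",
  coverage = "BodyVolume",
  nSubjects = "integer",
  provenance = "list"
))

setValidity("BodyAtlas", function(object) {
  msg <- character()
  for (p in object@probability) {
    if (!is(p, "BodyVolume")) { msg <- c(msg, "probability maps must be BodyVolume"); break }
    if (min(p@data) < -1e-6 || max(p@data) > 1 + 1e-6) {
      msg <- c(msg, "probability values must lie in [0, 1]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Voxel-wise group-comparison statistics
#'
#' Result of the voxel-based morphometry GLM: a z-score volume, the
#' FDR-corrected p volume, the significance mask after thresholding, and the
#' analysis mask the statistics were computed in.  Positive z means the
#' second (pathological) group mean exceeds the first (healthy) group mean.
#'
#' @slot z,p [BodyVolume] z-scores and corrected p-values.
#' @slot sigMask,analysisMask [BodyVolume] binary masks.
#' @slot flagged integer, count of in-mask voxels with zero within-group
#'   variance (z forced to 0 there).
#' @slot params list of test parameters (q, pRetain, fwhm, ...).
#' @export
setClass("VoxelZMap", representation(
  z = "BodyVolume",
  p = "BodyVolume",
  sigMask = "BodyVolume",
  analysisMask = "BodyVolume",
  flagged = "integer",
  params = "list"
))

setValidity("VoxelZMap", function(object) {
  sm <- object@sigMask@data > 0
  am <- object@analysisMask@data > 0
  if (any(sm & !am))
    return("significance mask must be a subset of the analysis mask")
  if (any(!is.finite(object@z@data[am])))
    return("z must be finite inside the analysis mask")
  TRUE
})
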