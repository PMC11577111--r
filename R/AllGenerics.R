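#' Construct a BodyVolume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3) voxel size in mm (recycled from a scalar).
#' @param origin numeric(3) physical position of the first voxel, mm.
#' @param axisTag axis-order convention tag.
#' @return A [BodyVolume].
#' @examples
#' v <- Volume(array(0, c(4, 4, 4)), spacing = 2)
#' dims(v)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   axisTag = "index-xyz") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  new("BodyVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axisTag = axisTag)
}

#' Construct a LabelVolume
#'
#' @inheritParams Volume
#' @param labels named character vector mapping integer ids (as names) to
#'   structure names; id 0 (background) is added when missing.
#' @return A [LabelVolume].
#' @export
LabelMap <- function(data, labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     axisTag = "index-xyz") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  if (!"0" %in% names(labels)) labels <- c("0" = "background", labels)
  new("LabelVolume", data = data, labels = labels,
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      axisTag = axisTag)
}

#' Construct a DisplacementField
#'
#' @param data 4D array \code{c(grid, 3)} of mm displacements, or NULL to
#'   create a zero field of dims \code{dim}.
#' @param spacing,origin grid geometry (mm).
#' @param dim integer(3) grid dims, used when \code{data} is NULL.
#' @return A [DisplacementField] under the pull-back convention.
#' @examples
#' zf <- zeroField(c(8, 8, 8), spacing = 2)
#' maxDisplacement(zf)
#' @export
Field <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                  dim = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  if (is.null(data)) data <- array(0, c(dim, 3L))
  new("DisplacementField", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), convention = "pullback")
}

#' @rdname Field
#' @export
zeroField <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  Field(NULL, spacing = spacing, origin = origin, dim = as.integer(dim))
}

#' Construct an AffineTransform3D
#'
#' @param linear 3x3 linear part (physical coordinates).
#' @param translation numeric(3) mm.
#' @return An [AffineTransform3D].
#' @export
Affine <- function(linear = diag(3), translation = c(0, 0, 0)) {
  new("AffineTransform3D", linear = linear,
      translation = as.numeric(translation))
}

#' Identity affine transform
#' @return An [AffineTransform3D] equal to the identity.
#' @export
identityAffine <- function() Affine()

# ---- accessors --------------------------------------------------------------

#' Grid accessors
#'
#' @param x a [BodyVolume], [DisplacementField] or other [Gridded] object.
#' @return \code{dims}: integer(3) grid dims; \code{volSpacing} /
#'   \code{volOrigin}: numeric(3) mm; \code{volData}: the underlying array.
#' @export
setGeneric("dims", function(x) standardGeneric("dims"))

#' @rdname dims
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))

#' @rdname dims
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))

#' @rdname dims
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname dims
setMethod("dims", "BodyVolume", function(x) dim(x@data))

#' @rdname dims
setMethod("dims", "DisplacementField", function(x) dim(x@data)[1:3])

#' @rdname dims
setMethod("volSpacing", "Gridded", function(x) x@spacing)

#' @rdname dims
setMethod("volOrigin", "Gridded", function(x) x@origin)

#' @rdname dims
setMethod("volData", "BodyVolume", function(x) x@data)

#' @rdname dims
setMethod("volData", "DisplacementField", function(x) x@data)

#' Label dictionary of a LabelVolume
#' @param x a [LabelVolume].
#' @return Named character vector (ids as names).
#' @export
labelDictionary <- function(x) {
  stopifnot(is(x, "LabelVolume"))
  x@labels
}

#' Largest displacement magnitude of a field (mm)
#' @param x a [DisplacementField].
#' @return Scalar mm.
#' @export
maxDisplacement <- function(x) {
  d <- dims(x)
  n <- prod(d)
  u <- x@data
  sqrt(max(u[seq_len(n)]^2 + u[n + seq_len(n)]^2 + u[2 * n + seq_len(n)]^2))
}

#' Atlas accessors
#'
#' @param x a [BodyAtlas].
#' @return \code{atlasAnatomy}: the anatomical [BodyVolume];
#'   \code{atlasProbability}: named list of probability volumes;
#'   \code{atlasCoverage}: the coverage [BodyVolume];
#'   \code{isUnbiased}: logical flag from provenance.
#' @export
atlasAnatomy <- function(x) x@anatomy

#' @rdname atlasAnatomy
#' @export
atlasProbability <- function(x) x@probability

#' @rdname atlasAnatomy
#' @export
atlasCoverage <- function(x) x@coverage

#' @rdname atlasAnatomy
#' @export
isUnbiased <- function(x) isTRUE(x@provenance$unbiased)

# ---- show methods -----------------------------------------------------------

setMethod("show", "BodyVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d, spacing %s mm, range [%.4g, %.4g]\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume %dx%dx%d, %d structures: %s\n",
              d[1], d[2], d[3], sum(names(object@labels) != "0"),
              paste(object@labels[names(object@labels) != "0"],
                    collapse = ", ")))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DisplacementField %dx%dx%d (pull-back), max |u| = %.3f mm\n",
    d[1], d[2], d[3], maxDisplacement(object)))
})

setMethod("show", "AffineTransform3D", function(object) {
  cat("AffineTransform3D  y = L x + t (mm)\n")
  cat("  t =", paste(signif(object@translation, 5), collapse = ", "), "\n")
  print(signif(object@linear, 5))
})

setMethod("show", "BodyAtlas", function(object) {
  cat(sprintf("BodyAtlas (%s) of %d subjects, %d probability maps\n",
              if (isUnbiased(object)) "unbiased" else "initial",
              object@nSubjects, length(object@probability)))
})

setMethod("show", "VoxelZMap", function(object) {
  ns <- sum(object@sigMask@data > 0)
  cat(sprintf("VoxelZMap: %d significant voxels (q = %g, p < %g), %d flagged\n",
              ns, object@params$q, object@params$pRetain, object@flagged))
})

# ---- internal grid helpers --------------------------------------------------

sameGrid <- function(a, b, tol = 1e-8) {
  all(dims(a) == dims(b)) &&
    all(abs(volSpacing(a) - volSpacing(b)) < tol) &&
    all(abs(volOrigin(a) - volOrigin(b)) < tol)
}

stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b))
    stop(sprintf("grid mismatch between %s: dims/spacing/origin differ", what),
         call. = FALSE)
  invisible(TRUE)
}

# physical coordinates (mm) of all voxel centres, as three arrays
gridCoords <- function(dim, spacing, origin) {
  list(
    x = array(origin[1] + (seq_len(dim[1]) - 1) * spacing[1], dim),
    y = array(rep(origin[2] + (seq_len(dim[2]) - 1) * spacing[2],
                  each = dim[1]), dim),
    z = array(rep(origin[3] + (seq_len(dim[3]) - 1) * spacing[3],
                  each = dim[1] * dim[2]), dim)
  )
}
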