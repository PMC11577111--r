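# Transform algebra on volumes and displacement fields.  Everything here
# follows the package-wide pull-back convention: a field u on the fixed grid
# maps fixed points x to moving points x + u(x), and warping resamples the
# moving image at those points, so outputs always live on the fixed grid.

#' Warp a volume with a displacement field
#'
#' Resamples \code{moving} at \code{x + u(x)} for every voxel centre
#' \code{x} of the field's (fixed) grid.  Samples outside the moving domain
#' take \code{fill} (0, background).
#'
#' @param moving a [BodyVolume] (or [LabelVolume]) to resample.
#' @param field a [DisplacementField] on the output grid.
#' @param interpolation \code{"linear"} for intensities, \code{"nearest"}
#'   for raw label ids.
#' @param fill out-of-domain fill value.
#' @return A volume of the same class as \code{moving} on the field's grid.
#' @examples
#' v <- Volume(array(rnorm(8^3), c(8, 8, 8)))
#' w <- warpVolume(v, zeroField(c(8, 8, 8)))
#' stopifnot(identical(volData(w), volData(v)))
#' @export
warpVolume <- function(moving, field, interpolation = c("linear", "nearest"),
                       fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(moving, "BodyVolume"), is(field, "DisplacementField"))
  fd <- dims(field)
  out <- .C_warp(as.numeric(moving@data), dim(moving@data),
                 moving@spacing, moving@origin,
                 as.numeric(field@data), fd, field@spacing, field@origin,
                 as.integer(interpolation == "nearest"), fill)
  arr <- array(out, fd)
  if (is(moving, "LabelVolume") && interpolation == "nearest")
    LabelMap(arr, moving@labels, spacing = field@spacing,
             origin = field@origin, axisTag = moving@axisTag)
  else
    Volume(arr, spacing = field@spacing, origin = field@origin,
           axisTag = moving@axisTag)
}

#' Compose two displacement fields
#'
#' Returns the field whose warp equals warping by \code{outer} first and by
#' \code{inner} second, i.e. the map \eqn{\phi_{outer} \circ \phi_{inner}}:
#' \code{u(x) = u_inner(x) + u_outer(x + u_inner(x))}.  Composing with a zero
#' field returns the other field up to interpolation.
#'
#' @param outer,inner [DisplacementField]s on the same grid.
#' @return A [DisplacementField].
#' @export
composeFields <- function(outer, inner) {
  stopIfGridMismatch(outer, inner, "composed fields")
  d <- dims(inner)
  out <- .C_compose(as.numeric(outer@data), as.numeric(inner@data),
                    d, inner@spacing)
  Field(array(out, c(d, 3L)), spacing = inner@spacing, origin = inner@origin)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Iterates \code{u_inv(x) <- -u(x + u_inv(x))} until the largest voxel
#' update falls below \code{tol} (mm).  Intended for diffeomorphic or
#' small-magnitude fields; non-convergence is signalled, not silently
#' returned.
#'
#' @param field a [DisplacementField].
#' @param tol convergence tolerance in mm.
#' @param maxIter maximum iterations.
#' @param onFail \code{"error"} (default) or \code{"warn"} on
#'   non-convergence.
#' @return The inverse [DisplacementField]; attribute \code{residual} holds
#'   the achieved last update in mm.
#' @export
invertField <- function(field, tol = 0.01, maxIter = 50L, onFail = "error") {
  stopifnot(is(field, "DisplacementField"), tol > 0)
  d <- dims(field)
  out <- .C_invert(as.numeric(field@data), d, field@spacing, tol,
                   as.integer(maxIter))
  if (!attr(out, "converged")) {
    msg <- sprintf(
      "field inversion did not converge in %d iterations (residual %.4g mm > tol %.4g mm)",
      maxIter, attr(out, "residual"), tol)
    if (identical(onFail, "error")) stop(msg, call. = FALSE) else warning(msg)
  }
  res <- Field(array(as.numeric(out), c(d, 3L)), spacing = field@spacing,
               origin = field@origin)
  attr(res, "residual") <- attr(out, "residual")
  res
}

#' Integrate a stationary velocity field (scaling and squaring)
#'
#' The unit-time flow of a stationary velocity \code{v} (mm) is computed by
#' scaling the field by \code{2^-squaringSteps} and recursively composing it
#' with itself \code{squaringSteps} times.  For velocities whose scaled step
#' stays below about 0.4 voxel the result is diffeomorphic (folding ratio 0).
#'
#' @param velocity a [DisplacementField] holding the velocity in mm.
#' @param squaringSteps non-negative integer.
#' @return A [DisplacementField] displacement.
#' @export
integrateVelocity <- function(velocity, squaringSteps = 6L) {
  stopifnot(is(velocity, "DisplacementField"), squaringSteps >= 0)
  d <- dims(velocity)
  u <- velocity@data / 2^squaringSteps
  for (s in seq_len(squaringSteps))
    u <- array(.C_compose(as.numeric(u), as.numeric(u), d, velocity@spacing),
               c(d, 3L))
  Field(u, spacing = velocity@spacing, origin = velocity@origin)
}

#' Jacobian determinant of a transformation
#'
#' Computes \code{det(I + grad u)} per voxel, derivatives in physical mm via
#' central differences (one-sided at the boundary).
#'
#' @param field a [DisplacementField].
#' @return A [BodyVolume] of determinants.
#' @export
jacobianDeterminant <- function(field) {
  stopifnot(is(field, "DisplacementField"))
  d <- dims(field)
  if (any(d < 3)) stop("grid must have at least 3 voxels per axis")
  out <- .C_jacdet(as.numeric(field@data), d, field@spacing)
  Volume(array(out, d), spacing = field@spacing, origin = field@origin)
}

#' Downsample a volume by an integer factor
#'
#' Gaussian anti-alias prefilter (sigma \code{0.5 * sqrt(factor^2 - 1)}
#' voxels) followed by decimation; spacing is multiplied by the factor and
#' the origin is kept at the first retained voxel centre.
#'
#' @param volume a [BodyVolume].
#' @param factor integer >= 1.
#' @return A [BodyVolume].
#' @export
downsampleVolume <- function(volume, factor = 2L) {
  stopifnot(is(volume, "BodyVolume"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(volume)
  d <- dim(volume@data)
  if (any(factor > d)) stop("downsampling factor exceeds grid size")
  sigma <- 0.5 * sqrt(factor^2 - 1)
  sm <- array(.C_gauss3d(as.numeric(volume@data), d, rep(sigma, 3)), d)
  idx <- lapply(d, function(n) seq(1L, n, by = factor))
  Volume(sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         spacing = volume@spacing * factor, origin = volume@origin,
         axisTag = volume@axisTag)
}

#' Resample a displacement field onto a target grid
#'
#' Interpolates the mm vector components linearly at the target voxel
#' centres (edge-clamped); used to carry coarse-level fields to finer
#' pyramid levels.
#'
#' @param field a [DisplacementField].
#' @param dim integer(3) target grid dims.
#' @param spacing,origin target grid geometry (mm).
#' @return A [DisplacementField] on the target grid.
#' @export
upsampleField <- function(field, dim, spacing, origin = field@origin) {
  stopifnot(is(field, "DisplacementField"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dim <- as.integer(dim)
  # sample each component at target voxel centres via a zero warp whose grid
  # is the target; component volumes are sampled with edge clamping through
  # the compose kernel (zero inner displacement)
  tgt <- zeroField(dim, spacing = spacing, origin = origin)
  comp <- lapply(1:3, function(cc) {
    v <- Volume(field@data[, , , cc], spacing = field@spacing,
                origin = field@origin)
    volData(warpVolume(v, tgt, fill = 0))
  })
  Field(array(c(comp[[1]], comp[[2]], comp[[3]]), c(dim, 3L)),
        spacing = spacing, origin = origin)
}

#' Rasterise an affine transform as a displacement field
#'
#' \code{u(x) = (L x + t) - x} at the voxel centres of the given grid, in
#' physical mm.
#'
#' @param affine an [AffineTransform3D].
#' @param dim integer(3) grid dims.
#' @param spacing,origin grid geometry (mm).
#' @return A [DisplacementField].
#' @export
affineToField <- function(affine, dim, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0)) {
  stopifnot(is(affine, "AffineTransform3D"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  dim <- as.integer(dim)
  g <- gridCoords(dim, spacing, origin)
  L <- affine@linear
  t <- affine@translation
  ux <- L[1, 1] * g$x + L[1, 2] * g$y + L[1, 3] * g$z + t[1] - g$x
  uy <- L[2, 1] * g$x + L[2, 2] * g$y + L[2, 3] * g$z + t[2] - g$y
  uz <- L[3, 1] * g$x + L[3, 2] * g$y + L[3, 3] * g$z + t[3] - g$z
  Field(array(c(ux, uy, uz), c(dim, 3L)), spacing = spacing, origin = origin)
}

#' Affine algebra
#'
#' \code{composeAffine(a, b)} returns the affine mapping \code{x} to
#' \code{a(b(x))}; \code{invertAffine} the exact inverse.
#'
#' @param a,b,affine [AffineTransform3D] objects.
#' @return An [AffineTransform3D].
#' @export
composeAffine <- function(a, b) {
  Affine(a@linear %*% b@linear,
         as.numeric(a@linear %*% b@translation) + a@translation)
}

#' @rdname composeAffine
#' @export
invertAffine <- function(affine) {
  Li <- solve(affine@linear)
  Affine(Li, as.numeric(-Li %*% affine@translation))
}

#' Decompose the linear part of an affine transform
#'
#' Polar decomposition \code{L = R P} (rotation times symmetric positive
#' stretch) via SVD; reports the rotation angle and per-axis stretch factors,
#' convenient for checking recovered against planted transforms.
#'
#' @param affine an [AffineTransform3D].
#' @return List with \code{rotation} (3x3), \code{stretch} (3x3),
#'   \code{angleDeg} (total rotation angle, degrees), \code{scales}
#'   (eigenvalues of the stretch).
#' @export
affineParameters <- function(affine) {
  s <- svd(affine@linear)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {  # keep a proper rotation
    s$v[, 3] <- -s$v[, 3]
    s$d[3] <- -s$d[3]
    R <- s$u %*% t(s$v)
  }
  P <- s$v %*% diag(s$d) %*% t(s$v)
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  list(rotation = R, stretch = P, angleDeg = ang, scales = sort(s$d))
}

#' Gaussian smoothing of a volume (voxel-unit sigma)
#'
#' Internal-grade helper shared by the pyramid, the phantom velocity
#' generator and [smoothVolume()]; sigma is per axis in voxels.
#'
#' @param volume a [BodyVolume].
#' @param sigmaVox numeric(3) (or scalar) sigma in voxels.
#' @return A [BodyVolume].
#' @export
gaussSmooth <- function(volume, sigmaVox) {
  if (length(sigmaVox) == 1L) sigmaVox <- rep(sigmaVox, 3L)
  d <- dim(volume@data)
  out <- .C_gauss3d(as.numeric(volume@data), d, as.numeric(sigmaVox))
  Volume(array(out, d), spacing = volume@spacing, origin = volume@origin,
         axisTag = volume@axisTag)
}
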