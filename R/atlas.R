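# Atlas construction and unbiasing.  With per-subject fields phi_i mapping
# reference-space points into subject space (pull-back), the initial atlas is
# the voxel-wise mean of the warped subjects, A_init = (1/n) sum I_i o phi_i.
# The unbiasing step warps the initial atlas by the average of the inverted
# subject fields, Phi = (1/n) sum phi_i^-1, so the result reflects the
# population's mean geometry rather than the reference subject's.

#' Average registered subjects into an initial anatomical atlas
#'
#' Computes \code{A_init = (1/n) sum I_i o phi_i} on the reference grid.
#' Voxels where no subject sampled inside its domain are 0; the per-voxel
#' fraction of in-domain subjects is returned as a coverage map.
#'
#' @param images list of subject [BodyVolume]s.
#' @param fields list of [DisplacementField]s on the reference grid, one per
#'   subject.
#' @return List: \code{atlas} ([BodyVolume]), \code{coverage}
#'   ([BodyVolume] in \code{[0, 1]}).
#' @export
buildInitialAtlas <- function(images, fields) {
  n <- length(images)
  if (n == 0L) stop("empty subject list", call. = FALSE)
  if (length(fields) != n)
    stop("images and fields must have equal length", call. = FALSE)
  ref <- fields[[1]]
  d <- dims(ref)
  acc <- array(0, d)
  cov <- array(0, d)
  for (i in seq_len(n)) {
    stopIfGridMismatch(fields[[i]], ref, "subject fields")
    w <- warpVolume(images[[i]], fields[[i]], "linear", fill = 0)
    ones <- Volume(array(1, dim(images[[i]]@data)), images[[i]]@spacing,
                   images[[i]]@origin)
    ind <- warpVolume(ones, fields[[i]], "nearest", fill = 0)
    acc <- acc + w@data
    cov <- cov + ind@data
  }
  list(atlas = Volume(acc / n, ref@spacing, ref@origin),
       coverage = Volume(cov / n, ref@spacing, ref@origin))
}

#' Probabilistic label atlases
#'
#' One-hot encodes each structure, warps the indicator with linear
#' interpolation (so probabilities stay smooth), and averages over subjects:
#' the value at a voxel is the estimated probability of finding the
#' structure there.
#'
#' @param labels list of subject [LabelVolume]s sharing one dictionary.
#' @param fields list of [DisplacementField]s on the reference grid.
#' @param ids integer ids to map (default: all non-background ids).
#' @return Named list of probability [BodyVolume]s.
#' @export
buildLabelAtlas <- function(labels, fields, ids = NULL) {
  n <- length(labels)
  if (n == 0L) stop("empty subject list", call. = FALSE)
  dict <- labelDictionary(labels[[1]])
  for (l in labels[-1])
    if (!identical(labelDictionary(l), dict))
      stop("inconsistent label dictionaries", call. = FALSE)
  if (is.null(ids)) {
    ids <- as.integer(names(dict))
    ids <- ids[ids != 0L]
  }
  ref <- fields[[1]]
  d <- dims(ref)
  out <- list()
  for (id in ids) {
    acc <- array(0, d)
    for (i in seq_len(n)) {
      onehot <- Volume((labels[[i]]@data == id) + 0, labels[[i]]@spacing,
                       labels[[i]]@origin)
      acc <- acc + warpVolume(onehot, fields[[i]], "linear", fill = 0)@data
    }
    out[[dict[[as.character(id)]]]] <-
      Volume(pmin(pmax(acc / n, 0), 1), ref@spacing, ref@origin)
  }
  out
}

#' Average inverse transformation field
#'
#' Inverts every subject field by fixed-point iteration and averages the
#' inverses vector-wise on the reference grid:
#' \code{Phi = (1/n) sum phi_i^-1}.  Per-field inversion residuals (mm) are
#' attached as the \code{"residuals"} attribute; a non-convergent inversion
#' aborts with the offending subject's index.
#'
#' @param fields list of [DisplacementField]s.
#' @param tol,maxIter passed to [invertField()].
#' @return A [DisplacementField] (Phi).
#' @export
averageInverseField <- function(fields, tol = 0.01, maxIter = 50L) {
  n <- length(fields)
  if (n == 0L) stop("empty field list", call. = FALSE)
  ref <- fields[[1]]
  acc <- array(0, dim(ref@data))
  resid <- numeric(n)
  for (i in seq_len(n)) {
    stopIfGridMismatch(fields[[i]], ref, "subject fields")
    inv <- tryCatch(invertField(fields[[i]], tol = tol, maxIter = maxIter),
                    error = function(e)
                      stop(sprintf("inversion failed for subject %d: %s",
                                   i, conditionMessage(e)), call. = FALSE))
    resid[i] <- attr(inv, "residual")
    acc <- acc + inv@data
  }
  out <- Field(acc / n, ref@spacing, ref@origin)
  attr(out, "residuals") <- resid
  out
}

#' Assemble a BodyAtlas object
#'
#' Builds the initial anatomical and label atlases from registered subjects.
#'
#' @param images list of subject [BodyVolume]s.
#' @param labels list of subject [LabelVolume]s (or NULL for anatomy only).
#' @param fields list of [DisplacementField]s on the reference grid.
#' @param referenceId id string recorded in provenance.
#' @return A [BodyAtlas] (initial, biased).
#' @export
buildAtlas <- function(images, labels = NULL, fields, referenceId = "") {
  a <- buildInitialAtlas(images, fields)
  prob <- if (is.null(labels)) list() else buildLabelAtlas(labels, fields)
  new("BodyAtlas", anatomy = a$atlas, probability = prob,
      coverage = a$coverage, nSubjects = length(images),
      provenance = list(reference = referenceId, unbiased = FALSE))
}

#' Unbias an atlas with the average inverse field
#'
#' Warps the anatomical volume, every probability volume and the coverage
#' map by \code{Phi} (\code{A_u = A_init o Phi}), yielding an atlas that
#' represents the population's mean geometry.  Linear interpolation keeps
#' probabilities inside \code{[0, 1]}.
#'
#' @param atlas a [BodyAtlas] built with [buildAtlas()].
#' @param fields the same subject fields used to build it (used to compute
#'   \code{Phi}), or NULL when \code{phi} is given.
#' @param phi optionally a precomputed average inverse [DisplacementField].
#' @param tol,maxIter inversion settings, see [averageInverseField()].
#' @return A [BodyAtlas] with the unbiased flag set.
#' @export
unbiasAtlas <- function(atlas, fields = NULL, phi = NULL, tol = 0.01,
                        maxIter = 50L) {
  if (is.null(phi)) {
    if (is.null(fields)) stop("need fields or phi", call. = FALSE)
    phi <- averageInverseField(fields, tol = tol, maxIter = maxIter)
  }
  warp1 <- function(v) warpVolume(v, phi, "linear", fill = 0)
  prob <- lapply(atlas@probability, function(p) {
    q <- warp1(p)
    q@data <- pmin(pmax(q@data, 0), 1)
    q
  })
  new("BodyAtlas", anatomy = warp1(atlas@anatomy), probability = prob,
      coverage = warp1(atlas@coverage), nSubjects = atlas@nSubjects,
      provenance = modifyList(atlas@provenance, list(unbiased = TRUE)))
}
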