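# Registration-quality metrics: Dice overlap, 95th-percentile Hausdorff
# distance on mask surfaces, folding ratio of deformation fields, and the
# per-stage group evaluation report.

#' Dice overlap of two binary masks
#'
#' \code{2|A n B| / (|A| + |B|)}.  Convention for degenerate inputs: 1 when
#' both masks are empty, 0 when exactly one is empty.
#'
#' @param a,b binary [BodyVolume]s or arrays on the same grid.
#' @return Scalar in \code{[0, 1]}.
#' @export
diceCoefficient <- function(a, b) {
  A <- if (is(a, "BodyVolume")) a@data > 0 else a > 0
  B <- if (is(b, "BodyVolume")) b@data > 0 else b > 0
  if (!all(dim(A) == dim(B))) stop("grid mismatch", call. = FALSE)
  sa <- sum(A)
  sb <- sum(B)
  if (sa == 0 && sb == 0) return(1)
  if (sa == 0 || sb == 0) return(0)
  2 * sum(A & B) / (sa + sb)
}

#' Per-label Dice scores
#'
#' @param a,b [LabelVolume]s sharing a label dictionary.
#' @param ids integer ids to evaluate (default: all non-background ids of
#'   \code{a}).
#' @return Named numeric vector of Dice scores.
#' @export
dicePerLabel <- function(a, b, ids = NULL) {
  if (is.null(ids)) {
    ids <- as.integer(names(labelDictionary(a)))
    ids <- ids[ids != 0L]
  }
  vapply(ids, function(id) diceCoefficient(a@data == id, b@data == id),
         numeric(1)) |>
    setNames(labelDictionary(a)[as.character(ids)])
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Surface-to-surface distances between the 6-connectivity boundary voxels
#' of the two masks, computed with an exact Euclidean distance transform;
#' the symmetric HD95 is the maximum of the two directed 95th percentiles
#' (quantile type 7).
#'
#' @param a,b non-empty binary [BodyVolume]s or arrays on the same grid.
#' @param spacing mm, taken from \code{a} when it is a [BodyVolume].
#' @return Scalar mm.
#' @export
hausdorff95 <- function(a, b, spacing = NULL) {
  if (is(a, "BodyVolume") && is.null(spacing)) spacing <- a@spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  A <- if (is(a, "BodyVolume")) a@data > 0 else a > 0
  B <- if (is(b, "BodyVolume")) b@data > 0 else b > 0
  if (!all(dim(A) == dim(B))) stop("grid mismatch", call. = FALSE)
  if (!any(A) || !any(B)) stop("empty mask", call. = FALSE)
  d <- dim(A)
  surf <- function(M) {
    m <- as.integer(M)
    er <- array(.C_morph_box(m, d, 0L), d)
    M & er == 0L
  }
  sa <- surf(A)
  sb <- surf(B)
  dta <- sqrt(array(.C_edt(as.integer(sa), d, spacing), d))
  dtb <- sqrt(array(.C_edt(as.integer(sb), d, spacing), d))
  dAB <- quantile(dtb[sa], 0.95, names = FALSE, type = 7)
  dBA <- quantile(dta[sb], 0.95, names = FALSE, type = 7)
  max(dAB, dBA)
}

#' Folding ratio of a transformation
#'
#' Fraction of interior voxels (one-voxel boundary excluded, where one-sided
#' differences would bias the estimate) whose Jacobian determinant is
#' non-positive.  0 for a diffeomorphic field.
#'
#' @param field a [DisplacementField].
#' @return Scalar in \code{[0, 1]}.
#' @export
foldingRatio <- function(field) {
  jd <- jacobianDeterminant(field)@data
  d <- dim(jd)
  interior <- jd[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  mean(interior <= 0)
}

#' Per-stage registration metrics for a group
#'
#' For each named stage (e.g. pre, affine, deformable) warps every subject's
#' labels to the reference with that stage's field (nearest-neighbour) and
#' reports per-label Dice, mean Dice, mean HD95 and, for deformable stages,
#' the folding ratio — mean and sd across subjects.
#'
#' @param subjectLabels list of [LabelVolume]s (moving).
#' @param referenceLabels [LabelVolume] (fixed).
#' @param stageFields named list (stage -> list of [DisplacementField]s,
#'   one per subject; NULL entries mean identity).
#' @param ids label ids to evaluate (default: the five organs, 3:7).
#' @return A data.frame with one row per stage and subject plus summary
#'   attribute \code{"summary"} (mean/sd per stage).
#' @export
evaluateGroup <- function(subjectLabels, referenceLabels, stageFields,
                          ids = 3:7) {
  rows <- list()
  for (stage in names(stageFields)) {
    flds <- stageFields[[stage]]
    for (i in seq_along(subjectLabels)) {
      lab <- subjectLabels[[i]]
      if (is.null(lab)) {
        message(sprintf("subject %d skipped in stage %s: missing labels",
                        i, stage))
        next
      }
      f <- flds[[i]]
      if (is.null(f))
        f <- zeroField(dims(referenceLabels), volSpacing(referenceLabels),
                       volOrigin(referenceLabels))
      w <- warpVolume(lab, f, "nearest")
      dc <- dicePerLabel(referenceLabels, w, ids = ids)
      hd <- vapply(ids, function(id) {
        if (!any(w@data == id) || !any(referenceLabels@data == id))
          return(NA_real_)
        hausdorff95(referenceLabels@data == id, w@data == id,
                    spacing = volSpacing(referenceLabels))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stage, subject = i, meanDice = mean(dc),
        meanHD95 = mean(hd, na.rm = TRUE),
        foldingRatio = foldingRatio(f),
        t(as.matrix(dc)), check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$stage), function(s) {
    data.frame(stage = s$stage[1], meanDice = mean(s$meanDice),
               sdDice = sd(s$meanDice), meanHD95 = mean(s$meanHD95),
               sdHD95 = sd(s$meanHD95), foldingRatio = mean(s$foldingRatio))
  }))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}
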