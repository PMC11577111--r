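# Pre-processing: min-max intensity normalisation, percentile-window
# contrast enhancement, automatic body masking, and centre-of-mass / ICP
# spatial initialisation.  Intensity statistics are computed inside the body
# mask wherever one is available, so background noise cannot shift the scale.

#' Min-max normalise a volume to [0, 1]
#'
#' Linear map of the observed \code{[min, max]} to \code{[0, 1]}.  With a
#' mask, the extrema are taken inside the mask only and out-of-mask voxels
#' are set to 0.
#'
#' @param v a [BodyVolume].
#' @param mask optional binary array or [BodyVolume]; statistics and output
#'   support are restricted to it.
#' @return A [BodyVolume] in \code{[0, 1]}.
#' @export
minmaxNormalize <- function(v, mask = NULL) {
  m <- .asMaskArray(mask, dim(v@data))
  vals <- if (is.null(m)) v@data else v@data[m]
  lo <- min(vals)
  hi <- max(vals)
  if (hi - lo <= 0)
    stop("constant volume: min-max normalisation is undefined", call. = FALSE)
  out <- (v@data - lo) / (hi - lo)
  if (!is.null(m)) out[!m] <- 0
  out <- pmin(pmax(out, 0), 1)
  Volume(array(out, dim(v@data)), spacing = v@spacing, origin = v@origin,
         axisTag = v@axisTag)
}

#' Contrast enhancement by percentile clipping
#'
#' Clips intensities at the lower/upper percentiles of the (optionally
#' masked) histogram and rescales the clipped range to \code{[0, 1]},
#' accentuating tissue boundaries.
#'
#' @param v a [BodyVolume].
#' @param lowerPct,upperPct percentile window, \code{0 <= lower < upper <= 100}.
#' @param mask optional mask, as in [minmaxNormalize()].
#' @return A [BodyVolume].
#' @export
enhanceContrast <- function(v, lowerPct = 1, upperPct = 99, mask = NULL) {
  if (!(lowerPct >= 0 && lowerPct < upperPct && upperPct <= 100))
    stop("need 0 <= lowerPct < upperPct <= 100", call. = FALSE)
  m <- .asMaskArray(mask, dim(v@data))
  vals <- if (is.null(m)) v@data else v@data[m]
  qs <- quantile(vals, c(lowerPct, upperPct) / 100, names = FALSE, type = 7)
  if (qs[2] - qs[1] <= 0)
    stop("degenerate percentile window: clipped range is constant",
         call. = FALSE)
  out <- pmin(pmax(v@data, qs[1]), qs[2])
  out <- (out - qs[1]) / (qs[2] - qs[1])
  if (!is.null(m)) out[!m] <- 0
  Volume(array(out, dim(v@data)), spacing = v@spacing, origin = v@origin,
         axisTag = v@axisTag)
}

# Otsu thresholding on a 256-bin histogram (maximising between-class
# variance).  nthresh = 1 is the classic bimodal split; nthresh = 2 is the
# three-class variant whose *lowest* threshold separates the dark background
# from all tissue classes — the right split for body images, where fat and
# lean tissue form distinct bright modes.
.otsu <- function(vals, nbins = 256L, nthresh = 1L) {
  lo <- min(vals)
  hi <- max(vals)
  if (hi <= lo) stop("constant volume: no threshold", call. = FALSE)
  h <- as.numeric(tabulate(pmin(pmax(floor((vals - lo) / (hi - lo) * nbins) + 1L,
                                     1L), nbins), nbins))
  W <- cumsum(h)
  MU <- cumsum(h * seq_len(nbins))
  csum <- function(i, j) {          # class (i, j]: weight and mean
    w <- W[j] - if (i > 0) W[i] else 0
    m <- MU[j] - if (i > 0) MU[i] else 0
    c(w, if (w > 0) m / w else 0)
  }
  if (nthresh == 1L) {
    best <- -Inf
    kbest <- 1L
    for (k in 1:(nbins - 1)) {
      a <- csum(0, k)
      b <- csum(k, nbins)
      if (a[1] == 0 || b[1] == 0) next
      bc <- a[1] * b[1] * (a[2] - b[2])^2
      if (bc > best) { best <- bc; kbest <- k }
    }
    return(lo + kbest / nbins * (hi - lo))
  }
  best <- -Inf
  kbest <- c(1L, 2L)
  for (k1 in 1:(nbins - 2)) {
    a <- csum(0, k1)
    if (a[1] == 0) next
    for (k2 in (k1 + 1):(nbins - 1)) {
      b <- csum(k1, k2)
      c_ <- csum(k2, nbins)
      if (b[1] == 0 || c_[1] == 0) next
      mt <- MU[nbins] / W[nbins]
      bc <- a[1] * (a[2] - mt)^2 + b[1] * (b[2] - mt)^2 +
        c_[1] * (c_[2] - mt)^2
      if (bc > best) { best <- bc; kbest <- c(k1, k2) }
    }
  }
  lo + kbest / nbins * (hi - lo)
}

#' Automatic body mask
#'
#' Three-class Otsu thresholding of the intensity histogram (the lowest
#' threshold separates the dark background from the fat and lean tissue
#' modes), largest 6-connected foreground component, morphological closing
#' (3x3x3 box), and interior hole filling.  The result is a single connected
#' component without interior holes.
#'
#' @param v a [BodyVolume]; the background must be darker than the body.
#' @return A [BodyMask]; provenance records the threshold and component
#'   sizes.
#' @export
bodyMask <- function(v) {
  d <- dim(v@data)
  if (all(v@data == 0)) stop("empty foreground", call. = FALSE)
  # a large mass of exactly-zero voxels marks an already-masked (or
  # noise-free synthetic) background: anything positive is tissue.  Raw
  # scanner data never has this, and goes through the histogram threshold.
  thr <- if (mean(v@data == 0) >= 0.25) 0
         else .otsu(as.numeric(v@data), nthresh = 2L)[1]
  fg <- as.integer(v@data > thr)
  if (sum(fg) == 0) stop("empty foreground", call. = FALSE)
  lab <- .C_label6(fg, d)
  ncomp <- max(lab)
  m <- as.integer(lab == 1L)  # largest component
  m <- .C_morph_box(.C_morph_box(m, d, 1L), d, 0L)  # closing
  # hole filling: background components not touching the volume boundary
  bg <- as.integer(m == 0L)
  bl <- array(.C_label6(bg, d), d)
  border <- unique(c(bl[1, , ], bl[d[1], , ], bl[, 1, ], bl[, d[2], ],
                     bl[, , 1], bl[, , d[3]]))
  border <- border[border > 0]
  hole <- bl > 0 & !(bl %in% border)
  m <- array(m, d)
  m[hole] <- 1L
  new("BodyMask", data = m + 0, spacing = v@spacing, origin = v@origin,
      axisTag = v@axisTag,
      provenance = list(threshold = thr, componentsFound = ncomp,
                        componentsKept = 1L, holeVoxelsFilled = sum(hole)))
}

.asMaskArray <- function(mask, d) {
  if (is.null(mask)) return(NULL)
  if (is(mask, "BodyVolume")) mask <- mask@data
  stopifnot(all(dim(mask) == d))
  mask > 0
}

# surface voxels of a binary mask: 6-neighbour erosion difference, returned
# as an n x 3 matrix of physical coordinates (mm)
.maskSurface <- function(mask, spacing, origin) {
  d <- dim(mask)
  m <- as.integer(mask > 0)
  er <- array(.C_morph_box(m, d, 0L), d)
  surf <- which(m == 1L & er == 0L, arr.ind = TRUE)
  sweep(sweep(surf - 1, 2, spacing, "*"), 2, origin, "+")
}

#' Centre-of-mass / ICP spatial initialisation
#'
#' \code{mode = "com"}: the translation aligning the mask centroids.
#' \code{mode = "icp"}: rigid refinement on mask surface points, initialised
#' at the centroid translation, with nearest-neighbour correspondences and a
#' Kabsch update per iteration.  The returned transform maps fixed points
#' into moving space (pull-back convention), so warping the moving mask by
#' it aligns it with the fixed mask.
#'
#' @param movingMask,fixedMask [BodyMask] (or binary [BodyVolume]) objects.
#' @param mode \code{"com"} or \code{"icp"}.
#' @param maxIter,tol ICP iteration cap and convergence tolerance (mm, mean
#'   surface distance change).
#' @param maxPoints surfaces are subsampled to at most this many points.
#' @param trim fraction of worst-matched correspondences dropped from each
#'   rigid update (trimmed ICP), for robustness to unmatched surface parts.
#' @return An [AffineTransform3D] (rigid).
#' @export
comAlign <- function(movingMask, fixedMask, mode = c("com", "icp"),
                     maxIter = 100L, tol = 1e-5, maxPoints = 2500L,
                     trim = 0.1) {
  mode <- match.arg(mode)
  md <- movingMask@data > 0
  fd <- fixedMask@data > 0
  if (!any(md) || !any(fd)) stop("empty mask", call. = FALSE)
  comOf <- function(mask, spacing, origin) {
    w <- which(mask, arr.ind = TRUE)
    colMeans(sweep(sweep(w - 1, 2, spacing, "*"), 2, origin, "+"))
  }
  cm <- comOf(md, movingMask@spacing, movingMask@origin)
  cf <- comOf(fd, fixedMask@spacing, fixedMask@origin)
  t0 <- cm - cf  # maps fixed points into moving space
  if (mode == "com") return(Affine(diag(3), t0))
  sub <- function(p, nmax) {
    if (nrow(p) <= nmax) return(p)
    p[seq(1, nrow(p), length.out = nmax), , drop = FALSE]
  }
  pf <- sub(.maskSurface(fd, fixedMask@spacing, fixedMask@origin), maxPoints)
  pm <- sub(.maskSurface(md, movingMask@spacing, movingMask@origin), maxPoints)
  R <- diag(3)
  t <- t0
  lastErr <- Inf
  ok <- FALSE
  for (it in seq_len(maxIter)) {
    q <- sweep(pf %*% t(R), 2, t, "+")          # fixed surface in moving space
    nn <- .C_nn_index(q, pm)
    tgt <- pm[nn, , drop = FALSE]
    dists <- sqrt(rowSums((q - tgt)^2))
    err <- mean(dists)
    if (abs(lastErr - err) < tol) { ok <- TRUE; break }
    lastErr <- err
    # trimmed Kabsch: rigid transform onto the best-matched correspondences
    keep <- dists <= quantile(dists, 1 - trim, names = FALSE)
    src <- pf[keep, , drop = FALSE]
    dst <- tgt[keep, , drop = FALSE]
    mu1 <- colMeans(src)
    mu2 <- colMeans(dst)
    H <- t(sweep(src, 2, mu1)) %*% sweep(dst, 2, mu2)
    sv <- svd(H)
    Rn <- sv$v %*% t(sv$u)
    if (det(Rn) < 0) {
      sv$v[, 3] <- -sv$v[, 3]
      Rn <- sv$v %*% t(sv$u)
    }
    R <- Rn
    t <- as.numeric(mu2 - Rn %*% mu1)
  }
  if (!ok) {
    warning("ICP did not converge; falling back to centre-of-mass translation")
    return(Affine(diag(3), t0))
  }
  Affine(R, t)
}

#' Full pre-processing of one volume
#'
#' Body mask, then percentile contrast enhancement and min-max scaling
#' computed inside the mask, background set to 0.  Idempotent on its own
#' output up to numerical tolerance.
#'
#' @param v a [BodyVolume].
#' @param lowerPct,upperPct contrast window (percent).
#' @details In-mask intensities are floored at a tiny positive value
#'   (1e-7), so the body support stays exactly recoverable from the output
#'   (background is the only exact zero) and a second pre-processing pass
#'   reproduces the first to within that floor.
#' @return List: \code{volume} (normalised [BodyVolume]), \code{mask}
#'   ([BodyMask]), \code{report} (list of the parameters used).
#' @export
preprocessVolume <- function(v, lowerPct = 1, upperPct = 99) {
  mk <- bodyMask(v)
  inMask <- mk@data > 0
  vals <- v@data[inMask]
  # an input whose histogram is already saturated at both window ends has
  # been windowed before: re-clipping would only re-shuffle the saturated
  # tails, so it is passed through (masked) unchanged
  saturated <- mean(vals == min(vals)) >= lowerPct / 200 &&
    mean(vals == max(vals)) >= (100 - upperPct) / 200
  if (saturated) {
    out <- v@data
    out[!inMask] <- 0
    enh <- Volume(out, v@spacing, v@origin, v@axisTag)
  } else {
    enh <- enhanceContrast(v, lowerPct, upperPct, mask = mk)
    enh@data[inMask] <- pmax(enh@data[inMask], 1e-7)
  }
  list(volume = enh, mask = mk,
       report = list(lowerPct = lowerPct, upperPct = upperPct,
                     windowed = !saturated,
                     threshold = mk@provenance$threshold))
}
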