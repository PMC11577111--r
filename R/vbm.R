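# Voxel-based morphometry: Gaussian smoothing of atlas-space tissue maps, a
# per-voxel two-sample general linear model yielding a z-map, and
# Benjamini-Hochberg false-discovery-rate control with a high-significance
# retention threshold (corrected p < 0.001 by default).

#' Gaussian smoothing with a physical FWHM
#'
#' Spacing-aware Gaussian convolution, \code{sd = fwhm / 2.355} mm per axis;
#' \code{fwhm = 0} returns the input unchanged.
#'
#' @param v a [BodyVolume].
#' @param fwhm full width at half maximum, mm.
#' @return A [BodyVolume].
#' @export
smoothVolume <- function(v, fwhm) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(v)
  sigma <- fwhm / 2.355 / v@spacing
  gaussSmooth(v, sigma)
}

#' Voxel-wise two-sample GLM z-map
#'
#' Fits the two-group design (intercept + group indicator) per voxel, which
#' for this design is the pooled-variance two-sample t-test with
#' \code{nA + nB - 2} degrees of freedom.  The two-sided p-value is mapped
#' to a z-score by the probit transform, signed so that positive z means
#' the second group's mean exceeds the first's.  Voxels with zero
#' within-group variance get z = 0 and are counted in \code{flagged}.
#'
#' @param a,b lists of [BodyVolume]s (the two groups; \code{b} is the
#'   "pathological" group), all on one grid, at least two subjects each.
#' @param mask optional analysis mask (array or [BodyVolume]).
#' @return A [VoxelZMap]; the \code{p} volume holds the raw two-sided
#'   p-values until [fdrThreshold()] replaces them with corrected ones.
#' @export
glmGroupTest <- function(a, b, mask = NULL) {
  nA <- length(a)
  nB <- length(b)
  if (nA < 2 || nB < 2)
    stop("need at least two subjects per group", call. = FALSE)
  ref <- a[[1]]
  d <- dim(ref@data)
  m <- .asMaskArray(mask, d)
  if (is.null(m)) m <- array(TRUE, d)
  if (!any(m)) stop("empty mask", call. = FALSE)
  X <- vapply(a, function(v) v@data[m], numeric(sum(m)))
  Y <- vapply(b, function(v) v@data[m], numeric(sum(m)))
  mA <- rowMeans(X)
  mB <- rowMeans(Y)
  vA <- rowSums((X - mA)^2)
  vB <- rowSums((Y - mB)^2)
  df <- nA + nB - 2
  sp2 <- (vA + vB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tstat <- (mB - mA) / se
  zero <- !is.finite(tstat)      # zero pooled variance
  tstat[zero] <- 0
  p <- 2 * pt(-abs(tstat), df)
  z <- sign(tstat) * qnorm(pmax(p / 2, .Machine$double.xmin),
                           lower.tail = FALSE)
  z[zero] <- 0
  p[zero] <- 1
  mk <- function(vals, fill = 0) {
    arr <- array(fill, d)
    arr[m] <- vals
    Volume(arr, ref@spacing, ref@origin)
  }
  # zero-variance voxels carry no test: they are flagged, excluded from the
  # analysis mask and hence from the multiple-testing correction
  new("VoxelZMap", z = mk(z), p = mk(p, fill = 1),
      sigMask = mk(numeric(sum(m))), analysisMask = mk((!zero) + 0),
      flagged = as.integer(sum(zero)),
      params = list(nA = nA, nB = nB, q = NA_real_, pRetain = NA_real_))
}

#' FDR thresholding of a z-map
#'
#' Benjamini-Hochberg correction over the in-mask voxel p-values; the
#' significance mask keeps voxels that survive BH at level \code{q} and
#' whose corrected p-value is below \code{pRetain} (the high-significance
#' retention, default 0.001).
#'
#' @param zmap a [VoxelZMap] from [glmGroupTest()].
#' @param q FDR level in (0, 1).
#' @param pRetain retention threshold on the corrected p-values.
#' @return The [VoxelZMap] with corrected p-values and the significance
#'   mask filled in.
#' @export
fdrThreshold <- function(zmap, q = 0.05, pRetain = 0.001) {
  stopifnot(q > 0, q < 1)
  m <- zmap@analysisMask@data > 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  p <- zmap@p@data[m]
  padj <- p.adjust(p, method = "BH")
  sig <- padj <= q & padj < pRetain
  d <- dim(zmap@p@data)
  pAdjArr <- array(1, d)
  pAdjArr[m] <- padj
  sigArr <- array(0, d)
  sigArr[m] <- sig + 0
  new("VoxelZMap", z = zmap@z,
      p = Volume(pAdjArr, zmap@p@spacing, zmap@p@origin),
      sigMask = Volume(sigArr, zmap@p@spacing, zmap@p@origin),
      analysisMask = zmap@analysisMask, flagged = zmap@flagged,
      params = modifyList(zmap@params, list(q = q, pRetain = pRetain)))
}

#' End-to-end voxel-based morphometry between two groups
#'
#' Takes per-subject tissue maps (e.g. visceral-fat indicators) with the
#' fields that map atlas space into each subject's space, warps every map
#' into atlas space, smooths, balances the group sizes by seeded subsampling
#' of the larger group, fits the voxel-wise GLM and applies FDR control.
#'
#' @param healthy,diseased lists of \code{list(map = BodyVolume, field =
#'   DisplacementField or NULL)}; NULL fields mean the map is already in
#'   atlas space.
#' @param analysisMask optional atlas-space mask (e.g. coverage x body
#'   mask); NULL uses all voxels.
#' @param fwhm smoothing FWHM in mm.
#' @param q,pRetain FDR settings, see [fdrThreshold()].
#' @param seed seed for the balancing subsample.
#' @return A [VoxelZMap].
#' @export
runVBM <- function(healthy, diseased, analysisMask = NULL, fwhm = NULL,
                   q = 0.05, pRetain = 0.001, seed = 1L) {
  if (length(healthy) < 2 || length(diseased) < 2)
    stop("need at least two subjects per group", call. = FALSE)
  toAtlas <- function(s) {
    v <- if (is.null(s$field)) s$map else warpVolume(s$map, s$field, "linear")
    if (is.null(fwhm)) fwhm <<- 2 * min(v@spacing)
    smoothVolume(v, fwhm)
  }
  hv <- lapply(healthy, toAtlas)
  dv <- lapply(diseased, toAtlas)
  set.seed(seed)
  if (length(hv) > length(dv))
    hv <- hv[sort(sample.int(length(hv), length(dv)))]
  else if (length(dv) > length(hv))
    dv <- dv[sort(sample.int(length(dv), length(hv)))]
  zm <- glmGroupTest(hv, dv, mask = analysisMask)
  zm <- fdrThreshold(zm, q = q, pRetain = pRetain)
  zm@params$fwhm <- fwhm
  zm@params$seed <- seed
  zm
}

#' Overlay figure of significant voxels
#'
#' Writes axial and coronal mid-slice PNGs of the anatomy with the
#' significant voxels of a z-map highlighted.  Optional reporting utility;
#' analysis results live in the [VoxelZMap] itself.
#'
#' @param zmap a [VoxelZMap].
#' @param anatomy background [BodyVolume].
#' @param file output PNG path.
#' @return The file path, invisibly.
#' @export
plotZMapOverlay <- function(zmap, anatomy, file) {
  d <- dim(anatomy@data)
  kz <- ceiling(d[3] / 2)
  ky <- ceiling(d[2] / 2)
  grDevices::png(file, width = 900, height = 450)
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  for (view in c("axial", "coronal")) {
    bg <- if (view == "axial") anatomy@data[, , kz] else anatomy@data[, ky, ]
    sg <- if (view == "axial") zmap@sigMask@data[, , kz] else
      zmap@sigMask@data[, ky, ]
    graphics::image(bg, col = grDevices::gray.colors(128), axes = FALSE,
                    main = view)
    if (any(sg > 0)) {
      ov <- ifelse(sg > 0, 1, NA)
      graphics::image(ov, col = grDevices::adjustcolor("red", 0.6),
                      add = TRUE)
    }
  }
  invisible(file)
}
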