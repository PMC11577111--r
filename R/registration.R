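# Pairwise registration: an affine stage (translation + rotation + scale +
# shear, optimised over a multi-resolution pyramid) followed by diffeomorphic
# B-spline free-form deformation.  The deformable transform is parameterised
# as a stationary velocity field on a control-point lattice; displacements
# are obtained by scaling-and-squaring, which keeps the transform invertible
# and topology-preserving.  The objective is
#     metric(F, M o phi) + lambda * bendingEnergy(velocity),
# optimised coarse-to-fine with gradient descent and a backtracking line
# search on the true objective, so accepted steps never increase it.

#' Registration configuration
#'
#' @param metric \code{"ncc"} (default; 1 - normalised cross-correlation),
#'   \code{"ssd"} (mean squared difference) or \code{"nmi"}
#'   (1 - normalised mutual information, 64 histogram bins).
#' @param lambda bending-energy weight (>= 0).
#' @param levels pyramid levels (factor-2 downsampling per level).
#' @param cpSpacing control-point spacing schedule in mm, one (decreasing)
#'   value per level, coarse to fine.
#' @param maxIter max optimizer iterations per level.
#' @param tol relative objective-change convergence tolerance.
#' @param squaringSteps scaling-and-squaring steps.
#' @param affineMaxIter max iterations of the affine optimiser per level.
#' @return List of class \code{"RegistrationConfig"}.
#' @export
registrationConfig <- function(metric = c("ncc", "ssd", "nmi"),
                               lambda = 1e-3, levels = 3L,
                               cpSpacing = c(32, 16, 8), maxIter = 100L,
                               tol = 1e-5, squaringSteps = 6L,
                               affineMaxIter = 60L) {
  metric <- match.arg(metric)
  stopifnot(lambda >= 0, levels >= 1, length(cpSpacing) == levels,
            !is.unsorted(rev(cpSpacing)))
  structure(list(metric = metric, lambda = lambda, levels = as.integer(levels),
                 cpSpacing = cpSpacing, maxIter = as.integer(maxIter),
                 tol = tol, squaringSteps = as.integer(squaringSteps),
                 affineMaxIter = as.integer(affineMaxIter)),
            class = "RegistrationConfig")
}

#' Image dissimilarity and its intensity gradient
#'
#' \code{ssd}: mean squared difference; \code{ncc}: 1 minus the (global)
#' normalised cross-correlation, invariant to affine intensity changes;
#' \code{nmi}: 1 minus the normalised mutual information
#' \code{(H(F) + H(W)) / H(F, W)} on a 64-bin joint histogram with linear
#' (hat-kernel) sample spreading.  ssd and ncc are 0 at a perfect match.
#' The gradient is taken with respect to the warped intensities.
#'
#' @param f fixed [BodyVolume] (or array).
#' @param w warped moving [BodyVolume] (or array) on the same grid.
#' @param metric \code{"ssd"}, \code{"ncc"} or \code{"nmi"}.
#' @param mask optional binary array restricting the evaluation.
#' @param bins histogram bins for nmi.
#' @return List with \code{value} (scalar) and \code{grad} (array, zero
#'   outside the mask).
#' @export
dissimilarity <- function(f, w, metric = c("ncc", "ssd", "nmi"), mask = NULL,
                          bins = 64L) {
  metric <- match.arg(metric)
  F_ <- if (is(f, "BodyVolume")) f@data else f
  W <- if (is(w, "BodyVolume")) w@data else w
  stopifnot(all(dim(F_) == dim(W)))
  m <- .asMaskArray(mask, dim(F_))
  if (!is.null(m) && !any(m)) stop("empty mask", call. = FALSE)
  idx <- if (is.null(m)) TRUE else m
  fv <- F_[idx]
  wv <- W[idx]
  n <- length(fv)
  grad <- array(0, dim(F_))
  if (metric == "ssd") {
    val <- mean((fv - wv)^2)
    g <- 2 * (wv - fv) / n
  } else if (metric == "ncc") {
    mf <- mean(fv)
    mw <- mean(wv)
    fc <- fv - mf
    wc <- wv - mw
    sf <- sqrt(mean(fc^2))
    sw <- sqrt(mean(wc^2))
    if (sf == 0 || sw == 0)
      stop("constant image inside mask: ncc undefined", call. = FALSE)
    rho <- mean(fc * wc) / (sf * sw)
    val <- 1 - rho
    g <- -(fc / (sf * sw) - rho * wc / sw^2) / n
  } else {
    hj <- .jointHistogram(fv, wv, bins)
    val <- 1 - hj$nmi
    g <- .nmiGradient(fv, wv, hj) # d(1 - NMI)/dW
  }
  if (is.null(m)) grad[] <- g else grad[m] <- g
  list(value = val, grad = grad)
}

# 64-bin joint histogram with linear (hat) spreading; returns probabilities,
# entropies, NMI and the bin geometry needed for the gradient.
.jointHistogram <- function(fv, wv, bins = 64L) {
  rf <- range(fv)
  rw <- range(wv)
  wf <- diff(rf) / (bins - 1)
  ww <- diff(rw) / (bins - 1)
  if (wf == 0 || ww == 0) stop("constant image: nmi undefined", call. = FALSE)
  xf <- (fv - rf[1]) / wf  # continuous bin coordinate in [0, bins-1]
  xw <- (wv - rw[1]) / ww
  i0 <- pmin(floor(xf), bins - 2)
  j0 <- pmin(floor(xw), bins - 2)
  af <- xf - i0
  aw <- xw - j0
  H <- matrix(0, bins, bins)
  add <- function(ii, jj, wt) {
    k <- ii + bins * jj + 1L
    tab <- tapply(wt, k, sum)
    H[as.integer(names(tab))] <<- H[as.integer(names(tab))] + tab
  }
  add(i0, j0, (1 - af) * (1 - aw))
  add(i0 + 1, j0, af * (1 - aw))
  add(i0, j0 + 1, (1 - af) * aw)
  add(i0 + 1, j0 + 1, af * aw)
  P <- H / length(fv)
  pf <- rowSums(P)
  pw <- colSums(P)
  eps <- .Machine$double.xmin
  Hf <- -sum(pf[pf > 0] * log(pf[pf > 0]))
  Hw <- -sum(pw[pw > 0] * log(pw[pw > 0]))
  Hj <- -sum(P[P > 0] * log(P[P > 0]))
  list(P = P, pf = pf, pw = pw, Hf = Hf, Hw = Hw, Hj = Hj,
       nmi = (Hf + Hw) / max(Hj, eps), bins = bins,
       rf = rf, rw = rw, wf = wf, ww = ww,
       i0 = i0, j0 = j0, af = af, aw = aw)
}

# gradient of 1 - NMI w.r.t. the warped intensities, via the chain rule
# through the hat-kernel joint histogram
.nmiGradient <- function(fv, wv, hj) {
  n <- length(wv)
  with(hj, {
    # d(1-NMI)/dP_ij = -[ dHf/dP + dHw/dP - NMI * dHj/dP ] / Hj
    lp <- function(x) ifelse(x > 0, log(x), 0)
    dHf <- -(lp(pf) + 1)[i0 + 1]        # row marginal term per sample bin i
    dHf1 <- -(lp(pf) + 1)[i0 + 2]
    dHw <- -(lp(pw) + 1)[j0 + 1]
    dHw1 <- -(lp(pw) + 1)[j0 + 2]
    dHj <- -(lp(P) + 1)
    # per-sample: dP_ij/dwv = d(weight)/dwv / n; weights depend on aw only
    # through the w-axis; daw/dwv = 1/ww
    g <- numeric(n)
    for (dj in 0:1) for (di in 0:1) {
      wgtF <- if (di == 0) (1 - af) else af
      dwgt <- (if (dj == 0) -1 else 1) * wgtF / ww / n
      kk <- cbind(i0 + di + 1, j0 + dj + 1)
      dHf_k <- if (di == 0) dHf else dHf1
      dHw_k <- if (dj == 0) dHw else dHw1
      dVal <- -(dHf_k + dHw_k - nmi * dHj[kk]) / max(Hj, .Machine$double.xmin)
      g <- g + dVal * dwgt
    }
    g
  })
}

#' Create a velocity lattice covering a grid
#'
#' @param gridDim integer(3) image dims.
#' @param spacing image voxel spacing (mm).
#' @param origin image origin (mm).
#' @param cpSpacing control-point spacing (mm, recycled to 3).
#' @return A [VelocityLattice] with zero coefficients.
#' @export
velocityLattice <- function(gridDim, spacing, origin = c(0, 0, 0),
                            cpSpacing = 16) {
  if (length(cpSpacing) == 1L) cpSpacing <- rep(cpSpacing, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  delta <- cpSpacing / spacing
  cd <- as.integer(floor((gridDim - 1) / delta) + 4)
  new("VelocityLattice", coef = array(0, c(cd, 3L)),
      cpSpacing = as.numeric(cpSpacing), gridDim = as.integer(gridDim),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Dense velocity field of a lattice
#'
#' Cubic B-spline interpolation of the lattice coefficients at every voxel
#' centre.
#'
#' @param lattice a [VelocityLattice].
#' @return A [DisplacementField] holding the velocity (mm).
#' @export
latticeVelocity <- function(lattice) {
  cd <- dim(lattice@coef)
  delta <- lattice@cpSpacing / lattice@spacing
  dense <- .C_bspline_eval(as.numeric(lattice@coef), cd, lattice@gridDim,
                           delta, c(0L, 0L, 0L), c(1, 1, 1))
  Field(array(dense, c(lattice@gridDim, 3L)), spacing = lattice@spacing,
        origin = lattice@origin)
}

#' Bending energy of a velocity lattice
#'
#' Mean over voxels of the squared second spatial derivatives of the dense
#' interpolated velocity (all components; mixed terms counted twice), the
#' standard thin-plate regulariser of free-form deformation.  Zero for any
#' affine (constant or linear) coefficient pattern.  Because the 3D basis is
#' a tensor product, the voxel sum factorises into per-axis Gram matrices of
#' the (derivative) B-spline bases, so the value is computed exactly without
#' materialising the dense derivative fields.
#'
#' @param lattice a [VelocityLattice].
#' @param gradient also return the gradient w.r.t. the coefficients.
#' @param units \code{"cp"} (default): derivatives taken with respect to the
#'   dimensionless control-point lattice coordinate, making the energy and a
#'   given weight \code{lambda} independent of image resolution and
#'   control-point spacing (the convention of the reference FFD
#'   implementations); \code{"mm"}: derivatives per physical mm.
#' @return \code{list(value, grad)} (grad NULL unless requested).
#' @export
bendingEnergy <- function(lattice, gradient = FALSE, units = c("cp", "mm")) {
  units <- match.arg(units)
  cd <- dim(lattice@coef)
  delta <- lattice@cpSpacing / lattice@spacing
  gd <- lattice@gridDim
  n <- prod(gd)
  # per-axis Gram matrices G[d][[ax]][m, m'] = sum_p B^(d)_m(p) B^(d)_m'(p)
  gram <- lapply(0:2, function(dv) lapply(1:3, function(ax) {
    nc <- cd[ax]
    G <- matrix(0, nc, nc)
    fac <- if (units == "mm") (1 / (delta[ax] * lattice@spacing[ax]))^dv
           else 1
    for (p in 0:(gd[ax] - 1)) {
      xc <- p / delta[ax]
      i <- floor(xc)
      w <- .bsplineWeights(xc - i, dv) * fac
      idx <- pmin(i + 1:4, nc)
      G[idx, idx] <- G[idx, idx] + outer(w, w)
    }
    G
  }))
  applyAxis <- function(arr, M, ax) {
    # multiply M along axis ax of a (c1, c2, c3, 3) array
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    a <- M %*% matrix(a, nrow = d[1])
    aperm(array(a, d), order(perm))
  }
  combos <- list(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
                 c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  wts <- c(1, 1, 1, 2, 2, 2)
  val <- 0
  grad <- if (gradient) array(0, cd) else NULL
  for (ci in seq_along(combos)) {
    dd <- combos[[ci]]
    t_ <- lattice@coef
    for (ax in 1:3) t_ <- applyAxis(t_, gram[[dd[ax] + 1]][[ax]], ax)
    val <- val + wts[ci] * sum(lattice@coef * t_) / n
    if (gradient) grad <- grad + 2 * wts[ci] * t_ / n
  }
  list(value = val, grad = grad)
}

# cubic B-spline basis weights (and derivatives) at local offset t in [0, 1)
.bsplineWeights <- function(t, deriv = 0L) {
  if (deriv == 0L)
    c((1 - t)^3, 3 * t^3 - 6 * t^2 + 4, -3 * t^3 + 3 * t^2 + 3 * t + 1,
      t^3) / 6
  else if (deriv == 1L)
    c(-(1 - t)^2 / 2, (9 * t^2 - 12 * t) / 6, (-9 * t^2 + 6 * t + 3) / 6,
      t^2 / 2)
  else c(1 - t, 3 * t - 2, 1 - 3 * t, t)
}

# central-difference spatial gradient (mm^-1) of a volume, per axis;
# one-sided at the boundary slices
.imageGradient <- function(arr, spacing) {
  d <- dim(arr)
  out <- vector("list", 3)
  for (ax in 1:3) {
    idx1 <- idx2 <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx1[[ax]] <- pmin(idx1[[ax]] + 1L, d[ax])
    idx2[[ax]] <- pmax(idx2[[ax]] - 1L, 1L)
    g <- arr[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE] -
         arr[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]
    den <- array(2 * spacing[ax], d)
    bnd <- rep(FALSE, d[ax])
    bnd[c(1L, d[ax])] <- TRUE
    if (ax == 1) den[bnd, , ] <- spacing[ax]
    else if (ax == 2) den[, bnd, ] <- spacing[ax]
    else den[, , bnd] <- spacing[ax]
    out[[ax]] <- g / den
  }
  out
}

# ---- affine stage -----------------------------------------------------------

# 12-dof parameter vector -> AffineTransform3D about a physical centre:
# y = R(rx,ry,rz) Sh(h1,h2,h3) diag(exp(s)) (x - c) + c + t
.paramsToAffine <- function(p, centre) {
  t <- p[1:3]
  r <- p[4:6]
  s <- exp(p[7:9])
  h <- p[10:12]
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Sh <- diag(3)
  Sh[1, 2] <- h[1]; Sh[1, 3] <- h[2]; Sh[2, 3] <- h[3]
  L <- Rz %*% Ry %*% Rx %*% Sh %*% diag(s)
  Affine(L, as.numeric(centre - L %*% centre) + t)
}

# derivatives of the linear part L = Rz Ry Rx Sh diag(exp(s)) w.r.t. the
# nine matrix parameters (rx, ry, rz, s1..s3, h1..h3), in p[4:12] order
.affineParamDerivs <- function(p) {
  r <- p[4:6]
  s <- exp(p[7:9])
  h <- p[10:12]
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  dRx <- matrix(c(0, 0, 0, 0, -sx, cx, 0, -cx, -sx), 3)
  dRy <- matrix(c(-sy, 0, -cy, 0, 0, 0, cy, 0, -sy), 3)
  dRz <- matrix(c(-sz, cz, 0, -cz, -sz, 0, 0, 0, 0), 3)
  Sh <- diag(3)
  Sh[1, 2] <- h[1]; Sh[1, 3] <- h[2]; Sh[2, 3] <- h[3]
  S <- diag(s)
  ShS <- Sh %*% S
  out <- vector("list", 9)
  out[[1]] <- Rz %*% Ry %*% dRx %*% ShS
  out[[2]] <- Rz %*% dRy %*% Rx %*% ShS
  out[[3]] <- dRz %*% Ry %*% Rx %*% ShS
  RR <- Rz %*% Ry %*% Rx
  for (j in 1:3) {
    dS <- matrix(0, 3, 3)
    dS[j, j] <- s[j]              # d exp(s_j) / d s_j
    out[[3 + j]] <- RR %*% Sh %*% dS
  }
  shIdx <- list(c(1, 2), c(1, 3), c(2, 3))
  for (j in 1:3) {
    dSh <- matrix(0, 3, 3)
    dSh[shIdx[[j]][1], shIdx[[j]][2]] <- 1
    out[[6 + j]] <- RR %*% dSh %*% S
  }
  out
}

#' Affine registration
#'
#' Optimises a 12-dof transform (translation, rotation, log-scale, shear)
#' over a factor-2 multi-resolution pyramid by quasi-Newton descent on the
#' chosen metric.  The optimised correction is composed with \code{init}
#' (applied first), and the better of \{init, composed result\} under the
#' full-resolution metric is returned, so the final metric never exceeds
#' the initial one.
#'
#' @param fixed,moving pre-processed [BodyVolume]s.
#' @param init initial [AffineTransform3D] (e.g. from [comAlign()]).
#' @param config a [registrationConfig()].
#' @param mask optional fixed-space analysis mask (array or [BodyVolume]).
#' @return An [AffineTransform3D]; attribute \code{metric} holds the final
#'   dissimilarity.
#' @export
registerAffine <- function(fixed, moving, init = identityAffine(),
                           config = registrationConfig(), mask = NULL) {
  pyr <- .pyramid(fixed, config$levels)
  pyrM <- .pyramid(moving, config$levels)
  maskArr <- .asMaskArray(mask, dim(fixed@data))
  centre <- fixed@origin + (dim(fixed@data) - 1) * fixed@spacing / 2
  p <- rep(0, 12)
  for (lev in seq_along(pyr)) {
    fl <- pyr[[lev]]
    moving <- pyrM[[lev]]  # anti-aliased moving image at this level
    gMov <- .imageGradient(moving@data, moving@spacing)
    dl <- dim(fl@data)
    ml <- if (is.null(maskArr)) NULL else {
      mm <- downsampleVolume(Volume(maskArr + 0, fixed@spacing, fixed@origin),
                             2^(config$levels - lev))
      mm@data > 0.5
    }
    crd <- gridCoords(dl, fl@spacing, fl@origin)
    cache <- new.env(parent = emptyenv())
    evalAt <- function(pp) {
      key <- paste(format(pp, digits = 17), collapse = ",")
      if (identical(cache$key, key)) return(cache$val)
      P <- .paramsToAffine(pp, centre)
      aff <- composeAffine(init, P)
      fld <- affineToField(aff, dl, fl@spacing, fl@origin)
      w <- warpVolume(moving, fld)
      ds <- tryCatch(dissimilarity(fl, w, config$metric, mask = ml),
                     error = function(e) NULL)
      val <- list(ds = ds, fld = fld, pp = pp)
      cache$key <- key
      cache$val <- val
      val
    }
    objfun <- function(pp) {
      e <- evalAt(pp)
      if (is.null(e$ds)) 1e6 else e$ds$value
    }
    gradfun <- function(pp) {
      e <- evalAt(pp)
      if (is.null(e$ds)) return(rep(0, 12))
      g0 <- e$ds$grad
      # moving-image gradient sampled at the mapped points
      gW <- lapply(gMov, function(ga)
        volData(warpVolume(Volume(ga, moving@spacing, moving@origin),
                           e$fld)))
      gv <- lapply(gW, function(ga) g0 * ga)     # force components
      Li <- init@linear
      # project through the init linear part
      lg1 <- Li[1, 1] * gv[[1]] + Li[2, 1] * gv[[2]] + Li[3, 1] * gv[[3]]
      lg2 <- Li[1, 2] * gv[[1]] + Li[2, 2] * gv[[2]] + Li[3, 2] * gv[[3]]
      lg3 <- Li[1, 3] * gv[[1]] + Li[2, 3] * gv[[2]] + Li[3, 3] * gv[[3]]
      sumg <- c(sum(lg1), sum(lg2), sum(lg3))
      xc <- crd$x - centre[1]
      yc <- crd$y - centre[2]
      zc <- crd$z - centre[3]
      M3 <- rbind(c(sum(lg1 * xc), sum(lg1 * yc), sum(lg1 * zc)),
                  c(sum(lg2 * xc), sum(lg2 * yc), sum(lg2 * zc)),
                  c(sum(lg3 * xc), sum(lg3 * yc), sum(lg3 * zc)))
      dL <- .affineParamDerivs(pp)
      c(sumg, vapply(dL, function(D) sum(D * M3), numeric(1)))
    }
    opt <- optim(p, objfun, gr = gradfun, method = "BFGS",
                 control = list(maxit = config$affineMaxIter, reltol = 1e-10,
                                parscale = c(rep(2, 3), rep(0.02, 3),
                                             rep(0.02, 3), rep(0.02, 3))))
    p <- opt$par
  }
  final <- composeAffine(init, .paramsToAffine(p, centre))
  # guard: never return worse than init under the full-resolution metric
  evalAff <- function(aff) {
    fld <- affineToField(aff, dim(fixed@data), fixed@spacing, fixed@origin)
    dissimilarity(fixed, warpVolume(moving, fld), config$metric,
                  mask = maskArr)$value
  }
  mFinal <- evalAff(final)
  mInit <- evalAff(init)
  if (mFinal > mInit) {
    warning("affine optimisation did not improve on the initialisation; returning best iterate")
    attr(init, "metric") <- mInit
    return(init)
  }
  attr(final, "metric") <- mFinal
  final
}

.pyramid <- function(vol, levels) {
  out <- vector("list", levels)
  out[[levels]] <- vol
  if (levels > 1)
    for (lev in (levels - 1):1)
      out[[lev]] <- downsampleVolume(out[[lev + 1]], 2L)
  out
}

# ---- deformable stage -------------------------------------------------------

#' Diffeomorphic B-spline FFD registration
#'
#' Per pyramid level (coarse to fine) optimises the coefficients of a
#' stationary velocity lattice by gradient descent with backtracking line
#' search on \code{metric + lambda * bendingEnergy}.  The displacement is
#' the scaling-and-squaring flow of the interpolated velocity; each level's
#' result initialises the next finer level; the affine (or other) init field
#' is composed in.  Velocities are capped so the scaled integration step
#' stays below 0.4 voxel, a sufficient condition against folding.
#'
#' @param fixed,moving pre-processed [BodyVolume]s.
#' @param initField initial [DisplacementField] on the fixed grid (e.g. the
#'   rasterised affine), or NULL for identity.
#' @param config a [registrationConfig()].
#' @param mask optional fixed-space analysis mask.
#' @param verbose print per-level objective values.
#' @return List: \code{field} (total [DisplacementField]), \code{lattices}
#'   (per level), \code{objective} (trace per level), \code{foldingRatio}.
#' @export
registerFFD <- function(fixed, moving, initField = NULL,
                        config = registrationConfig(), mask = NULL,
                        verbose = FALSE) {
  d0 <- dim(fixed@data)
  if (is.null(initField))
    initField <- zeroField(d0, fixed@spacing, fixed@origin)
  stopifnot(all(dims(initField) == d0))
  pyr <- .pyramid(fixed, config$levels)
  pyrM <- .pyramid(moving, config$levels)
  maskArr <- .asMaskArray(mask, d0)
  lattices <- vector("list", config$levels)
  traces <- vector("list", config$levels)
  init <- initField
  for (lev in seq_along(pyr)) {
    fl <- pyr[[lev]]
    dl <- dim(fl@data)
    initL <- if (all(dims(init) == dl)) init else
      upsampleField(init, dl, fl@spacing, fl@origin)
    ml <- if (is.null(maskArr)) NULL else {
      mm <- downsampleVolume(Volume(maskArr + 0, fixed@spacing, fixed@origin),
                             2^(config$levels - lev))
      mm@data > 0.5
    }
    # anti-aliased moving at this level, brought to the level's init
    w0 <- warpVolume(pyrM[[lev]], initL)
    lat <- velocityLattice(dl, fl@spacing, fl@origin,
                           config$cpSpacing[lev])
    res <- .optimizeLevel(fl, w0, lat, config, ml, verbose)
    lattices[[lev]] <- res$lattice
    traces[[lev]] <- res$trace
    disp <- integrateVelocity(latticeVelocity(res$lattice),
                              config$squaringSteps)
    init <- composeFields(initL, disp)
  }
  total <- init
  list(field = total, lattices = lattices, objective = traces,
       foldingRatio = foldingRatio(total))
}

# gradient descent with backtracking line search for one pyramid level
.optimizeLevel <- function(fl, w0, lat, config, mask, verbose) {
  capMM <- 0.4 * min(fl@spacing) * 2^config$squaringSteps
  cd <- dim(lat@coef)
  delta <- lat@cpSpacing / lat@spacing
  gd <- lat@gridDim
  objective <- function(coefs) {
    lat@coef <- coefs
    u <- integrateVelocity(latticeVelocity(lat), config$squaringSteps)
    w <- warpVolume(w0, u)
    ds <- dissimilarity(fl, w, config$metric, mask = mask)
    be <- if (config$lambda > 0) bendingEnergy(lat)$value else 0
    list(value = ds$value + config$lambda * be, ds = ds, u = u, w = w)
  }
  coefs <- lat@coef
  cur <- objective(coefs)
  trace <- cur$value
  step <- NULL
  gw <- .imageGradient(w0@data, fl@spacing)
  for (it in seq_len(config$maxIter)) {
    # force field: dD/dW(x) * grad(M o init)(x + u(x))
    gx <- volData(warpVolume(Volume(gw[[1]], fl@spacing, fl@origin), cur$u))
    gy <- volData(warpVolume(Volume(gw[[2]], fl@spacing, fl@origin), cur$u))
    gz <- volData(warpVolume(Volume(gw[[3]], fl@spacing, fl@origin), cur$u))
    force <- array(c(cur$ds$grad * gx, cur$ds$grad * gy, cur$ds$grad * gz),
                   c(gd, 3L))
    g <- array(.C_bspline_project(as.numeric(force), cd, gd, delta,
                                  c(0L, 0L, 0L), c(1, 1, 1)), cd)
    if (config$lambda > 0)
      g <- g + config$lambda * bendingEnergy(lat, gradient = TRUE)$grad
    if (any(!is.finite(g))) {
      warning("non-finite gradient; aborting level with best iterate")
      break
    }
    gmax <- max(abs(g))
    if (gmax == 0) break
    if (is.null(step)) step <- 0.5 * min(fl@spacing) / gmax
    accepted <- FALSE
    for (try_ in 1:10) {
      cand <- array(pmin(pmax(coefs - step * g, -capMM), capMM), cd)
      nxt <- objective(cand)
      if (nxt$value < cur$value) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    relchg <- (cur$value - nxt$value) / max(abs(cur$value), 1e-12)
    coefs <- cand
    cur <- nxt
    lat@coef <- coefs
    trace <- c(trace, cur$value)
    step <- step * 2   # try growing again next iteration
    if (verbose && it %% 10 == 0)
      message(sprintf("  iter %d: objective %.6g", it, cur$value))
    if (relchg < config$tol) break
  }
  lat@coef <- coefs
  list(lattice = lat, trace = trace)
}

#' Full pairwise registration chain
#'
#' Pre-processing, centre-of-mass (or ICP) initialisation, affine stage and
#' deformable FFD stage, each stage initialised by the previous one.
#' Deterministic given the config and inputs.
#'
#' @param fixed,moving raw [BodyVolume]s.
#' @param config a [registrationConfig()].
#' @param initMode \code{"com"} or \code{"icp"}.
#' @param verbose print progress.
#' @return List of class \code{"TransformChain"}: \code{comInit}
#'   ([AffineTransform3D]), \code{affine} ([AffineTransform3D]),
#'   \code{affineField}, \code{ffd} (the [registerFFD()] result),
#'   \code{field} (total [DisplacementField]), \code{preprocess} (fixed and
#'   moving pre-processing reports), \code{foldingRatio}.
#' @export
registerPair <- function(fixed, moving, config = registrationConfig(),
                         initMode = "com", verbose = FALSE) {
  pf <- preprocessVolume(fixed)
  pm <- preprocessVolume(moving)
  com <- comAlign(pm$mask, pf$mask, mode = initMode)
  aff <- registerAffine(pf$volume, pm$volume, init = com, config = config,
                        mask = pf$mask@data)
  d0 <- dim(fixed@data)
  affField <- affineToField(aff, d0, fixed@spacing, fixed@origin)
  ffd <- registerFFD(pf$volume, pm$volume, initField = affField,
                     config = config, mask = pf$mask@data, verbose = verbose)
  if (verbose)
    message(sprintf("folding ratio of total field: %.5f", ffd$foldingRatio))
  structure(list(comInit = com, affine = aff, affineField = affField,
                 ffd = ffd, field = ffd$field,
                 preprocess = list(fixed = pf$report, moving = pm$report),
                 foldingRatio = ffd$foldingRatio),
            class = "TransformChain")
}
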