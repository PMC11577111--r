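# Registration: dissimilarity metrics, bending energy, affine and FFD stages.

test_that("dissimilarity metrics honour their invariance contracts", {
  d <- c(6L, 6L, 6L)
  f <- blobVolume(d, seed = 110)
  ds <- dissimilarity(f, f, "ssd")
  expect_equal(ds$value, 0)
  expect_equal(max(abs(ds$grad)), 0)
  expect_equal(dissimilarity(f, f, "ncc")$value, 0, tolerance = 1e-12)

  # ncc is invariant to positive affine intensity changes, ssd is not
  m <- Volume(2.5 * volData(f) + 0.3, volSpacing(f))
  expect_equal(dissimilarity(f, m, "ncc")$value, 0, tolerance = 1e-12)
  expect_gt(dissimilarity(f, m, "ssd")$value, 0)

  # analytic intensity gradients agree with finite differences
  set.seed(111)
  w <- Volume(volData(f) + array(rnorm(prod(d), 0, 0.1), d))
  for (metric in c("ssd", "ncc")) {
    ds <- dissimilarity(f, w, metric)
    eps <- 1e-6
    for (vx in c(1, 50, 111)) {
      w2 <- w
      w2@data[vx] <- w2@data[vx] + eps
      num <- (dissimilarity(f, w2, metric)$value - ds$value) / eps
      expect_equal(ds$grad[vx], num, tolerance = 1e-4)
    }
  }
  expect_error(dissimilarity(f, w, "ncc", mask = array(FALSE, d)), "empty")
})

test_that("nmi matches a hand-rolled joint-histogram oracle", {
  d <- c(4L, 4L, 4L)
  set.seed(112)
  f <- array(runif(prod(d)), d)
  w <- array(runif(prod(d)), d)
  got <- dissimilarity(Volume(f), Volume(w), "nmi", bins = 8L)$value
  # oracle: direct double-loop joint histogram with the same linear
  # (hat-kernel) bin spreading, entropies from scratch
  bins <- 8L
  hx <- (f - min(f)) / (max(f) - min(f)) * (bins - 1)
  hy <- (w - min(w)) / (max(w) - min(w)) * (bins - 1)
  H <- matrix(0, bins, bins)
  for (i in seq_along(hx)) {
    i0 <- min(floor(hx[i]), bins - 2); a <- hx[i] - i0
    j0 <- min(floor(hy[i]), bins - 2); b <- hy[i] - j0
    H[i0 + 1, j0 + 1] <- H[i0 + 1, j0 + 1] + (1 - a) * (1 - b)
    H[i0 + 2, j0 + 1] <- H[i0 + 2, j0 + 1] + a * (1 - b)
    H[i0 + 1, j0 + 2] <- H[i0 + 1, j0 + 2] + (1 - a) * b
    H[i0 + 2, j0 + 2] <- H[i0 + 2, j0 + 2] + a * b
  }
  P <- H / sum(H)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  nmi <- (ent(rowSums(P)) + ent(colSums(P))) / ent(as.vector(P))
  expect_equal(got, 1 - nmi, tolerance = 1e-10)
})

test_that("bending energy vanishes on affine lattices and matches the
           dense finite-difference oracle", {
  lat <- velocityLattice(c(12L, 10L, 14L), spacing = 2, cpSpacing = 6)
  expect_equal(bendingEnergy(lat)$value, 0)

  # linear-in-position coefficients lie in the kernel of the penalty
  cd <- dim(lat@coef)
  for (m in seq_len(cd[1])) lat@coef[m, , , 1] <- 0.3 * m
  for (m in seq_len(cd[2])) lat@coef[, m, , 2] <- -0.1 * m + 2
  expect_lt(abs(bendingEnergy(lat)$value), 1e-12)
  expect_lt(abs(bendingEnergy(lat, units = "mm")$value), 1e-12)

  # random coefficients against central differences of the dense field
  set.seed(113)
  lat@coef <- array(rnorm(prod(cd)), cd)
  vel <- latticeVelocity(lat)
  u <- vel@data
  d <- dims(vel)
  sp <- volSpacing(vel)
  combos <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  wts <- c(1, 1, 1, 2, 2, 2)
  shift <- function(a, ax, s) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- pmin(pmax(idx[[ax]] + s, 1L), d[ax])
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  oracle <- 0
  inner <- interiorIndex(d, 2L)
  for (ci in seq_along(combos)) {
    ab <- combos[[ci]]
    for (c_ in 1:3) {
      uc <- u[, , , c_]
      der <- if (ab[1] == ab[2]) {
        (shift(uc, ab[1], 1L) - 2 * uc + shift(uc, ab[1], -1L)) / sp[ab[1]]^2
      } else {
        (shift(shift(uc, ab[1], 1L), ab[2], 1L) -
           shift(shift(uc, ab[1], 1L), ab[2], -1L) -
           shift(shift(uc, ab[1], -1L), ab[2], 1L) +
           shift(shift(uc, ab[1], -1L), ab[2], -1L)) /
          (4 * sp[ab[1]] * sp[ab[2]])
      }
      oracle <- oracle + wts[ci] * sum(der[inner]^2)
    }
  }
  oracle <- oracle / sum(inner)
  got <- bendingEnergy(lat, units = "mm")$value
  expect_equal(got, oracle, tolerance = 0.15)  # discretisation tolerance
})

test_that("registering a volume to itself stays near the identity", {
  spec <- smallSpec(seed = 120)
  tpl <- makeTemplate(spec)
  pp <- preprocessVolume(tpl$volume)
  cfg <- registrationConfig(levels = 2L, cpSpacing = c(32, 16),
                            maxIter = 20L, affineMaxIter = 20L)
  aff <- registerAffine(pp$volume, pp$volume, config = cfg,
                        mask = volData(pp$mask))
  expect_lt(sqrt(sum(aff@translation^2)), 0.5 * min(spec$spacing))
  expect_lt(max(abs(aff@linear - diag(3))), 1e-2)

  ffd <- registerFFD(pp$volume, pp$volume, config = cfg,
                     mask = volData(pp$mask))
  mag <- fieldMagnitude(ffd$field)
  expect_lt(mean(mag), 0.1 * min(spec$spacing))
  expect_equal(ffd$foldingRatio, 0)
})

test_that("a planted affine is recovered within tight tolerances", {
  spec <- smallSpec(noiseSd = 0.02, seed = 121)
  tpl <- makeTemplate(spec)
  ctr <- (spec$gridDim - 1) * spec$spacing / 2
  th <- 4 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  L <- Rz %*% (diag(3) * 1.06)
  planted <- Affine(L, as.numeric(ctr - L %*% ctr) + c(5, -3, 2))
  mov <- warpVolume(tpl$volume, affineToField(planted, spec$gridDim,
                                              spec$spacing))
  pf <- preprocessVolume(tpl$volume)
  pm <- preprocessVolume(mov)
  com <- comAlign(pm$mask, pf$mask)
  rec <- registerAffine(pf$volume, pm$volume, init = com,
                        mask = volData(pf$mask))
  tgt <- invertAffine(planted)
  pr <- affineParameters(rec)
  pt_ <- affineParameters(tgt)
  expect_lt(abs(pr$angleDeg - pt_$angleDeg), 1)
  expect_lt(max(abs(pr$scales - pt_$scales)), 0.02)
  expect_lt(sqrt(sum((rec@translation - tgt@translation)^2)), 0.75 * 6)
  expect_lte(attr(rec, "metric"),
             dissimilarity(pf$volume,
                           warpVolume(pm$volume,
                                      affineToField(com, spec$gridDim,
                                                    spec$spacing)),
                           "ncc", mask = volData(pf$mask) > 0)$value + 1e-12)
})

test_that("the FFD objective never increases across accepted steps and a
           huge penalty drives the field to identity", {
  spec <- smallSpec(seed = 122)
  tpl <- makeTemplate(spec)
  s <- sampleSubject(tpl, spec, deform = list(amplitude = 5), seed = 3)
  pf <- preprocessVolume(tpl$volume)
  pm <- preprocessVolume(s$volume)
  cfg <- registrationConfig(levels = 2L, cpSpacing = c(24, 12),
                            maxIter = 15L)
  res <- registerFFD(pf$volume, pm$volume, config = cfg,
                     mask = volData(pf$mask))
  for (tr in res$objective)
    expect_true(all(diff(tr) <= 1e-12))

  rigid <- registrationConfig(levels = 2L, cpSpacing = c(24, 12),
                              maxIter = 15L, lambda = 1e6)
  res2 <- registerFFD(pf$volume, pm$volume, config = rigid,
                      mask = volData(pf$mask))
  expect_lt(maxDisplacement(res2$field), 0.35 * min(spec$spacing))
})

test_that("Dice improves monotonically across stages on a phantom suite", {
  spec <- smallSpec(seed = 123)
  tpl <- makeTemplate(spec)
  cfg <- registrationConfig(levels = 2L, cpSpacing = c(24, 12),
                            maxIter = 25L, affineMaxIter = 30L)
  pre <- aff <- def <- numeric(0)
  for (sd_ in 1:3) {
    s <- sampleSubject(tpl, spec, deform = list(amplitude = 5), seed = sd_)
    ch <- registerPair(tpl$volume, s$volume, config = cfg)
    pre <- c(pre, mean(dicePerLabel(tpl$labels, s$labels, 3:7)))
    wA <- warpVolume(s$labels, ch$affineField, "nearest")
    aff <- c(aff, mean(dicePerLabel(tpl$labels, wA, 3:7)))
    wD <- warpVolume(s$labels, ch$field, "nearest")
    def <- c(def, mean(dicePerLabel(tpl$labels, wD, 3:7)))
    expect_lt(ch$foldingRatio, 0.05)
  }
  expect_gt(mean(aff), mean(pre))
  expect_gte(mean(def), mean(aff))
})

test_that("registration is deterministic for identical inputs", {
  spec <- smallSpec(seed = 124)
  tpl <- makeTemplate(spec)
  s <- sampleSubject(tpl, spec, deform = list(amplitude = 4), seed = 9)
  cfg <- registrationConfig(levels = 2L, cpSpacing = c(24, 12),
                            maxIter = 10L, affineMaxIter = 15L)
  ch1 <- registerPair(tpl$volume, s$volume, config = cfg)
  ch2 <- registerPair(tpl$volume, s$volume, config = cfg)
  expect_identical(ch1$field@data, ch2$field@data)
})
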