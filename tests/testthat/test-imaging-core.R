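# Transform algebra: warping, composition, inversion, velocity integration,
# Jacobians, resampling.

test_that("warping respects identity, constants and exact voxel shifts", {
  d <- c(8L, 8L, 8L)
  v <- Volume(array(as.numeric(1:512), d), spacing = 2)
  expect_identical(volData(warpVolume(v, zeroField(d, 2))), volData(v))

  cst <- Volume(array(7, d), spacing = 2)
  f <- smoothField(d, spacing = 2, amplitude = 1.5, seed = 2)
  w <- warpVolume(cst, f)
  inner <- interiorIndex(d)
  expect_true(all(abs(volData(w)[inner] - 7) < 1e-12))

  # ramp shifted by exactly one voxel matches the index-shift oracle
  ramp <- Volume(array(rep(1:8, times = 64), d), spacing = 2)
  shift <- Field(array(rep(c(2, 0, 0), each = 512), c(d, 3)), spacing = 2)
  ws <- volData(warpVolume(ramp, shift))
  oracle <- volData(ramp)[c(2:8, 8), , ]  # out-of-range voxel not compared
  expect_equal(ws[1:7, , ], oracle[1:7, , ], tolerance = 1e-12)
})

test_that("warp errors on grid mismatch between field and volume classes", {
  v <- Volume(array(0, c(4, 4, 4)))
  expect_error(warpVolume(v, "not a field"))
})

test_that("composition has the zero field as identity and adds translations", {
  d <- c(12L, 10L, 8L)
  f <- smoothField(d, amplitude = 1, seed = 3)
  z <- zeroField(d)
  expect_equal(composeFields(f, z)@data, f@data, tolerance = 1e-9)
  expect_equal(composeFields(z, f)@data, f@data, tolerance = 1e-12)

  t1 <- Field(array(rep(c(1.5, -0.5, 2), each = prod(d)), c(d, 3)))
  t2 <- Field(array(rep(c(0.25, 1, -1), each = prod(d)), c(d, 3)))
  comp <- composeFields(t1, t2)
  expect_equal(comp@data[, , , 1], array(1.75, d), tolerance = 1e-12)
  expect_equal(comp@data[, , , 2], array(0.5, d), tolerance = 1e-12)
  expect_equal(comp@data[, , , 3], array(1, d), tolerance = 1e-12)
})

test_that("composition agrees with two-step warping on smooth fields", {
  d <- c(16L, 16L, 16L)
  f1 <- smoothField(d, amplitude = 1.2, seed = 4)
  f2 <- smoothField(d, amplitude = 1.2, seed = 5)
  v <- blobVolume(d, seed = 6)
  oneStep <- warpVolume(v, composeFields(f1, f2))
  twoStep <- warpVolume(warpVolume(v, f1), f2)
  inner <- interiorIndex(d, 4L)  # keep displaced samples inside the domain
  expect_lt(max(abs(volData(oneStep)[inner] - volData(twoStep)[inner])), 0.05)
  # on a linear ramp (interpolated exactly) the two routes agree to
  # machine precision, so the 0.05 above is pure double-interpolation error
  r <- Volume(array(rep(seq_len(d[1]), times = prod(d[2:3])), d))
  oneR <- warpVolume(r, composeFields(f1, f2))
  twoR <- warpVolume(warpVolume(r, f1), f2)
  expect_lt(max(abs(volData(oneR)[inner] - volData(twoR)[inner])), 1e-12)
})

test_that("composition is associative to interpolation tolerance", {
  d <- c(16L, 16L, 16L)
  f1 <- smoothField(d, amplitude = 0.8, seed = 7)
  f2 <- smoothField(d, amplitude = 0.8, seed = 8)
  f3 <- smoothField(d, amplitude = 0.8, seed = 9)
  left <- composeFields(composeFields(f1, f2), f3)
  right <- composeFields(f1, composeFields(f2, f3))
  inner <- interiorIndex(d, 4L)
  expect_lt(max(abs((left@data - right@data)[array(inner, c(d, 3))])), 0.05)
})

test_that("inversion: identity, exact translations, composition residual", {
  d <- c(16L, 16L, 16L)
  z <- invertField(zeroField(d))
  expect_equal(max(abs(z@data)), 0)

  tf <- Field(array(rep(c(1.2, -0.7, 0.4), each = prod(d)), c(d, 3)))
  ti <- invertField(tf, tol = 1e-6, maxIter = 200)
  expect_equal(ti@data[, , , 1], array(-1.2, d), tolerance = 1e-5)
  expect_equal(ti@data[, , , 2], array(0.7, d), tolerance = 1e-5)

  f <- smoothField(d, amplitude = 1.5, seed = 10)
  fi <- invertField(f, tol = 1e-4, maxIter = 200)
  resid <- composeFields(f, fi)  # phi o phi^-1 - id
  mag <- fieldMagnitude(resid)
  inner <- interiorIndex(d, 3L)
  expect_lt(max(mag[inner]), 0.1)  # < 0.1 voxel (spacing 1)
})

test_that("inversion signals non-convergence instead of returning silently", {
  d <- c(8L, 8L, 8L)
  f <- smoothField(d, amplitude = 2, seed = 11)
  expect_error(invertField(f, tol = 1e-12, maxIter = 1L),
               "did not converge")
  expect_warning(invertField(f, tol = 1e-12, maxIter = 1L, onFail = "warn"),
                 "did not converge")
})

test_that("velocity integration: identity, constant flow, linear flow", {
  d <- c(16L, 16L, 16L)
  expect_equal(max(abs(integrateVelocity(zeroField(d))@data)), 0)

  v0 <- c(2.5, -1, 0.5)
  cv <- Field(array(rep(v0, each = prod(d)), c(d, 3)))
  iv <- integrateVelocity(cv, 6L)
  inner <- interiorIndex(d, 4L)
  for (c_ in 1:3)
    expect_lt(max(abs(iv@data[, , , c_][inner] - v0[c_])), 1e-9)

  # v(x) = B x integrates to (expm(B) - I) x
  B <- matrix(c(0.02, 0.01, 0, -0.01, 0.03, 0.005, 0, 0.01, -0.02), 3)
  ctr <- (d - 1) / 2
  g <- expand.grid(x = seq_len(d[1]) - 1 - ctr[1],
                   y = seq_len(d[2]) - 1 - ctr[2],
                   z = seq_len(d[3]) - 1 - ctr[3])
  X <- as.matrix(g)
  vel <- Field(array(X %*% t(B), c(d, 3)))
  disp <- integrateVelocity(vel, 8L)
  E <- as.matrix(Matrix::expm(B)) - diag(3)
  expected <- array(X %*% t(E), c(d, 3))
  inner4 <- array(interiorIndex(d, 3L), c(d, 1))[, , , rep(1, 3)]
  err <- abs(disp@data - expected)
  normx <- sqrt(rowSums(X^2))
  tol <- 1e-3 * max(normx)
  inner <- interiorIndex(d, 3L)
  for (c_ in 1:3)
    expect_lt(max(err[, , , c_][inner]), tol)
})

test_that("integrating -v approximates the inverse of integrating v", {
  d <- c(16L, 16L, 16L)
  set.seed(12)
  v <- randomVelocity(d, 1, amplitude = 1.5, corrLength = 6)
  fwd <- integrateVelocity(v, 6L)
  bwd <- integrateVelocity(Field(-v@data), 6L)
  inv <- invertField(fwd, tol = 1e-4, maxIter = 200)
  inner <- interiorIndex(d, 3L)
  diff <- fieldMagnitude(Field(bwd@data - inv@data))
  expect_lt(max(diff[inner]), 0.1)
})

test_that("integration of bounded velocities is folding-free", {
  d <- c(14L, 14L, 14L)
  for (seed in 1:5) {
    set.seed(seed)
    v <- randomVelocity(d, 1, amplitude = 0.4 * 2^6, corrLength = 5)
    expect_equal(foldingRatio(integrateVelocity(v, 6L)), 0)
  }
})

test_that("Jacobian determinants match closed forms and the oracle", {
  d <- c(10L, 10L, 10L)
  jd <- jacobianDeterminant(zeroField(d, spacing = 2))
  expect_equal(volData(jd), array(1, d), tolerance = 1e-14)

  A <- matrix(c(0.1, 0.02, 0, 0.01, -0.05, 0.03, 0, 0.01, 0.08), 3)
  g <- expand.grid(x = (seq_len(d[1]) - 1) * 2, y = (seq_len(d[2]) - 1) * 2,
                   z = (seq_len(d[3]) - 1) * 2)
  lin <- Field(array(as.matrix(g) %*% t(A), c(d, 3)), spacing = 2)
  jl <- jacobianDeterminant(lin)
  inner <- interiorIndex(d, 1L)
  expect_equal(volData(jl)[inner], rep(det(diag(3) + A), sum(inner)),
               tolerance = 1e-10)

  f <- smoothField(d, spacing = 2, amplitude = 1.5, seed = 13)
  jf <- volData(jacobianDeterminant(f))
  oracle <- jacobianOracle(f)
  keep <- !is.na(oracle)
  expect_lt(max(abs(jf[keep] - oracle[keep])), 1e-10)
})

test_that("downsampling and field resampling preserve geometry", {
  d <- c(16L, 16L, 16L)
  v <- blobVolume(d, seed = 14)
  expect_identical(downsampleVolume(v, 1L), v)

  cst <- Volume(array(3, d), spacing = 1)
  dc <- downsampleVolume(cst, 2L)
  expect_equal(dims(dc), c(8L, 8L, 8L))
  expect_equal(volData(dc), array(3, c(8, 8, 8)), tolerance = 1e-12)
  expect_equal(volSpacing(dc), c(2, 2, 2))

  # linear ramp: prefiltered decimation still matches the analytic ramp at
  # the retained voxel centres (away from the reflected boundary)
  ramp <- Volume(array(rep(1:16, times = 256), d), spacing = 1)
  dr <- downsampleVolume(ramp, 2L)
  expected <- array(rep(seq(1, 15, by = 2), times = 64), c(8, 8, 8))
  expect_equal(volData(dr)[3:6, , ], expected[3:6, , ], tolerance = 1e-6)

  expect_error(downsampleVolume(v, 32L), "exceeds grid")

  f <- smoothField(c(8L, 8L, 8L), spacing = 2, amplitude = 1, seed = 15)
  up <- upsampleField(f, c(15L, 15L, 15L), spacing = 1)
  expect_equal(dims(up), c(15L, 15L, 15L))
  # vectors at coinciding physical locations are preserved
  expect_equal(up@data[seq(1, 15, 2), seq(1, 15, 2), seq(1, 15, 2), ],
               f@data, tolerance = 1e-9)
})

test_that("affine fields: identity, translation, right-angle rotation", {
  d <- c(8L, 8L, 8L)
  zf <- affineToField(identityAffine(), d)
  expect_equal(max(abs(zf@data)), 0)

  tf <- affineToField(Affine(diag(3), c(1, 2, -3)), d)
  expect_equal(tf@data[, , , 1], array(1, d))
  expect_equal(tf@data[, , , 3], array(-3, d))

  # 90 degree rotation about z around the grid centre permutes voxels exactly
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  ctr <- (d - 1) / 2
  aff <- Affine(Rz, as.numeric(ctr - Rz %*% ctr))
  bar <- array(0, d)
  bar[2:7, 4, 4] <- 1  # axis-aligned bar
  v <- Volume(bar, spacing = 1)
  w <- warpVolume(v, affineToField(aff, d), "nearest")
  # index-permutation oracle: the pull-back warp places value bar(A(x)) at x,
  # so the warped bar is the original mapped through the inverse rotation
  oracle <- array(0, d)
  for (i in which(bar == 1)) {
    idx <- as.numeric(arrayInd(i, d)) - 1
    p <- as.numeric(t(Rz) %*% (idx - ctr)) + ctr  # inverse rotation
    oracle[round(p[1]) + 1, round(p[2]) + 1, round(p[3]) + 1] <- 1
  }
  expect_identical(w@data + 0, oracle)
  expect_true(all(w@data[4, 2:7, 4] == 1))

  expect_error(Affine(matrix(0, 3, 3)), "invertible")
})

test_that("affine algebra composes and inverts exactly", {
  a <- Affine(matrix(c(1.1, 0.1, 0, 0, 0.9, 0.05, 0.02, 0, 1), 3), c(4, -2, 1))
  b <- Affine(matrix(c(1, 0, 0.1, 0.05, 1.05, 0, 0, 0.02, 0.95), 3), c(-1, 3, 2))
  ab <- composeAffine(a, b)
  x <- c(10, -5, 7)
  expect_equal(as.numeric(ab@linear %*% x) + ab@translation,
               as.numeric(a@linear %*% (b@linear %*% x + b@translation)) +
                 a@translation, tolerance = 1e-12)
  ai <- invertAffine(a)
  ident <- composeAffine(a, ai)
  expect_equal(ident@linear, diag(3), tolerance = 1e-12)
  expect_equal(ident@translation, c(0, 0, 0), tolerance = 1e-12)
})
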