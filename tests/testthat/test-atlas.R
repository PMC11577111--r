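# Atlas construction: averaging, label atlases, inverse-field unbiasing.

test_that("initial atlas averaging matches trivial and oracle cases", {
  d <- c(10L, 10L, 10L)
  v <- blobVolume(d, seed = 30)
  one <- buildInitialAtlas(list(v), list(zeroField(d)))
  expect_equal(volData(one$atlas), volData(v), tolerance = 1e-14)
  expect_equal(volData(one$coverage), array(1, d))

  a0 <- Volume(array(0, d))
  a1 <- Volume(array(1, d))
  two <- buildInitialAtlas(list(a0, a1), list(zeroField(d), zeroField(d)))
  expect_equal(volData(two$atlas), array(0.5, d))

  # warp-then-mean oracle on 5 deformed copies
  flds <- lapply(1:5, function(s) smoothField(d, amplitude = 1, seed = 30 + s))
  imgs <- lapply(1:5, function(s) blobVolume(d, seed = 40 + s))
  got <- buildInitialAtlas(imgs, flds)
  oracle <- Reduce(`+`, Map(function(i, f) volData(warpVolume(i, f)),
                            imgs, flds)) / 5
  expect_equal(volData(got$atlas), oracle, tolerance = 1e-12)
  expect_error(buildInitialAtlas(list(), list()), "empty")
  expect_error(buildInitialAtlas(imgs, flds[1:2]), "equal length")
})

test_that("label atlases are probability maps of warped indicators", {
  d <- c(8L, 8L, 8L)
  lab1 <- array(0L, d); lab1[2:4, 2:4, 2:4] <- 1L
  lab2 <- array(0L, d); lab2[3:5, 2:4, 2:4] <- 1L
  l1 <- LabelMap(lab1, c("1" = "organ"))
  l2 <- LabelMap(lab2, c("1" = "organ"))
  ident <- list(zeroField(d), zeroField(d))

  single <- buildLabelAtlas(list(l1), ident[1])
  expect_equal(volData(single$organ), (lab1 == 1) + 0)

  same <- buildLabelAtlas(list(l1, l1), ident)
  expect_true(all(volData(same$organ)[lab1 == 1] == 1))
  expect_true(all(volData(same$organ)[lab1 == 0] == 0))

  # half-overlapping masks with identity fields: exactly 0.5 on the
  # symmetric difference, 1 on the intersection
  half <- buildLabelAtlas(list(l1, l2), ident)
  sym <- xor(lab1 == 1, lab2 == 1)
  expect_true(all(volData(half$organ)[sym] == 0.5))
  expect_true(all(volData(half$organ)[lab1 == 1 & lab2 == 1] == 1))

  l3 <- LabelMap(lab2, c("1" = "something_else"))
  expect_error(buildLabelAtlas(list(l1, l3), ident), "inconsistent")
})

test_that("average inverse field cancels symmetric translations", {
  d <- c(10L, 10L, 10L)
  tp <- Field(array(rep(c(2, -1, 0.5), each = prod(d)), c(d, 3)))
  tm <- Field(-tp@data)
  phi <- averageInverseField(list(tp, tm), tol = 1e-8, maxIter = 200)
  expect_lt(max(abs(phi@data)), 1e-6)
  expect_length(attr(phi, "residuals"), 2L)

  # n = 1: the inverse itself
  one <- averageInverseField(list(tp), tol = 1e-8, maxIter = 200)
  expect_equal(one@data, invertField(tp, tol = 1e-8, maxIter = 200)@data,
               tolerance = 1e-12)

  # invert-each-then-mean oracle on integrated velocities
  flds <- lapply(1:5, function(s) smoothField(d, amplitude = 1, seed = 50 + s))
  got <- averageInverseField(flds, tol = 1e-6, maxIter = 300)
  oracle <- Reduce(`+`, lapply(flds, function(f)
    invertField(f, tol = 1e-6, maxIter = 300)@data)) / 5
  expect_equal(got@data, oracle, tolerance = 1e-12)
})

test_that("unbiasing recovers the n = 1 round trip within 2 percent", {
  d <- c(28L, 28L, 28L)
  # a well-resolved Gaussian: two trilinear interpolations stay within the
  # stated 2 percent of the dynamic range
  g <- coordArrays(d)
  v <- Volume(exp(-((g$x - 13.5)^2 + (g$y - 13.5)^2 + (g$z - 13.5)^2) / 80))
  f <- smoothField(d, amplitude = 1, corrLength = 10, seed = 61)
  atlas <- buildAtlas(list(warpOrig <- v), labels = NULL, fields = list(f))
  # A_init = I o phi; A_u = (I o phi) o phi^-1 ~ I
  ua <- unbiasAtlas(atlas, fields = list(f), tol = 1e-6, maxIter = 300)
  rng <- diff(range(volData(v)))
  inner <- interiorIndex(d, 3L)
  expect_lt(max(abs(volData(atlasAnatomy(ua))[inner] -
                      volData(v)[inner])), 0.02 * rng)
  expect_true(isUnbiased(ua))
  expect_false(isUnbiased(atlas))
})

test_that("pure-translation populations unbias to the exact mean shift", {
  d <- c(12L, 12L, 12L)
  v <- blobVolume(d, seed = 62)
  ts <- list(c(1, 0, 0), c(3, 0, 0), c(2, 1, -1))
  flds <- lapply(ts, function(t)
    Field(array(rep(t, each = prod(d)), c(d, 3))))
  atlas <- buildAtlas(list(v, v, v), fields = flds)
  ua <- unbiasAtlas(atlas, fields = flds, tol = 1e-9, maxIter = 500)
  # closed form: A_u = A_init shifted by mean(-t_i)
  mt <- -Reduce(`+`, ts) / 3
  shifted <- warpVolume(atlasAnatomy(atlas),
                        Field(array(rep(mt, each = prod(d)), c(d, 3))))
  expect_equal(volData(atlasAnatomy(ua)), volData(shifted), tolerance = 1e-6)
})

test_that("unbiasing moves the atlas centroid toward the population mean", {
  # population deformed symmetrically about the template, reference
  # deliberately off-centre: the unbiased centroid must be closer to the
  # template's centroid than the initial atlas's is
  spec <- smallSpec(seed = 70)
  tpl <- makeTemplate(spec)
  d <- spec$gridDim
  shift <- function(t) affineToField(Affine(diag(3), t), d, spec$spacing)
  offs <- list(c(12, 0, 0), c(-12, 0, 0), c(0, 9, 0), c(0, -9, 0))
  subs <- lapply(offs, function(t) warpVolume(tpl$volume, shift(t)))
  # reference = first subject (off-centre); fields map reference -> subject
  flds <- lapply(offs, function(t) shift(c(t[1] - 12, t[2], t[3])))
  centroid <- function(v) {
    w <- volData(v)
    w[w < 0.1] <- 0
    idx <- which(w > 0, arr.ind = TRUE)
    colSums(idx * w[w > 0]) / sum(w[w > 0])
  }
  atlas <- buildAtlas(subs, fields = flds)
  ua <- unbiasAtlas(atlas, fields = flds, tol = 1e-6, maxIter = 300)
  c0 <- centroid(tpl$volume)
  dInit <- sqrt(sum((centroid(atlasAnatomy(atlas)) - c0)^2))
  dUnb <- sqrt(sum((centroid(atlasAnatomy(ua)) - c0)^2))
  expect_lt(dUnb, dInit)
})

test_that("probability ranges survive unbiasing and coverage masks flow", {
  spec <- smallSpec(seed = 71)
  tpl <- makeTemplate(spec)
  subs <- lapply(1:3, function(s)
    sampleSubject(tpl, spec, deform = list(amplitude = 4), seed = 80 + s))
  flds <- lapply(subs, function(s) invertField(s$phiTrue, maxIter = 100))
  atlas <- buildAtlas(lapply(subs, `[[`, "volume"),
                      lapply(subs, `[[`, "labels"), flds)
  expect_length(atlasProbability(atlas), 7L)
  ua <- unbiasAtlas(atlas, fields = flds)
  for (p in atlasProbability(ua)) {
    expect_gte(min(volData(p)), 0)
    expect_lte(max(volData(p)), 1)
  }
  expect_true(all(volData(atlasCoverage(ua)) <= 1 + 1e-9))
})
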