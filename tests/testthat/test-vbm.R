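# Voxel-based morphometry: smoothing, GLM z-maps, FDR control.

mkMaps <- function(n, d, gen, spacing = 1) {
  lapply(seq_len(n), function(i) Volume(gen(i), spacing = spacing))
}

test_that("smoothing honours FWHM conventions", {
  d <- c(9L, 9L, 9L)
  v <- blobVolume(d, seed = 90)
  expect_identical(smoothVolume(v, 0), v)

  cst <- Volume(array(4, d), spacing = 2)
  expect_equal(volData(smoothVolume(cst, 5)), array(4, d), tolerance = 1e-9)

  # delta impulse away from the boundary: discrete Gaussian with unit mass
  d13 <- c(13L, 13L, 13L)
  imp <- array(0, d13); imp[7, 7, 7] <- 1
  sm <- smoothVolume(Volume(imp, spacing = 2), fwhm = 2.355 * 2)
  expect_equal(sum(volData(sm)), 1, tolerance = 1e-6)
  expect_equal(which.max(volData(sm)), which.max(imp))
})

test_that("the GLM z-map is zero for identical groups and matches t.test", {
  d <- c(5L, 4L, 3L)
  set.seed(91)
  a <- mkMaps(3, d, function(i) array(rnorm(prod(d)), d))
  same <- glmGroupTest(a, a)
  expect_true(all(volData(same@z) == 0))
  expect_equal(same@flagged, 0L)  # variance within groups is non-zero

  # constant maps: zero pooled variance everywhere -> all voxels flagged,
  # z forced to 0, and excluded from the analysis mask
  cst <- mkMaps(3, d, function(i) array(1, d))
  cst2 <- mkMaps(3, d, function(i) array(2, d))
  degen <- glmGroupTest(cst, cst2)
  expect_equal(degen@flagged, prod(d))
  expect_true(all(volData(degen@z) == 0))
  expect_equal(sum(volData(degen@analysisMask)), 0)

  b <- mkMaps(3, d, function(i) array(rnorm(prod(d), 0.5), d))
  zm <- glmGroupTest(a, b)
  # independent oracle: per-voxel pooled-variance two-sample t
  av <- vapply(a, volData, array(0, d))
  bv <- vapply(b, volData, array(0, d))
  dim(av) <- c(prod(d), 3); dim(bv) <- c(prod(d), 3)
  for (vx in c(1, 7, 30, prod(d))) {
    tt <- t.test(bv[vx, ], av[vx, ], var.equal = TRUE)
    expect_equal(volData(zm@z)[vx],
                 sign(tt$statistic) * qnorm(tt$p.value / 2, lower.tail = FALSE),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(volData(zm@p)[vx], tt$p.value, tolerance = 1e-12)
  }
  # sign convention: positive z where the second group mean is larger
  expect_gt(mean(volData(zm@z)), 0)
})

test_that("closed-form t on a tiny fixture reproduces the textbook value", {
  d <- c(2L, 1L, 1L)
  a <- mkMaps(3, d, function(i) array(c(1, 5) + c(0.1, -0.2, 0.1)[i], d))
  b <- mkMaps(3, d, function(i) array(c(2, 4) + c(-0.1, 0.2, -0.1)[i], d))
  zm <- glmGroupTest(a, b)
  av <- sapply(a, function(v) volData(v)[1])
  bv <- sapply(b, function(v) volData(v)[1])
  sp <- sqrt((sum((av - mean(av))^2) + sum((bv - mean(bv))^2)) / 4)
  tman <- (mean(bv) - mean(av)) / (sp * sqrt(2 / 3))
  p <- 2 * pt(-abs(tman), 4)
  expect_equal(volData(zm@p)[1], p, tolerance = 1e-12)
})

test_that("null z-scores have the nominal tail rate", {
  d <- c(16L, 16L, 8L)
  set.seed(92)
  a <- mkMaps(8, d, function(i) array(rnorm(prod(d)), d))
  b <- mkMaps(8, d, function(i) array(rnorm(prod(d)), d))
  zm <- glmGroupTest(a, b)
  rate <- mean(abs(volData(zm@z)) > qnorm(0.975))
  mcse <- sqrt(0.05 * 0.95 / prod(d))
  expect_lt(abs(rate - 0.05), 4 * mcse + 0.005)
})

test_that("BH thresholding follows the step-up rule", {
  d <- c(3L, 1L, 1L)
  mkZ <- function(ps) {
    z <- Volume(array(qnorm(ps / 2, lower.tail = FALSE), d))
    new("VoxelZMap", z = z, p = Volume(array(ps, d)),
        sigMask = Volume(array(0, d)),
        analysisMask = Volume(array(1, d)), flagged = 0L,
        params = list(q = NA_real_, pRetain = NA_real_))
  }
  # {0.001, 0.02, 0.04} all pass BH at q = 0.05 (step-up from the largest)
  zm <- fdrThreshold(mkZ(c(0.001, 0.02, 0.04)), q = 0.05, pRetain = 1)
  expect_equal(sum(volData(zm@sigMask)), 3)
  expect_equal(volData(zm@p)[1], 0.003, tolerance = 1e-12)  # 0.001 * 3 / 1

  flat <- fdrThreshold(mkZ(rep(0.5, 3)), q = 0.05, pRetain = 1)
  expect_equal(sum(volData(flat@sigMask)), 0)

  # the retention threshold bites on corrected values
  strict <- fdrThreshold(mkZ(c(1e-5, 0.02, 0.04)), q = 0.05, pRetain = 0.001)
  expect_equal(sum(volData(strict@sigMask)), 1)
})

test_that("null runVBM yields an empty significance mask and is seeded", {
  d <- c(12L, 12L, 8L)
  set.seed(93)
  h <- lapply(1:6, function(i)
    list(map = Volume(array(rnorm(prod(d), 1), d)), field = NULL))
  zm1 <- runVBM(h[1:3], h[4:6], fwhm = 2, seed = 5)
  expect_equal(sum(volData(zm1@sigMask)), 0)
  zm2 <- runVBM(h[1:3], h[4:6], fwhm = 2, seed = 5)
  expect_identical(volData(zm1@z), volData(zm2@z))
  # balancing subsamples the larger group deterministically
  zb <- runVBM(h[1:4], h[5:6], fwhm = 2, seed = 7)
  expect_equal(zb@params$nA, 2L)
})

test_that("null false-discovery proportion is controlled at level q", {
  # 200 replicates of small-grid two-group nulls; all discoveries are false,
  # so the mean FDP must not exceed q within Monte-Carlo error
  d <- c(8L, 8L, 4L)
  q <- 0.05
  set.seed(94)
  fdp <- replicate(200, {
    a <- mkMaps(5, d, function(i) array(rnorm(prod(d)), d))
    b <- mkMaps(5, d, function(i) array(rnorm(prod(d)), d))
    zm <- fdrThreshold(glmGroupTest(a, b), q = q, pRetain = 1)
    r <- sum(volData(zm@sigMask))
    if (r == 0) 0 else 1  # every discovery under the null is false
  })
  mcse <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), q + 2 * mcse)
})

test_that("a planted regional effect is recovered with high sensitivity", {
  # small-scale planted-effect check (the full phantom version runs in the
  # acceptance suite): a +0.15 mean shift in a known region, n = 15 vs 15
  d <- c(16L, 16L, 8L)
  region <- array(FALSE, d); region[5:12, 5:12, 3:6] <- TRUE
  set.seed(95)
  gen <- function(shift) function(i) {
    x <- array(rnorm(prod(d), 0, 0.25), d)
    x[region] <- x[region] + shift
    x
  }
  h <- mkMaps(15, d, gen(0))
  dis <- mkMaps(15, d, gen(0.3))
  zm <- runVBM(lapply(h, function(m) list(map = m, field = NULL)),
               lapply(dis, function(m) list(map = m, field = NULL)),
               fwhm = 2, q = 0.05, pRetain = 0.01, seed = 9)
  sig <- volData(zm@sigMask) > 0
  sens <- sum(sig & region) / sum(region)
  expect_gte(sens, 0.7)
  # discoveries outside the smoothing reach of the region are rare
  reach <- volData(gaussSmooth(Volume(region + 0), 2)) > 1e-4
  fpFrac <- sum(sig & !reach) / max(sum(sig), 1)
  expect_lte(fpFrac, 0.1)
})
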