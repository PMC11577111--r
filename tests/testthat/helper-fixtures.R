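# Shared fixtures: all synthetic, built in code at test time.

# a reduced-scale phantom spec for fast end-to-end tests
smallSpec <- function(noiseSd = 0.02, seed = 1L, ...) {
  phantomSpec(gridDim = c(32L, 24L, 48L), spacing = 6, noiseSd = noiseSd,
              seed = seed, ...)
}

# smooth random displacement field from an integrated bounded velocity
smoothField <- function(dim, spacing = 1, amplitude = 1, corrLength = 6,
                        seed = 1L, steps = 6L) {
  set.seed(seed)
  v <- randomVelocity(dim, spacing, amplitude = amplitude,
                      corrLength = corrLength)
  integrateVelocity(v, steps)
}

# smooth test image: sum of Gaussian blobs, strictly positive in the interior
blobVolume <- function(dim, spacing = 1, seed = 1L) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  v <- numeric(nrow(g))
  for (b in 1:3) {
    c_ <- runif(3, 0.25, 0.75) * dim
    s_ <- runif(1, 0.1, 0.25) * min(dim)
    v <- v + exp(-((g$x - c_[1])^2 + (g$y - c_[2])^2 + (g$z - c_[3])^2) /
                   (2 * s_^2))
  }
  Volume(array(v, dim), spacing = spacing)
}

# independent finite-difference Jacobian-determinant oracle (plain R loops,
# central differences in the interior only)
jacobianOracle <- function(field) {
  u <- field@data
  d <- dim(u)[1:3]
  sp <- field@spacing
  out <- array(NA_real_, d)
  for (k in 2:(d[3] - 1)) for (j in 2:(d[2] - 1)) for (i in 2:(d[1] - 1)) {
    J <- matrix(0, 3, 3)
    for (c_ in 1:3) {
      J[c_, 1] <- (u[i + 1, j, k, c_] - u[i - 1, j, k, c_]) / (2 * sp[1])
      J[c_, 2] <- (u[i, j + 1, k, c_] - u[i, j - 1, k, c_]) / (2 * sp[2])
      J[c_, 3] <- (u[i, j, k + 1, c_] - u[i, j, k - 1, c_]) / (2 * sp[3])
    }
    out[i, j, k] <- det(diag(3) + J)
  }
  out
}

# magnitude array (mm) of a displacement field
fieldMagnitude <- function(field) {
  n <- prod(dims(field))
  u <- field@data
  array(sqrt(u[seq_len(n)]^2 + u[n + seq_len(n)]^2 + u[2 * n + seq_len(n)]^2),
        dims(field))
}

# physical coordinate arrays of voxel centres (origin 0)
coordArrays <- function(dim, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  list(x = array((seq_len(dim[1]) - 1) * spacing[1], dim),
       y = array(rep((seq_len(dim[2]) - 1) * spacing[2], each = dim[1]), dim),
       z = array(rep((seq_len(dim[3]) - 1) * spacing[3],
                     each = dim[1] * dim[2]), dim))
}

# interior (boundary ring stripped) logical index
interiorIndex <- function(dim, ring = 2L) {
  m <- array(FALSE, dim)
  m[(ring + 1):(dim[1] - ring), (ring + 1):(dim[2] - ring),
    (ring + 1):(dim[3] - ring)] <- TRUE
  m
}
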