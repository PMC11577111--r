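# Synthetic 3D body phantoms: a template body (outline, subcutaneous-fat
# shell, visceral-fat blobs, five organ ellipsoids), per-subject ground-truth
# diffeomorphic deformations, and matching phenotype tables.  The phantom
# cohort stands in for access-restricted whole-body MRI data; every generated
# deformation is exact ground truth for registration and atlas tests.

PHANTOM_LABELS <- c("0" = "background", "1" = "subcutaneous_fat",
                    "2" = "visceral_fat", "3" = "liver", "4" = "spleen",
                    "5" = "pancreas", "6" = "kidney_L", "7" = "kidney_R")

#' Phantom specification
#'
#' Geometry, intensity model and seed of the synthetic body template.  All
#' lengths are mm; organ centres are offsets from the body centre.  The
#' default grid (64 x 48 x 96 at 3 mm) mimics the neck-to-knee aspect ratio
#' of whole-body MRI at a reduced scale.
#'
#' @param gridDim integer(3) grid dims.
#' @param spacing mm per voxel.
#' @param bodySemiAxes mm semi-axes of the body ellipsoid.
#' @param shellThickness mm thickness of the subcutaneous-fat shell.
#' @param visceralBlobs number of visceral-fat blobs.
#' @param blobRadius mm range of blob radii.
#' @param organs named list of \code{list(centre =, semi =)} for liver,
#'   spleen, pancreas, kidney_L, kidney_R.
#' @param intensity named means per tissue (water-contrast convention: lean
#'   tissue and organs bright, fat dark, background 0).
#' @param noiseSd Gaussian intensity noise sd.
#' @param seed integer controlling blob placement and noise.
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(gridDim = c(64L, 48L, 96L), spacing = 3,
                        bodySemiAxes = c(80, 55, 130), shellThickness = 12,
                        visceralBlobs = 6L, blobRadius = c(8, 14),
                        organs = NULL,
                        intensity = c(lean = 0.55, subcutaneous_fat = 0.25,
                                      visceral_fat = 0.25, liver = 0.8,
                                      spleen = 0.75, pancreas = 0.7,
                                      kidney_L = 0.85, kidney_R = 0.85),
                        noiseSd = 0.02, seed = 1L) {
  if (is.null(organs)) {
    organs <- list(
      liver = list(centre = c(32, -5, 42), semi = c(28, 22, 26)),
      spleen = list(centre = c(-40, 5, 38), semi = c(14, 12, 17)),
      pancreas = list(centre = c(-4, 14, 14), semi = c(24, 8, 8)),
      kidney_L = list(centre = c(-28, 26, -14), semi = c(11, 10, 19)),
      kidney_R = list(centre = c(28, 26, -14), semi = c(11, 10, 19))
    )
  }
  if (shellThickness >= min(bodySemiAxes))
    stop("shell thickness must be smaller than the body minor axis")
  spec <- list(gridDim = as.integer(gridDim), spacing = rep(spacing, 3)[1:3],
               bodySemiAxes = bodySemiAxes, shellThickness = shellThickness,
               visceralBlobs = as.integer(visceralBlobs),
               blobRadius = blobRadius, organs = organs,
               intensity = intensity, noiseSd = noiseSd,
               seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

# squared normalised ellipsoid coordinate: <= 1 inside
.ellipsoidQ <- function(g, centre, semi) {
  ((g$x - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
    ((g$z - centre[3]) / semi[3])^2
}

.phantomCentre <- function(spec) {
  (spec$gridDim - 1) * spec$spacing / 2
}

#' Build the phantom template
#'
#' Deterministic given the spec's seed.  Paints, in order: subcutaneous-fat
#' shell (body minus inner ellipsoid), visceral-fat blobs (random spheres in
#' the abdominal interior), then the five organ ellipsoids (which take
#' precedence).  Intensities are tissue means plus Gaussian noise; the
#' background is exactly 0.
#'
#' @param spec a [phantomSpec()].
#' @return List with \code{volume} ([BodyVolume]), \code{labels}
#'   ([LabelVolume]) and \code{bodySupport} (binary array of the body
#'   ellipsoid, the ground-truth mask support).
#' @export
makeTemplate <- function(spec = phantomSpec()) {
  d <- spec$gridDim
  ctr <- .phantomCentre(spec)
  g <- gridCoords(d, spec$spacing, c(0, 0, 0))
  body <- .ellipsoidQ(g, ctr, spec$bodySemiAxes) <= 1
  inner <- .ellipsoidQ(g, ctr, spec$bodySemiAxes - spec$shellThickness) <= 1
  lab <- array(0L, d)
  lab[body & !inner] <- 1L
  set.seed(spec$seed)
  if (spec$visceralBlobs > 0) {
    core <- spec$bodySemiAxes - spec$shellThickness - max(spec$blobRadius)
    placed <- 0L
    while (placed < spec$visceralBlobs) {
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      cen <- ctr + u * core * c(1, 1, 0.45)  # abdominal band
      r <- runif(1, spec$blobRadius[1], spec$blobRadius[2])
      blob <- .ellipsoidQ(g, cen, rep(r, 3)) <= 1
      lab[blob & inner] <- 2L
      placed <- placed + 1L
    }
  }
  organIds <- c(liver = 3L, spleen = 4L, pancreas = 5L, kidney_L = 6L,
                kidney_R = 7L)
  organMask <- array(FALSE, d)
  for (nm in names(organIds)) {
    o <- spec$organs[[nm]]
    m <- .ellipsoidQ(g, ctr + o$centre, o$semi) <= 1
    if (any(m & organMask))
      stop(sprintf("overlapping organ spec: %s intersects another organ", nm))
    if (any(m & !inner))
      stop(sprintf("organ %s extends outside the body interior", nm))
    lab[m] <- organIds[[nm]]
    organMask <- organMask | m
  }
  vol <- .paintAnatomy(lab, body, spec)
  list(volume = Volume(vol, spacing = spec$spacing),
       labels = LabelMap(lab, PHANTOM_LABELS, spacing = spec$spacing),
       bodySupport = body)
}

# intensity painting: tissue means + Gaussian noise inside the body.
# assumes the RNG state is positioned as intended by the caller.
.paintAnatomy <- function(lab, body, spec) {
  d <- dim(lab)
  vol <- array(0, d)
  vol[body & lab == 0L] <- spec$intensity[["lean"]]
  for (id in 1:7)
    vol[lab == id] <- spec$intensity[[PHANTOM_LABELS[[as.character(id)]]]]
  if (spec$noiseSd > 0)
    vol[body] <- vol[body] + rnorm(sum(body), 0, spec$noiseSd)
  vol
}

#' Smooth random velocity field
#'
#' White Gaussian noise per component, convolved with a Gaussian kernel of
#' the given correlation length and rescaled so the largest velocity
#' magnitude equals \code{amplitude} mm.  Small amplitudes integrate to
#' folding-free (diffeomorphic) displacements.
#'
#' @param dim integer(3) grid dims.
#' @param spacing mm.
#' @param amplitude mm, maximum velocity magnitude.
#' @param corrLength mm, Gaussian correlation length.
#' @return A [DisplacementField] holding the velocity.
#' @export
randomVelocity <- function(dim, spacing, amplitude = 6, corrLength = 24) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sig <- corrLength / spacing
  comp <- lapply(1:3, function(cc) {
    w <- array(rnorm(prod(dim)), dim)
    array(.C_gauss3d(as.numeric(w), as.integer(dim), sig), dim)
  })
  u <- array(c(comp[[1]], comp[[2]], comp[[3]]), c(dim, 3L))
  if (amplitude > 0) {
    n <- prod(dim)
    mag <- sqrt(u[seq_len(n)]^2 + u[n + seq_len(n)]^2 + u[2 * n + seq_len(n)]^2)
    mx <- max(mag)
    if (mx > 0) u <- u * (amplitude / mx)
  } else u[] <- 0
  Field(u, spacing = spacing)
}

#' Sample one synthetic subject from the template
#'
#' The ground-truth transform is \code{phi_true = affine(scale, translation)
#' composed with the flow of a smooth random velocity}; anatomy (linear) and
#' labels (nearest) are warped by it.  The subject image equals the template
#' resampled at \code{phi_true}, so registering the subject back to the
#' template should recover the inverse of \code{phi_true}.  Fully
#' reproducible from \code{seed}; zero amplitude with an identity affine
#' reproduces the template bit-for-bit.
#'
#' @param template result of [makeTemplate()].
#' @param spec the [phantomSpec()] used for the template.
#' @param deform list: \code{amplitude} (mm), \code{corrLength} (mm),
#'   \code{scaleRange}, \code{translationRange} (mm).
#' @param group requested sex x BMI group for the phenotype record.
#' @param subjectId id string.
#' @param extraFat optional \code{list(mask =, prob =)}: template-space
#'   voxels (array) painted as visceral fat with the given per-voxel
#'   probability before deformation (used for planted-effect cohorts).
#' @param seed integer.
#' @return List of class \code{"SyntheticSubject"}: \code{volume},
#'   \code{labels}, \code{phiTrue} ([DisplacementField]), \code{record}
#'   (one-row data.frame).
#' @export
sampleSubject <- function(template, spec, deform = list(), group = "female-overweight",
                          subjectId = "S0001", extraFat = NULL, seed = 1L) {
  dp <- modifyList(list(amplitude = 6, corrLength = 24,
                        scaleRange = c(0.95, 1.05), translationRange = 9,
                        squaringSteps = 6L), deform)
  d <- spec$gridDim
  set.seed(seed)
  lab <- template$labels@data
  vol <- template$volume@data
  if (!is.null(extraFat)) {
    idx <- which(extraFat$mask & lab == 0L)
    take <- idx[runif(length(idx)) < extraFat$prob]
    lab[take] <- 2L
    vol[take] <- spec$intensity[["visceral_fat"]] +
      if (spec$noiseSd > 0) rnorm(length(take), 0, spec$noiseSd) else 0
  }
  # ground-truth transform
  vel <- randomVelocity(d, spec$spacing, dp$amplitude, dp$corrLength)
  disp <- integrateVelocity(vel, dp$squaringSteps)
  s <- runif(1, dp$scaleRange[1], dp$scaleRange[2])
  tr <- runif(3, -dp$translationRange, dp$translationRange)
  ctr <- .phantomCentre(spec)
  aff <- Affine(diag(3) * s, as.numeric(ctr - s * ctr + tr))
  affField <- affineToField(aff, d, spec$spacing)
  identity_ <- dp$amplitude == 0 && all(dp$scaleRange == 1) &&
    dp$translationRange == 0
  if (identity_) {
    phiTrue <- zeroField(d, spec$spacing)  # exact identity: no resampling
    volW <- Volume(vol, spacing = spec$spacing)
    labW <- LabelMap(lab, PHANTOM_LABELS, spacing = spec$spacing)
  } else {
    phiTrue <- composeFields(affField, disp)
    fr <- foldingRatio(phiTrue)
    if (fr > 0)
      stop(sprintf(
        "requested deformation folds (folding ratio %.4g); reduce amplitude %g mm",
        fr, dp$amplitude))
    volM <- Volume(vol, spacing = spec$spacing)
    labM <- LabelMap(lab, PHANTOM_LABELS, spacing = spec$spacing)
    volW <- warpVolume(volM, phiTrue, "linear")
    labW <- warpVolume(labM, phiTrue, "nearest")
  }
  rec <- .sampleRecord(group, subjectId)
  out <- list(volume = volW, labels = labW, phiTrue = phiTrue, record = rec,
              seed = seed)
  class(out) <- "SyntheticSubject"
  out
}

# phenotypes consistent with the requested sex x BMI group
.sampleRecord <- function(group, subjectId) {
  parts <- strsplit(group, "-")[[1]]
  sex <- parts[1]
  cat_ <- parts[2]
  h <- min(max(rnorm(1, if (sex == "female") 163 else 176, 6), 145), 198)
  rng <- switch(cat_, normal = c(18.5, 24.9), overweight = c(25, 29.9),
                obese = c(30, 40))
  bmi <- runif(1, rng[1], rng[2])
  w <- bmi * (h / 100)^2
  bf <- if (sex == "female") 30 + 0.45 * bmi + rnorm(1, 0, 3)
        else -12 + 1.3 * bmi + rnorm(1, 0, 3)
  bf <- min(max(bf, 5), 60)
  data.frame(subject_id = subjectId, sex = sex,
             age = as.integer(round(runif(1, 45, 78))),
             weight = round(w, 1), height = round(h, 1),
             bmi = round(computeBMI(round(w, 1), round(h, 1)), 3),
             body_fat = round(bf, 1), cancer_record = FALSE,
             self_reported_disease = FALSE, operation_history = FALSE,
             stringsAsFactors = FALSE)
}

#' Perirenal region mask
#'
#' Template-space shell around both kidney ellipsoids (normalised ellipsoid
#' coordinate between 1 and the margin-expanded surface), restricted to the
#' body interior and excluding organ voxels.
#'
#' @param template result of [makeTemplate()].
#' @param spec the matching [phantomSpec()].
#' @param margin mm added to the kidney semi-axes for the outer shell.
#' @return Logical array on the template grid.
#' @export
perirenalRegion <- function(template, spec, margin = 9) {
  d <- spec$gridDim
  shell <- .perirenalMargin(spec) <= margin
  ctr <- .phantomCentre(spec)
  g <- gridCoords(d, spec$spacing, c(0, 0, 0))
  inner <- .ellipsoidQ(g, ctr, spec$bodySemiAxes - spec$shellThickness) <= 1
  shell & inner & template$labels@data == 0L
}

# per-voxel capsule margin: the smallest mm margin added to both kidney
# semi-axes that covers the voxel; Inf outside a 40 mm search radius and
# inside the kidneys themselves
.perirenalMargin <- function(spec) {
  d <- spec$gridDim
  ctr <- .phantomCentre(spec)
  g <- gridCoords(d, spec$spacing, c(0, 0, 0))
  m <- array(Inf, d)
  for (nm in c("kidney_L", "kidney_R")) {
    o <- spec$organs[[nm]]
    qi <- .ellipsoidQ(g, ctr + o$centre, o$semi)
    cand <- qi > 1 & .ellipsoidQ(g, ctr + o$centre, o$semi + 40) <= 1
    lo <- array(0, d)
    hi <- array(40, d)
    for (it in 1:25) {  # bisection: q(semi + mid) vs 1, monotone in mid
      mid <- (lo + hi) / 2
      qm <- ((g$x - ctr[1] - o$centre[1]) / (o$semi[1] + mid))^2 +
        ((g$y - ctr[2] - o$centre[2]) / (o$semi[2] + mid))^2 +
        ((g$z - ctr[3] - o$centre[3]) / (o$semi[3] + mid))^2
      inside <- qm <= 1
      hi[inside] <- mid[inside]
      lo[!inside] <- mid[!inside]
    }
    m[cand] <- pmin(m[cand], hi[cand])
  }
  m
}

#' Analytic capsule coverage probabilities
#'
#' For the capsule-thickness disease model (see [makeCohort()]): the
#' probability, per template voxel, that a subject's perirenal fat capsule
#' covers it, for a Gaussian thickness distribution.
#'
#' @param spec a [phantomSpec()].
#' @param thickness mean capsule thickness, mm.
#' @param sd between-subject thickness sd, mm.
#' @return Array of probabilities on the template grid.
#' @export
capsuleCoverageProb <- function(spec, thickness, sd) {
  m <- .perirenalMargin(spec)
  p <- array(0, spec$gridDim)
  fin <- is.finite(m)
  p[fin] <- stats::pnorm(m[fin], mean = thickness, sd = sd,
                         lower.tail = FALSE)
  p
}

#' Generate a phantom cohort
#'
#' Samples \code{n} subjects per requested group from one template.  With a
#' \code{diseaseEffect}, every subject carries a perirenal fat capsule — a
#' contiguous visceral-fat layer around both kidneys whose thickness is
#' drawn per subject from a Gaussian — and the diseased subgroup's mean
#' thickness is \code{(1 + delta)} times the healthy mean (a +30 percent
#' regional fat increase by default, the planted effect for the
#' voxel-based-morphometry experiment).  The \code{plantedRegion} returned
#' is the set of voxels whose analytic capsule-coverage probability differs
#' between the groups by more than 0.5.  When \code{dir} is given, subjects
#' are written as NIfTI volumes with a phenotype CSV and a JSON ground-truth
#' manifest; otherwise the cohort is returned in memory.
#'
#' @param n subjects per group.
#' @param groups character vector of group names.
#' @param spec a [phantomSpec()].
#' @param deform deformation parameters, see [sampleSubject()].
#' @param diseaseEffect NULL or \code{list(thickness = 18, sd = 2.5,
#'   delta = 0.3)} (mm, mm, relative increase).
#' @param nDiseased diseased subjects (sampled in the first group).
#' @param seed master seed; each subject uses a derived sub-seed.
#' @param dir optional output directory.
#' @return List with \code{template}, \code{spec}, \code{subjects} (list of
#'   [sampleSubject()] results), \code{diseased} (list), \code{phenotypes}
#'   (data.frame), \code{plantedRegion} (logical array or NULL).
#' @export
makeCohort <- function(n, groups = "female-overweight", spec = phantomSpec(),
                       deform = list(), diseaseEffect = NULL, nDiseased = 0L,
                       seed = 1L, dir = NULL) {
  stopifnot(n >= 1)
  template <- makeTemplate(spec)
  region <- NULL
  de <- NULL
  margin <- NULL
  if (!is.null(diseaseEffect)) {
    de <- modifyList(list(thickness = 18, sd = 2.5, delta = 0.3),
                     diseaseEffect)
    margin <- .perirenalMargin(spec)
    pH <- capsuleCoverageProb(spec, de$thickness, de$sd)
    pD <- capsuleCoverageProb(spec, de$thickness * (1 + de$delta), de$sd)
    paintable <- template$labels@data == 0L
    region <- abs(pD - pH) > 0.5 & paintable
  }
  capsule <- function(k, diseased) {
    if (is.null(de)) return(NULL)
    set.seed(seed * 1000L + k)  # thickness stream, separate from the subject
    t_i <- max(0, rnorm(1, de$thickness * (1 + if (diseased) de$delta else 0),
                        de$sd))
    list(mask = margin <= t_i, prob = 1)
  }
  subjects <- list()
  diseased <- list()
  recs <- list()
  k <- 0L
  for (g in groups) for (i in seq_len(n)) {
    k <- k + 1L
    id <- sprintf("S%04d", k)
    subjects[[id]] <- sampleSubject(template, spec, deform, group = g,
                                    subjectId = id,
                                    extraFat = capsule(k, FALSE),
                                    seed = seed * 10000L + k)
    recs[[id]] <- subjects[[id]]$record
  }
  for (i in seq_len(nDiseased)) {
    k <- k + 1L
    id <- sprintf("D%04d", i)
    diseased[[id]] <- sampleSubject(template, spec, deform, group = groups[1],
                                    subjectId = id,
                                    extraFat = capsule(k, TRUE),
                                    seed = seed * 10000L + k)
    rec <- diseased[[id]]$record
    rec$self_reported_disease <- TRUE
    diseased[[id]]$record <- rec
    recs[[id]] <- rec
  }
  phen <- do.call(rbind, recs)
  rownames(phen) <- NULL
  out <- list(template = template, spec = spec, subjects = subjects,
              diseased = diseased, phenotypes = phen, plantedRegion = region)
  if (!is.null(dir)) .writeCohort(out, dir)
  out
}

.writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(cohort$template$volume, file.path(dir, "template.nii.gz"))
  writeVolume(cohort$template$labels, file.path(dir, "template_labels.nii.gz"))
  all_ <- c(cohort$subjects, cohort$diseased)
  for (id in names(all_)) {
    s <- all_[[id]]
    writeVolume(s$volume, file.path(dir, paste0(id, ".nii.gz")))
    writeVolume(s$labels, file.path(dir, paste0(id, "_labels.nii.gz")))
    writeField(s$phiTrue, file.path(dir, paste0(id, "_phi_true.nii.gz")))
  }
  write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  manifest <- list(
    subjects = names(cohort$subjects), diseased = names(cohort$diseased),
    gridDim = cohort$spec$gridDim, spacing = cohort$spec$spacing,
    seed = cohort$spec$seed, labels = as.list(PHANTOM_LABELS))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
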