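# End-to-end orchestration: from a cohort directory (volumes + labels +
# phenotype CSV) through healthy filtering, grouping, reference selection,
# registration of every subject to the reference, atlas construction,
# unbiasing and evaluation.  Every artifact gets a provenance JSON (input
# hashes, config hash, package version) and completed stages are skipped on
# re-runs when their outputs and hashes are intact.

#' Pipeline configuration
#'
#' @param cohortDir directory holding \code{<id>.nii.gz},
#'   \code{<id>_labels.nii.gz} and \code{phenotypes.csv}.
#' @param outDir output root.
#' @param group group to build, e.g. \code{"female-overweight"}.
#' @param registration a [registrationConfig()].
#' @param initMode \code{"com"} or \code{"icp"}.
#' @param unbias build the unbiased atlas as well.
#' @param seed global seed recorded in provenance.
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(cohortDir, outDir, group = "female-overweight",
                           registration = registrationConfig(),
                           initMode = "com", unbias = TRUE, seed = 1L) {
  structure(list(cohortDir = cohortDir, outDir = outDir, group = group,
                 registration = registration, initMode = initMode,
                 unbias = unbias, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.writeProvenance <- function(path, config, inputs = character()) {
  prov <- list(
    configHash = .configHash(config),
    inputs = as.list(unname(tools::md5sum(inputs))),
    package = as.character(utils::packageVersion("bodyatlas")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full atlas pipeline for one group
#'
#' Stages: read phenotypes, filter healthy, assign groups, select the
#' reference subject, register every remaining subject of the group to the
#' reference (pre-processing + centre-of-mass init + affine + deformable),
#' build the initial anatomical and label atlases, unbias them, and write
#' the per-stage evaluation report.  Stage outputs already present with a
#' matching config hash are reused (resumable).
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage progress.
#' @return The output directory, invisibly; primary outputs are
#'   \code{atlas_initial*.nii.gz}, \code{atlas_unbiased*.nii.gz}, per-subject
#'   fields, \code{metrics.csv} and \code{provenance.json}.
#' @export
runGroupPipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  phenFile <- file.path(config$cohortDir, "phenotypes.csv")
  if (!file.exists(phenFile))
    stop("phenotype table not found: ", phenFile, call. = FALSE)
  phen <- readPhenotypes(phenFile)
  groups <- partitionCohort(phen, quiet = !verbose)
  if (is.null(groups[[config$group]]) || nrow(groups[[config$group]]) == 0L)
    stop(sprintf("group '%s' is empty after the healthy filter",
                 config$group), call. = FALSE)
  tab <- groups[[config$group]]
  refId <- selectReference(tab)
  say("reference subject: %s (phenotypes logged in provenance)", refId)
  loadSubject <- function(id) {
    vf <- file.path(config$cohortDir, paste0(id, ".nii.gz"))
    lf <- file.path(config$cohortDir, paste0(id, "_labels.nii.gz"))
    if (!file.exists(vf)) stop("missing volume for subject ", id,
                               call. = FALSE)
    list(volume = readVolume(vf),
         labels = if (file.exists(lf)) readVolume(lf) else NULL,
         volumeFile = vf)
  }
  ref <- loadSubject(refId)
  movingIds <- setdiff(tab$subject_id, refId)
  hash <- .configHash(config)
  fields <- list()
  affineFields <- list()
  subjects <- list()
  for (id in movingIds) {
    sub <- loadSubject(id)
    subjects[[id]] <- sub
    fieldFile <- file.path(config$outDir, paste0(id, "_field.nii.gz"))
    stampFile <- file.path(config$outDir, paste0(id, "_field.stamp.json"))
    if (file.exists(fieldFile) && file.exists(stampFile) &&
        identical(jsonlite::read_json(stampFile)$configHash, hash)) {
      say("subject %s: reusing existing field", id)
      fields[[id]] <- readField(fieldFile)
      affineFields[[id]] <- readField(
        file.path(config$outDir, paste0(id, "_affine_field.nii.gz")))
      next
    }
    say("registering subject %s to %s", id, refId)
    chain <- registerPair(ref$volume, sub$volume,
                          config = config$registration,
                          initMode = config$initMode, verbose = FALSE)
    fields[[id]] <- chain$field
    affineFields[[id]] <- chain$affineField
    writeField(chain$field, fieldFile)
    writeField(chain$affineField,
               file.path(config$outDir, paste0(id, "_affine_field.nii.gz")))
    jsonlite::write_json(list(configHash = hash,
                              foldingRatio = chain$foldingRatio),
                         stampFile, auto_unbox = TRUE)
  }
  say("building atlases from %d subjects", length(fields))
  images <- lapply(subjects, `[[`, "volume")
  labels <- lapply(subjects, `[[`, "labels")
  haveLabels <- !any(vapply(labels, is.null, logical(1)))
  atlas <- buildAtlas(images, if (haveLabels) labels else NULL,
                      unname(fields), referenceId = as.character(refId))
  .writeAtlas(atlas, config$outDir, "atlas_initial")
  if (config$unbias) {
    ua <- unbiasAtlas(atlas, fields = unname(fields))
    .writeAtlas(ua, config$outDir, "atlas_unbiased")
  }
  if (haveLabels) {
    say("evaluating registration quality")
    report <- evaluateGroup(
      labels, ref$labels,
      stageFields = list(pre = vector("list", length(fields)),
                         affine = unname(affineFields),
                         deformable = unname(fields)))
    write.csv(report, file.path(config$outDir, "metrics.csv"),
              row.names = FALSE)
    write.csv(attr(report, "summary"),
              file.path(config$outDir, "metrics_summary.csv"),
              row.names = FALSE)
  }
  .writeProvenance(file.path(config$outDir, "provenance.json"), config,
                   inputs = vapply(subjects, `[[`, "", "volumeFile"))
  invisible(config$outDir)
}

.writeAtlas <- function(atlas, dir, prefix) {
  writeVolume(atlas@anatomy, file.path(dir, paste0(prefix, ".nii.gz")))
  writeVolume(atlas@coverage,
              file.path(dir, paste0(prefix, "_coverage.nii.gz")))
  for (nm in names(atlas@probability))
    writeVolume(atlas@probability[[nm]],
                file.path(dir, sprintf("%s_prob_%s.nii.gz", prefix, nm)))
  jsonlite::write_json(atlas@provenance,
                       file.path(dir, paste0(prefix, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
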