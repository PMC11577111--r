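# NIfTI-1 and tabular I/O.  Volumes and label maps round-trip through
# .nii/.nii.gz with spacing and origin encoded in the header transform;
# displacement fields are 4D NIfTI (3 components, mm) with a JSON sidecar
# recording the warping convention.

#' Read / write volumes as NIfTI-1
#'
#' Spacing and origin are stored in the header affine (axis-aligned,
#' positive-diagonal transform).  \code{writeVolume} accepts a [BodyVolume],
#' [LabelVolume] or [BodyMask]; label dictionaries travel in a JSON sidecar
#' \code{<file>.labels.json} and are restored by \code{readVolume}.
#'
#' @param v volume to write.
#' @param file path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{readVolume}: a [BodyVolume] or [LabelVolume];
#'   \code{writeVolume}: the path, invisibly.
#' @export
writeVolume <- function(v, file) {
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing
  aff <- diag(c(v@spacing, 1))
  aff[1:3, 4] <- v@origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, file)
  if (is(v, "LabelVolume"))
    jsonlite::write_json(as.list(v@labels), .sidecarPath(file, "labels"),
                         auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeVolume
#' @export
readVolume <- function(file) {
  img <- RNifti::readNifti(file)
  geo <- .niftiGeometry(img)
  sidecar <- .sidecarPath(file, "labels")
  if (file.exists(sidecar)) {
    labels <- unlist(jsonlite::read_json(sidecar))
    LabelMap(array(as.integer(round(img)), dim(img)[1:3]), labels,
             spacing = geo$spacing, origin = geo$origin)
  } else {
    Volume(array(as.numeric(img), dim(img)[1:3]), spacing = geo$spacing,
           origin = geo$origin)
  }
}

.sidecarPath <- function(file, tag) {
  sub("\\.nii(\\.gz)?$", sprintf(".%s.json", tag), file)
}

.niftiGeometry <- function(img) {
  x <- RNifti::xform(img)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  list(spacing = as.numeric(spacing), origin = as.numeric(x[1:3, 4]))
}

#' Read / write displacement fields
#'
#' Fields are written as 4D NIfTI with three mm components plus a JSON
#' sidecar \code{<file>.field.json} recording the convention tag
#' (\code{"pullback"}), which is verified on read.
#'
#' @param field a [DisplacementField].
#' @param file path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{readField}: a [DisplacementField]; \code{writeField}: the
#'   path, invisibly.
#' @export
writeField <- function(field, file) {
  img <- RNifti::asNifti(field@data)
  RNifti::pixdim(img) <- c(field@spacing, 1)
  aff <- diag(c(field@spacing, 1))
  aff[1:3, 4] <- field@origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, file)
  jsonlite::write_json(list(convention = field@convention, units = "mm"),
                       .sidecarPath(file, "field"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeField
#' @export
readField <- function(file) {
  img <- RNifti::readNifti(file)
  geo <- .niftiGeometry(img)
  sidecar <- .sidecarPath(file, "field")
  conv <- "pullback"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    conv <- meta$convention
    if (!identical(conv, "pullback"))
      stop(sprintf("unsupported field convention '%s' in %s", conv, sidecar),
           call. = FALSE)
  }
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement field file must be 4D with 3 components", call. = FALSE)
  Field(array(as.numeric(img), d), spacing = geo$spacing, origin = geo$origin)
}

#' Read / write phenotype tables
#'
#' CSV with the schema of [validateSubjectTable()]; logical flags round-trip
#' as TRUE/FALSE, and the table is validated on read with errors naming the
#' offending column.
#'
#' @param records data.frame to write.
#' @param file CSV path.
#' @return \code{readPhenotypes}: validated data.frame.
#' @export
writePhenotypes <- function(records, file) {
  write.csv(records, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(file) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  tab <- validateSubjectTable(tab)
  for (f in c("cancer_record", "self_reported_disease", "operation_history"))
    tab[[f]] <- as.logical(tab[[f]])
  tab
}
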