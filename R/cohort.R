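# Phenotype handling: BMI, sex x BMI partitioning, healthy-subject filtering
# and median-phenotype reference selection.  Subject tables are plain
# data.frames with the columns documented in `validateSubjectTable`.

#' Body-mass index from weight and height
#'
#' BMI = weight / (height/100)^2 in kg/m^2; height is given in cm as in the
#' cohort tables.  Vectorised.
#'
#' @param weight kg, > 0.
#' @param height cm, > 0.
#' @return Numeric BMI; display convention is one decimal
#'   (\code{round(bmi, 1)}).
#' @examples
#' round(computeBMI(71.2, 163.0), 1)  # 26.8
#' @export
computeBMI <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  weight / (height / 100)^2
}

#' BMI category boundaries
#'
#' Normal weight is \code{[18.5, 25)}, overweight \code{[25, 30)}, obese
#' \code{>= 30} (half-open ranges; a BMI of exactly 30 is obese, following
#' the WHO convention).  BMIs below the inclusion floor are excluded.
#'
#' @param bmi numeric vector.
#' @param lowerBound inclusion floor (default 18.5).
#' @return Character vector in \code{c("normal", "overweight", "obese")};
#'   \code{NA} below the inclusion floor.
#' @export
bmiCategory <- function(bmi, lowerBound = 18.5) {
  out <- rep(NA_character_, length(bmi))
  out[bmi >= lowerBound & bmi < 25] <- "normal"
  out[bmi >= 25 & bmi < 30] <- "overweight"
  out[bmi >= 30] <- "obese"
  out
}

#' Assign a subject to one of the six sex x BMI groups
#'
#' @param sex \code{"female"} or \code{"male"} (vectorised).
#' @param bmi numeric BMI.
#' @param lowerBound BMI inclusion floor.
#' @param strict if TRUE (default) an out-of-range BMI is an error; if
#'   FALSE it yields \code{NA} with the exclusion reason in the
#'   \code{"excluded"} attribute.
#' @return Character vector like \code{"female-overweight"}.
#' @examples
#' assignGroup("female", 26.8)  # "female-overweight"
#' assignGroup("male", 33.6)    # "male-obese"
#' @export
assignGroup <- function(sex, bmi, lowerBound = 18.5, strict = TRUE) {
  if (length(sex) == 0L) return(character(0))
  sex <- match.arg(tolower(as.character(sex)), c("female", "male"),
                   several.ok = TRUE)
  cat_ <- bmiCategory(bmi, lowerBound)
  if (strict && anyNA(cat_))
    stop(sprintf("BMI below inclusion bound %.1f for %d subject(s)",
                 lowerBound, sum(is.na(cat_))), call. = FALSE)
  out <- ifelse(is.na(cat_), NA_character_, paste(sex, cat_, sep = "-"))
  if (anyNA(out))
    attr(out, "excluded") <- sprintf("BMI %.1f below inclusion bound %.1f",
                                     bmi[is.na(out)], lowerBound)
  out
}

#' The six canonical group names
#' @return Character vector of \code{sex-category} names.
#' @export
groupNames <- function() {
  as.vector(outer(c("female", "male"), c("normal", "overweight", "obese"),
                  paste, sep = "-"))
}

#' Validate a subject phenotype table
#'
#' Checks the documented schema: \code{subject_id}, \code{sex},
#' \code{age} (years), \code{weight} (kg), \code{height} (cm),
#' optional \code{bmi}, \code{body_fat} (percent) and the three health
#' flags \code{cancer_record}, \code{self_reported_disease},
#' \code{operation_history}.  A provided \code{bmi} must agree with
#' weight/height to 0.05; a missing one is derived.
#'
#' @param records data.frame.
#' @return The table with \code{bmi} filled in.
#' @export
validateSubjectTable <- function(records) {
  need <- c("subject_id", "sex", "age", "weight", "height", "body_fat",
            "cancer_record", "self_reported_disease", "operation_history")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(records$weight <= 0, na.rm = TRUE) ||
      any(records$height <= 0, na.rm = TRUE))
    stop("weight and height must be positive", call. = FALSE)
  if (any(records$body_fat < 0 | records$body_fat > 100, na.rm = TRUE))
    stop("body_fat must lie in [0, 100]", call. = FALSE)
  derived <- computeBMI(records$weight, records$height)
  if (!"bmi" %in% names(records)) {
    records$bmi <- derived
  } else {
    bad <- which(abs(records$bmi - derived) > 0.05)
    if (length(bad))
      stop(sprintf("bmi inconsistent with weight/height for subject(s): %s",
                   paste(records$subject_id[bad], collapse = ", ")),
           call. = FALSE)
  }
  records
}

#' Retain only healthy subjects
#'
#' Keeps records with no cancer record, no self-reported disease and no
#' operation history.  A missing (NA) flag is treated conservatively as
#' unknown health status and the record is excluded.  One message is emitted
#' per exclusion.
#'
#' @param records validated subject table.
#' @param quiet suppress per-exclusion messages.
#' @return The retained subset (idempotent).
#' @export
filterHealthy <- function(records, quiet = FALSE) {
  flags <- c("cancer_record", "self_reported_disease", "operation_history")
  miss <- setdiff(flags, names(records))
  if (length(miss))
    stop("health flags missing: ", paste(miss, collapse = ", "), call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  for (f in flags) {
    v <- records[[f]]
    unknown <- is.na(v)
    bad <- !unknown & as.logical(v)
    reason[keep & unknown] <- "unknown health status"
    reason[keep & bad] <- f
    keep <- keep & !unknown & !bad
  }
  if (!quiet) {
    for (i in which(!keep))
      message(sprintf("excluded subject %s: %s", records$subject_id[i],
                      reason[i]))
  }
  records[keep, , drop = FALSE]
}

#' Select the most representative reference subject of a group
#'
#' Computes the component-wise median of (age, weight, height, bmi,
#' body_fat) over the group, scales each component by its robust spread
#' (MAD; components with zero spread contribute their raw distance), and
#' returns the subject with the smallest Euclidean distance to the median
#' vector.  Ties break to the lowest subject id.  The chosen subject's
#' phenotypes are attached as the \code{"phenotypes"} attribute so the
#' selection can be reported and reviewed.
#'
#' @param records validated subject table (one group).
#' @return The selected \code{subject_id}.
#' @export
selectReference <- function(records) {
  if (nrow(records) == 0L) stop("empty group", call. = FALSE)
  records <- validateSubjectTable(records)
  vars <- c("age", "weight", "height", "bmi", "body_fat")
  X <- as.matrix(records[, vars])
  med <- apply(X, 2, median)
  scale_ <- apply(X, 2, mad)
  scale_[scale_ == 0] <- 1
  Z <- sweep(sweep(X, 2, med), 2, scale_, "/")
  d <- sqrt(rowSums(Z^2))
  ord <- order(d, as.character(records$subject_id))
  sel <- ord[1]
  id <- records$subject_id[sel]
  attr(id, "phenotypes") <- records[sel, c("subject_id", "sex", vars)]
  attr(id, "distance") <- d[sel]
  id
}

#' Partition a cohort into the six sex x BMI groups
#'
#' Applies the healthy filter, assigns groups, and returns a named list of
#' per-group tables; subjects below the BMI inclusion floor are dropped with
#' a logged reason.
#'
#' @param records subject table.
#' @param lowerBound BMI inclusion floor.
#' @param quiet suppress exclusion messages.
#' @return Named list of data.frames keyed by group name.
#' @export
partitionCohort <- function(records, lowerBound = 18.5, quiet = FALSE) {
  records <- validateSubjectTable(records)
  records <- filterHealthy(records, quiet = quiet)
  grp <- assignGroup(records$sex, records$bmi, lowerBound, strict = FALSE)
  if (!quiet) {
    for (i in which(is.na(grp)))
      message(sprintf("excluded subject %s: BMI %.1f below inclusion bound %.1f",
                      records$subject_id[i], records$bmi[i], lowerBound))
  }
  keep <- !is.na(grp)
  split(records[keep, , drop = FALSE], grp[keep])
}
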