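#' @include momics-package.R
NULL

MODALITIES <- c("transcriptomics", "proteomics", "metabolomics")

#' FeatureMatrix: one modality's subjects-by-features table
#'
#' A validated numeric matrix of normalized abundances for a single omics
#' modality. Rows are subjects, columns are features; dimnames carry the
#' identifiers. Values must be finite (missing entries are imputed at load
#' time by [readFeatureMatrix()]).
#'
#' @slot modality single string, one of `"transcriptomics"`, `"proteomics"`,
#'   `"metabolomics"`.
#' @slot values numeric matrix, subjects x features, with unique row and
#'   column names and no missing entries.
#'
#' @seealso [featureMatrix()], [readFeatureMatrix()], [assayValues()]
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(modality = "character", values = "matrix"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% MODALITIES)
    msg <- c(msg, sprintf("modality must be one of: %s",
                          paste(MODALITIES, collapse = ", ")))
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have subject rownames and feature colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate subject ids")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate feature ids")
  }
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "values contain missing or non-finite entries")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric subjects x features matrix with dimnames.
#' @param modality modality name.
#' @return A [FeatureMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("S", 1:3), c("F1", "F2")))
#' featureMatrix(m, "proteomics")
#' @export
featureMatrix <- function(values, modality) {
  new("FeatureMatrix", modality = modality, values = values)
}

#' @describeIn featureMatrix modality of a FeatureMatrix.
#' @param x a `FeatureMatrix`.
#' @export
modality <- function(x) x@modality

#' @describeIn featureMatrix subject identifiers (row order).
#' @export
subjectIDs <- function(x) rownames(x@values)

#' @describeIn featureMatrix feature identifiers (column order).
#' @export
featureIDs <- function(x) colnames(x@values)

#' @describeIn featureMatrix the numeric subjects x features matrix.
#' @export
assayValues <- function(x) x@values

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d subjects x %d features\n",
              object@modality, nrow(object@values), ncol(object@values)))
})

#' @describeIn featureMatrix number of subjects (rows).
#' @export
setMethod("nrow", "FeatureMatrix", function(x) nrow(x@values))

#' @describeIn featureMatrix number of features (columns).
#' @export
setMethod("ncol", "FeatureMatrix", function(x) ncol(x@values))

#' MultiOmicsDataset: aligned subject metadata plus per-modality matrices
#'
#' Container tying a subject table (cohort, gestational ages, outcome,
#' storage time, covariates) to one [FeatureMatrix-class] per modality, all
#' sharing the identical subject set and ordering. Build one with
#' [alignDataset()] or [generateDataset()].
#'
#' @slot subjects data.frame with one row per subject; required columns
#'   `subject_id`, `cohort`, `ga_sampling_weeks`, `ga_delivery_weeks`,
#'   `ptb`, `storage_days`.
#' @slot matrices named list of [FeatureMatrix-class] objects keyed by
#'   modality.
#'
#' @seealso [alignDataset()], [subjectTable()], [modalityMatrix()]
#' @exportClass MultiOmicsDataset
setClass("MultiOmicsDataset",
  representation(subjects = "data.frame", matrices = "list"))

setValidity("MultiOmicsDataset", function(object) {
  msg <- character()
  s <- object@subjects
  req <- c("subject_id", "cohort", "ga_sampling_weeks",
           "ga_delivery_weeks", "ptb", "storage_days")
  missing_cols <- setdiff(req, names(s))
  if (length(missing_cols))
    msg <- c(msg, sprintf("subject table lacks columns: %s",
                          paste(missing_cols, collapse = ", ")))
  if (length(object@matrices) < 1L)
    msg <- c(msg, "at least one modality matrix is required")
  if (!length(msg)) {
    if (anyDuplicated(s$subject_id)) msg <- c(msg, "duplicate subject ids")
    if (!identical(s$ptb, s$ga_delivery_weeks < 37))
      msg <- c(msg, "ptb flag inconsistent with ga_delivery_weeks < 37")
    if (any(s$ga_sampling_weeks >= s$ga_delivery_weeks))
      msg <- c(msg, "ga_sampling_weeks must precede ga_delivery_weeks")
    if (min(table(s$cohort)) < 2L)
      msg <- c(msg, "every cohort needs at least 2 subjects")
    for (m in object@matrices) {
      if (!is(m, "FeatureMatrix")) {
        msg <- c(msg, "matrices must be FeatureMatrix objects"); break
      }
      if (!identical(subjectIDs(m), as.character(s$subject_id))) {
        msg <- c(msg, sprintf(
          "matrix [%s] subjects differ from subject table", modality(m)))
      }
    }
    if (!identical(unname(vapply(object@matrices, modality, "")),
                   names(object@matrices)))
      msg <- c(msg, "matrix list names must equal their modalities")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn alignDataset subject metadata table.
#' @param x a `MultiOmicsDataset`.
#' @export
subjectTable <- function(x) x@subjects

#' @describeIn alignDataset modality names present in the dataset.
#' @export
modalities <- function(x) names(x@matrices)

#' @describeIn alignDataset the [FeatureMatrix-class] for one modality.
#' @param mod modality name.
#' @export
modalityMatrix <- function(x, mod) {
  if (!mod %in% names(x@matrices))
    stop(sprintf("modality '%s' not in dataset (has: %s)", mod,
                 paste(names(x@matrices), collapse = ", ")))
  x@matrices[[mod]]
}

#' @describeIn alignDataset number of subjects.
#' @export
nSubjects <- function(x) nrow(x@subjects)

setMethod("show", "MultiOmicsDataset", function(object) {
  s <- object@subjects
  cat(sprintf("MultiOmicsDataset: %d subjects (%d PTB / %d term), %d cohorts\n",
              nrow(s), sum(s$ptb), sum(!s$ptb),
              length(unique(s$cohort))))
  for (m in object@matrices)
    cat(sprintf("  %-15s %5d features\n", modality(m), ncol(m)))
})

#' PathwayCollection: named feature sets over a feature universe
#'
#' Pathway membership as read from a GMT file ([readGMT()]) or planted by
#' [generatePathways()]. Every member set is a non-empty subset of the
#' universe.
#'
#' @slot pathways named list of character vectors of feature ids.
#' @slot descriptions character vector parallel to `pathways`.
#' @slot universe character vector of all feature ids considered.
#'
#' @seealso [readGMT()], [enrichPathways()]
#' @exportClass PathwayCollection
setClass("PathwayCollection",
  representation(pathways = "list", descriptions = "character",
                 universe = "character"))

setValidity("PathwayCollection", function(object) {
  msg <- character()
  if (length(object@pathways) == 0L) msg <- c(msg, "no pathways")
  if (is.null(names(object@pathways)) || anyDuplicated(names(object@pathways)))
    msg <- c(msg, "pathways must have unique names")
  if (length(object@descriptions) != length(object@pathways))
    msg <- c(msg, "descriptions must parallel pathways")
  for (p in object@pathways) {
    if (length(p) == 0L) { msg <- c(msg, "empty pathway member set"); break }
    if (!all(p %in% object@universe)) {
      msg <- c(msg, "pathway members outside the universe"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn readGMT pathway identifiers.
#' @export
pathwayIDs <- function(x) names(x@pathways)

#' @describeIn readGMT member feature ids of one pathway.
#' @param id pathway identifier.
#' @export
pathwayMembers <- function(x, id) {
  if (!id %in% names(x@pathways)) stop(sprintf("unknown pathway '%s'", id))
  x@pathways[[id]]
}

#' @describeIn readGMT the feature universe.
#' @export
pathwayUniverse <- function(x) x@universe

setMethod("show", "PathwayCollection", function(object) {
  sizes <- lengths(object@pathways)
  cat(sprintf("PathwayCollection: %d pathways (sizes %d-%d) over %d features\n",
              length(sizes), min(sizes), max(sizes), length(object@universe)))
})

#' PredictionResult: out-of-fold predictions with performance summaries
#'
#' Returned by [predictGACV()] and [loocvPredict()]. Holds one out-of-fold
#' prediction per subject per model (each modality plus the integrated
#' model), a performance table, integration weights and, for classification,
#' the per-fold selected-feature lists.
#'
#' @slot task `"ga"` or `"ptb"`.
#' @slot predictions data.frame: `subject_id`, `truth`, then one column per
#'   model (modalities + `integrated`). For `"ptb"` the model columns are
#'   probabilities in `[0, 1]`.
#' @slot performance data.frame of per-model summaries (Spearman rho and
#'   p-values for `"ga"`; AUROC and bootstrap CI for `"ptb"`).
#' @slot weights numeric integration-layer weights (per modality).
#' @slot selectedFeatures list (per modality) of per-fold selected feature
#'   id vectors; empty for `"ga"`.
#'
#' @exportClass PredictionResult
setClass("PredictionResult",
  representation(task = "character", predictions = "data.frame",
                 performance = "data.frame", weights = "numeric",
                 selectedFeatures = "list"))

setValidity("PredictionResult", function(object) {
  msg <- character()
  if (!object@task %in% c("ga", "ptb")) msg <- c(msg, "task must be ga|ptb")
  p <- object@predictions
  if (!all(c("subject_id", "truth") %in% names(p)))
    msg <- c(msg, "predictions need subject_id and truth columns")
  if (anyDuplicated(p$subject_id))
    msg <- c(msg, "one prediction row per subject required")
  if (object@task == "ptb" && ncol(p) > 2L) {
    pr <- as.matrix(p[, setdiff(names(p), c("subject_id", "truth")), drop = FALSE])
    if (any(pr < -1e-9 | pr > 1 + 1e-9))
      msg <- c(msg, "probabilities must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn loocvPredict out-of-fold predictions, one row per subject.
#' @export
predictions <- function(x) x@predictions

#' @describeIn loocvPredict per-model performance table.
#' @export
performance <- function(x) x@performance

#' @describeIn loocvPredict integration-layer weights.
#' @export
integrationWeights <- function(x) x@weights

#' @describeIn loocvPredict per-fold selected feature lists (classification).
#' @export
selectedFeatures <- function(x) x@selectedFeatures

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult [%s]: %d subjects, models: %s\n",
              object@task, nrow(object@predictions),
              paste(setdiff(names(object@predictions),
                            c("subject_id", "truth")), collapse = ", ")))
  print(object@performance, row.names = FALSE, digits = 3)
})
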