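## Readers and writers for the package's plain-text interchange formats:
## TSV feature matrices, TSV subject tables, GMT pathway sets.

#' Read a feature matrix from TSV
#'
#' Reads a tab-separated subjects-by-features table whose header row holds
#' feature ids and whose first column (named `subject_id`) holds subject ids.
#' Empty cells are imputed with the per-feature (column) median computed on
#' the full matrix; the number of imputed cells is logged.
#'
#' @param path path to the TSV file.
#' @param modality one of `"transcriptomics"`, `"proteomics"`,
#'   `"metabolomics"`.
#' @return A [FeatureMatrix-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("S", 1:3), c("F1", "F2")))
#' writeFeatureMatrix(featureMatrix(m + 0, "proteomics"), tf)
#' readFeatureMatrix(tf, "proteomics")
#' @export
readFeatureMatrix <- function(path, modality) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("feature matrix needs subject_id plus >=1 feature")
  sid <- df[[1L]]
  if (anyDuplicated(sid))
    stop(sprintf("duplicate subject id(s): %s",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  fid <- colnames(df)[-1L]
  if (anyDuplicated(fid))
    stop(sprintf("duplicate feature id(s): %s",
                 paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  vals <- matrix(NA_real_, nrow(df), length(fid),
                 dimnames = list(sid, fid))
  for (j in seq_along(fid)) {
    raw <- df[[j + 1L]]
    empty <- is.na(raw) | !nzchar(trimws(raw))
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   raw[bad[1L]], sid[bad[1L]], fid[j]))
    vals[, j] <- num
  }
  n_missing <- sum(is.na(vals))
  if (n_missing > 0L) {
    for (j in which(colSums(is.na(vals)) > 0L)) {
      med <- median(vals[, j], na.rm = TRUE)
      if (is.na(med))
        stop(sprintf("column '%s' is entirely empty; cannot impute", fid[j]))
      vals[is.na(vals[, j]), j] <- med
    }
    .mlog("io", "imputed %d missing cell(s) in %s with column medians",
          n_missing, basename(path))
  }
  fm <- featureMatrix(vals, modality)
  attr(fm, "n_imputed") <- n_missing
  fm
}

#' Write a feature matrix to TSV
#'
#' Inverse of [readFeatureMatrix()]: round-tripping preserves ids exactly and
#' values to better than 1e-12 relative error.
#'
#' @param x a [FeatureMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(x, path) {
  df <- data.frame(subject_id = subjectIDs(x), check.names = FALSE)
  vals <- assayValues(x)
  for (j in seq_len(ncol(vals))) df[[featureIDs(x)[j]]] <- vals[, j]
  write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table from TSV
#'
#' Required columns: `subject_id`, `cohort`, `ga_sampling_weeks`,
#' `ga_delivery_weeks`, `storage_days`. The preterm flag is always derived as
#' `ga_delivery_weeks < 37` (delivery before completion of 37 weeks); a `ptb`
#' column in the file is ignored with a warning. Additional columns are kept
#' as covariates.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per subject and a logical `ptb` column.
#' @export
readSubjectTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "")
  req <- c("subject_id", "cohort", "ga_sampling_weeks",
           "ga_delivery_weeks", "storage_days")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("subject table lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if ("ptb" %in% names(df)) {
    warning("'ptb' column in file is ignored; the flag is recomputed from ga_delivery_weeks")
    df$ptb <- NULL
  }
  df$subject_id <- as.character(df$subject_id)
  df$cohort <- as.character(df$cohort)
  if (anyDuplicated(df$subject_id))
    stop(sprintf("duplicate subject id(s): %s",
                 paste(unique(df$subject_id[duplicated(df$subject_id)]),
                       collapse = ", ")))
  for (cc in c("ga_sampling_weeks", "ga_delivery_weeks", "storage_days"))
    df[[cc]] <- as.numeric(df[[cc]])
  bad <- which(df$ga_delivery_weeks <= df$ga_sampling_weeks)
  if (length(bad))
    stop(sprintf("ga_delivery_weeks <= ga_sampling_weeks for subject(s): %s",
                 paste(df$subject_id[bad], collapse = ", ")))
  if (any(df$storage_days < 0)) stop("storage_days must be non-negative")
  df$ptb <- df$ga_delivery_weeks < 37
  df
}

#' Align a subject table with feature matrices into a MultiOmicsDataset
#'
#' Takes the intersection of subject ids across the subject table and every
#' matrix, imposes the subject-table ordering everywhere and logs dropped
#' subjects.
#'
#' @param subjects subject data.frame as from [readSubjectTable()].
#' @param matrices list of [FeatureMatrix-class] objects (distinct
#'   modalities).
#' @return A [MultiOmicsDataset-class].
#' @export
alignDataset <- function(subjects, matrices) {
  if (is(matrices, "FeatureMatrix")) matrices <- list(matrices)
  if (length(matrices) < 1L) stop("at least one feature matrix required")
  mods <- vapply(matrices, modality, "")
  if (anyDuplicated(mods)) stop("duplicate modalities in matrix list")
  keep <- subjects$subject_id
  for (m in matrices) keep <- intersect(keep, subjectIDs(m))
  if (length(keep) == 0L) stop("empty subject intersection across inputs")
  dropped <- setdiff(union(subjects$subject_id,
                           unlist(lapply(matrices, subjectIDs))), keep)
  if (length(dropped))
    .mlog("io", "dropped %d unaligned subject(s): %s", length(dropped),
          paste(dropped, collapse = ", "))
  subjects <- subjects[match(keep, subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL
  matrices <- lapply(matrices, function(m)
    featureMatrix(assayValues(m)[keep, , drop = FALSE], modality(m)))
  names(matrices) <- mods
  out <- new("MultiOmicsDataset", subjects = subjects, matrices = matrices)
  attr(out, "dropped_subjects") <- dropped
  out
}

#' Read pathway membership from a GMT file
#'
#' Standard GMT: one pathway per line; tab-separated pathway id, description,
#' then member feature ids. The universe defaults to the union of all
#' members.
#'
#' @param path path to the GMT file.
#' @param universe optional character vector overriding the default
#'   universe; must contain every member.
#' @return A [PathwayCollection-class].
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file")
  pw <- list(); desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    id <- parts[1L]
    if (id %in% names(pw)) stop(sprintf("duplicate pathway id '%s'", id))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT line %d has no members", i))
    pw[[id]] <- members
    desc <- c(desc, parts[2L])
  }
  if (is.null(universe)) universe <- sort(unique(unlist(pw)))
  new("PathwayCollection", pathways = pw, descriptions = desc,
      universe = universe)
}

#' Write a PathwayCollection to GMT
#'
#' @param x a [PathwayCollection-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path) {
  lines <- vapply(seq_along(x@pathways), function(i)
    paste(c(names(x@pathways)[i], x@descriptions[i], x@pathways[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects the cross-validation and resampling settings shared by the
#' modelling functions. All randomized operations derive their random streams
#' from `seed`, so identical configurations give identical results.
#'
#' @param seed integer master seed.
#' @param outer_folds outer cross-validation folds for gestational-age
#'   estimation (the preterm classifier always uses leave-one-out).
#' @param inner_folds inner folds (>= 3) for penalty selection and for the
#'   within-training stacking layer.
#' @param k_top univariate feature-selection cap per modality.
#' @param n_perm permutations for permutation p-values.
#' @param n_boot bootstrap resamples for AUROC confidence intervals.
#' @param rf_trees trees per random forest.
#' @return list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(seed = 1L, outer_folds = 10L, inner_folds = 5L,
                           k_top = 50L, n_perm = 1000L, n_boot = 2000L,
                           rf_trees = 500L) {
  stopifnot(outer_folds >= 2L, inner_folds >= 3L, k_top >= 1L,
            n_perm >= 1L, n_boot >= 1L, rf_trees >= 1L)
  structure(list(seed = as.integer(seed), outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds), k_top = as.integer(k_top),
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 rf_trees = as.integer(rf_trees)),
            class = "AnalysisConfig")
}

#' Write a JSON run manifest next to an output file
#'
#' Records the configuration, seed and input checksums of a run so that any
#' written output can be traced back to the exact invocation.
#'
#' @param path output file the manifest describes; the manifest is written
#'   to `<path>.manifest.json`.
#' @param config an `AnalysisConfig` (or any list).
#' @param inputs named character vector of input file paths to checksum.
#' @return manifest path, invisibly.
#' @export
writeRunManifest <- function(path, config, inputs = character()) {
  sums <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_, "")
  manifest <- list(output = basename(path),
                   written = format(Sys.time(), tz = "UTC"),
                   config = unclass(config),
                   input_md5 = as.list(sums))
  mp <- paste0(path, ".manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
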