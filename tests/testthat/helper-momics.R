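## Shared fixture builders. Everything is generated in code at test time;
## no data files are stored.

## Small generated dataset: full structure, reduced dimensionality.
tinyDataset <- function(seed = 1, n = 30, n_cohorts = 3, ...) {
  generateDataset(generatorConfig(
    seed = seed, n_subjects = n, n_ptb = n %/% 2, n_cohorts = n_cohorts,
    dims = c(transcriptomics = 40L, proteomics = 25L, metabolomics = 30L),
    ga_n = c(transcriptomics = 8L, proteomics = 4L, metabolomics = 8L),
    ptb_n = c(transcriptomics = 8L, proteomics = 4L, metabolomics = 6L),
    ...))
}

## Hand-built dataset with fully controlled matrix values: `maker(n, p)`
## returns the value matrix for each modality.
manualDataset <- function(values_by_modality, cohort = NULL,
                          ga_delivery = NULL) {
  n <- nrow(values_by_modality[[1L]])
  sid <- sprintf("S%02d", seq_len(n))
  if (is.null(cohort)) cohort <- rep_len(c("A", "B"), n)
  if (is.null(ga_delivery))
    ga_delivery <- rep_len(c(34, 40), n)  # alternate preterm/term
  subjects <- data.frame(
    subject_id = sid, cohort = cohort,
    ga_sampling_weeks = rep(12, n), ga_delivery_weeks = ga_delivery,
    ptb = ga_delivery < 37, storage_days = seq(100, 900, length.out = n),
    stringsAsFactors = FALSE)
  mats <- lapply(names(values_by_modality), function(mod) {
    v <- values_by_modality[[mod]]
    dimnames(v) <- list(sid, sprintf("%s_F%02d", toupper(substr(mod, 1, 2)),
                                     seq_len(ncol(v))))
    featureMatrix(v, mod)
  })
  names(mats) <- names(values_by_modality)
  new("MultiOmicsDataset", subjects = subjects, matrices = mats)
}

## Fast analysis configuration for tests.
testConfig <- function(seed = 1, ...) {
  analysisConfig(seed = seed, n_perm = 19L, n_boot = 200L, rf_trees = 100L,
                 ...)
}

## Brute-force hypergeometric upper-tail oracle (independent of phyper).
hyperTailOracle <- function(k, K, N, m) {
  jmax <- min(K, m)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j)
    choose(K, j) * choose(N - K, m - j), 0)) / choose(N, m)
}

## All-pairs AUROC oracle.
aurocOracle <- function(scores, labels) {
  ca <- scores[as.logical(labels)]; co <- scores[!as.logical(labels)]
  tot <- 0
  for (a in ca) for (b in co) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ca) * length(co))
}
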