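## Gestational-age-at-sampling estimation: per-modality sparse linear models
## combined by a non-negative stacking layer, evaluated under two-layer
## cross-validation, plus the urine-metabolome surrogate model.

## Deterministic inner fold ids for cv.glmnet.
innerFoldId <- function(n, k, seed, strata = NULL)
  makeFolds(n, k, seed, strata = strata)

## NNLS stacking fit: y ~ intercept + w %*% preds with w >= 0.
nnlsStack <- function(Z, y) {
  Zc <- scale(Z, scale = FALSE)
  w <- pracma::lsqnonneg(Zc, y - mean(y))$x
  list(w = w, intercept = mean(y) - sum(w * colMeans(Z)))
}

#' Cross-validated estimation of gestational age at sampling
#'
#' Two-layer scheme. Outer 10-fold cross-validation over subjects; within
#' each outer training set, one L1-regularized (lasso) linear model per
#' modality with its penalty chosen by inner 5-fold cross-validation
#' predicts the held-out fold. The integration layer is a non-negative
#' least-squares combination of the per-modality estimates, itself fit only
#' on out-of-fold predictions generated inside the outer training set, so no
#' held-out subject's gestational age ever reaches any model that scores it.
#' Spearman correlations between out-of-fold estimates and truth are
#' reported raw and Bonferroni-adjusted across the four models (three
#' modalities plus integrated). Estimates are centred within each outer fold
#' (reported relative to the cohort mean) to remove fold-baseline artifacts
#' that would otherwise bias the null towards negative correlations.
#'
#' @param dataset a [MultiOmicsDataset-class] with `ga_sampling_weeks` for
#'   all subjects.
#' @param config an [analysisConfig()].
#' @param ga optional override of the gestational-age vector (used by
#'   permutation controls).
#' @return A [PredictionResult-class] with task `"ga"`; `performance` holds
#'   `rho`, `p_raw`, `p_bonferroni` per model and `integrationWeights()` the
#'   mean non-negative stacking weights.
#' @export
predictGACV <- function(dataset, config = analysisConfig(), ga = NULL) {
  s <- subjectTable(dataset)
  if (is.null(ga)) ga <- s$ga_sampling_weeks
  stopifnot(all(is.finite(ga)))
  n <- nSubjects(dataset)
  mods <- modalities(dataset)
  k <- config$outer_folds
  if (n < 2L * k) {
    k <- max(2L, n %/% 2L)
    warning(sprintf("too few subjects for %d outer folds; using %d",
                    config$outer_folds, k))
  }
  folds <- makeFolds(n, k, childSeed(config$seed, 101L))
  Xs <- lapply(mods, function(m) assayValues(modalityMatrix(dataset, m)))
  names(Xs) <- mods
  oof <- matrix(NA_real_, n, length(mods) + 1L,
                dimnames = list(s$subject_id, c(mods, "integrated")))
  wsum <- numeric(length(mods))
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    lambda_used <- numeric(length(mods))
    for (mi in seq_along(mods)) {
      X <- Xs[[mi]]
      fid <- innerFoldId(length(tr), config$inner_folds,
                         childSeed(config$seed, 200L + 10L * f + mi))
      cv <- suppressWarnings(
        glmnet::cv.glmnet(X[tr, , drop = FALSE], ga[tr], alpha = 1,
                          foldid = fid, nlambda = 60))
      lambda_used[mi] <- cv$lambda.min
      oof[te, mi] <- as.numeric(predict(cv, X[te, , drop = FALSE],
                                        s = "lambda.min"))
    }
    ## stacking layer: inner out-of-fold first-layer estimates on the
    ## training set only
    sfid <- innerFoldId(length(tr), config$inner_folds,
                        childSeed(config$seed, 300L + f))
    Z <- matrix(NA_real_, length(tr), length(mods))
    for (g in sort(unique(sfid))) {
      itr <- tr[sfid != g]; ite <- tr[sfid == g]
      for (mi in seq_along(mods)) {
        X <- Xs[[mi]]
        fit <- glmnet::glmnet(X[itr, , drop = FALSE], ga[itr], alpha = 1,
                              lambda = lambda_used[mi])
        Z[sfid == g, mi] <- as.numeric(predict(fit, X[ite, , drop = FALSE]))
      }
    }
    st <- nnlsStack(Z, ga[tr])
    oof[te, "integrated"] <- st$intercept +
      as.numeric(oof[te, seq_along(mods), drop = FALSE] %*% st$w)
    wsum <- wsum + st$w
  }
  ## Centre every model's estimates within each outer fold. Pooled
  ## out-of-fold predictions otherwise carry fold-specific baselines (each
  ## fold's model sees a slightly different training mean), which induces a
  ## spurious negative correlation with truth when no signal exists; the
  ## centred estimates are free of that artifact and Spearman performance
  ## under real signal is essentially unchanged. Estimates are therefore
  ## reported relative to the cohort mean rather than in absolute weeks.
  for (f in sort(unique(folds))) {
    te <- folds == f
    oof[te, ] <- sweep(oof[te, , drop = FALSE], 2L,
                       colMeans(oof[te, , drop = FALSE]))
  }
  weights <- setNames(wsum / length(unique(folds)), mods)
  perf <- do.call(rbind, lapply(colnames(oof), function(mn) {
    st <- spearmanTest(oof[, mn], ga)
    data.frame(model = mn, rho = st$rho, p_raw = st$p,
               p_bonferroni = min(1, st$p * ncol(oof)), row.names = NULL)
  }))
  preds <- data.frame(subject_id = s$subject_id, truth = ga,
                      as.data.frame(oof), row.names = NULL,
                      check.names = FALSE)
  new("PredictionResult", task = "ga", predictions = preds,
      performance = perf, weights = weights,
      selectedFeatures = list())
}

#' Urine-metabolome surrogate model for a plasma protein
#'
#' Random forest regression of a target measurement (for example the plasma
#' placental growth factor, PGF) on the urine metabolomics matrix under
#' 5-fold cross-validation. Reports the Spearman correlation between
#' out-of-fold predictions and truth with a permutation p-value in which the
#' full cross-validated fit is repeated on permuted targets.
#'
#' @param metabolome a [FeatureMatrix-class] (metabolomics) or matrix.
#' @param target finite numeric vector, one value per subject.
#' @param config an [analysisConfig()]; `n_perm` sizes the null.
#' @param folds cross-validation folds.
#' @return list with `oof` (out-of-fold predictions), `spearman_r`, `p`.
#' @export
surrogateModel <- function(metabolome, target, config = analysisConfig(),
                           folds = 5L) {
  X <- if (is(metabolome, "FeatureMatrix")) assayValues(metabolome)
       else metabolome
  stopifnot(length(target) == nrow(X))
  if (!all(is.finite(target))) stop("target must be finite for all subjects")
  if (sd(target) == 0) stop("constant target")
  cvfit <- function(y, seed) {
    fid <- makeFolds(nrow(X), folds, seed)
    rfCrossVal(X, y, fid, config$rf_trees, seed, classification = FALSE)
  }
  oof <- cvfit(target, childSeed(config$seed, 0L))
  r <- cor(oof, target, method = "spearman")
  null <- vapply(seq_len(config$n_perm), function(b) {
    set.seed(childSeed(config$seed, b))
    yp <- sample(target)
    cor(cvfit(yp, childSeed(config$seed, b)), yp, method = "spearman")
  }, 0)
  list(oof = setNames(oof, rownames(X)), spearman_r = r,
       p = permPValue(r, null))
}
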