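## Leave-one-out, cohort-adjusted, late-integrated preterm-birth
## classification, with its permutation null control, comparator strategies
## and clinical-covariate confounding screen.
##
## Cohort adjustment enters in three places: features are z-scored with
## per-cohort training statistics, univariate feature selection is
## restricted to the training subjects of the held-out subject's cohort,
## and the integration layer carries per-cohort intercepts.

#' Cohort-restricted univariate feature selection
#'
#' Ranks features by a Wilcoxon rank-sum test computed only on the training
#' subjects belonging to the held-out subject's cohort, and returns up to
#' `k_top` feature ids ordered by ascending p, ties broken by descending
#' absolute rank-biserial effect and then feature id. When that cohort lacks
#' two training members in either class the test falls back to the pooled
#' training set (logged).
#'
#' @param train a [FeatureMatrix-class] or subjects x features matrix of
#'   training data.
#' @param labels logical preterm labels of the training subjects.
#' @param cohorts cohort vector of the training subjects.
#' @param test_cohort cohort of the held-out subject.
#' @param k_top maximum number of features to return (>= 1).
#' @return character vector of selected feature ids; attribute `pooled`
#'   records whether the pooled fallback fired.
#' @export
cohortRestrictedFeatureSelection <- function(train, labels, cohorts,
                                             test_cohort, k_top = 50L) {
  if (k_top < 1L) stop("k_top must be >= 1")
  X <- if (is(train, "FeatureMatrix")) assayValues(train) else train
  labels <- as.logical(labels)
  idx <- which(cohorts == test_cohort)
  pooled <- FALSE
  if (sum(labels[idx]) < 2L || sum(!labels[idx]) < 2L) {
    pooled <- TRUE
    .mlog("ptb", "cohort %s lacks both classes (>=2 each); pooled selection",
          test_cohort)
    idx <- seq_along(labels)
  }
  scr <- rankSumScreen(X[idx, , drop = FALSE], labels[idx])
  ord <- order(scr$p, -abs(scr$effect), colnames(X))
  sel <- colnames(X)[ord][seq_len(min(k_top, ncol(X)))]
  attr(sel, "pooled") <- pooled
  sel
}

## Per-cohort (or global) z-scoring statistics from training rows, applied
## to arbitrary rows.
cohortZScore <- function(X, cohorts, train_idx, by_cohort = TRUE) {
  out <- X
  if (by_cohort) {
    for (co in unique(cohorts)) {
      tr <- intersect(train_idx, which(cohorts == co))
      all_co <- which(cohorts == co)
      if (length(tr) == 0L) tr <- train_idx  # unseen cohort: global stats
      st <- colStats(X[tr, , drop = FALSE])
      out[all_co, ] <- zscoreApply(X[all_co, , drop = FALSE], st$mean, st$sd)
    }
  } else {
    st <- colStats(X[train_idx, , drop = FALSE])
    out <- zscoreApply(X, st$mean, st$sd)
  }
  out
}

## Balanced class weights: each class contributes half the total weight,
## so leave-one-out training sets are not tilted against the held-out
## subject's class (the source of below-chance bias under null labels).
balancedWeights <- function(y) {
  y <- as.logical(y)
  w <- ifelse(y, 0.5 / mean(y), 0.5 / mean(!y))
  w / mean(w)
}

## Ridge-logistic fit/predict at a fixed lambda (glm fallback for a single
## feature), class-balanced.
ridgeLogistic <- function(Xtr, ytr, Xte, lambda) {
  wts <- balancedWeights(ytr)
  if (ncol(Xtr) >= 2L) {
    fit <- suppressWarnings(
      glmnet::glmnet(Xtr, factor(ytr), family = "binomial", alpha = 0,
                     lambda = lambda, weights = wts, standardize = FALSE))
    as.numeric(predict(fit, Xte, type = "response"))
  } else {
    df <- data.frame(y = ytr, x = Xtr[, 1L])
    fit <- suppressWarnings(glm(y ~ x, df, family = binomial(),
                                weights = wts))
    as.numeric(predict(fit, data.frame(x = Xte[, 1L]), type = "response"))
  }
}

## Penalty grid for the ridge-logistic learners.
RIDGE_LAMBDA <- 10^seq(1.5, -2.5, length.out = 12L)

## Inner-CV lambda selection (binomial deviance) on a fixed grid.
chooseRidgeLambda <- function(X, y, foldid) {
  if (ncol(X) < 2L) return(RIDGE_LAMBDA[1L])
  cv <- suppressWarnings(
    glmnet::cv.glmnet(X, factor(y), family = "binomial", alpha = 0,
                      lambda = RIDGE_LAMBDA, foldid = foldid,
                      weights = balancedWeights(y), standardize = FALSE))
  cv$lambda.min
}

#' Fit and apply the weighted integration layer
#'
#' Logistic model of the class labels on the per-modality probabilities with
#' modality weights constrained non-negative and one intercept per cohort
#' (the cohort adjustment of the integration layer). With
#' `per_cohort_intercepts = FALSE` a single intercept is used (plain
#' stacking). Degenerate inputs (all-constant probabilities) fall back to
#' equal weights, logged.
#'
#' @param per_modality_probs subjects x modalities matrix of probabilities
#'   in `[0, 1]`.
#' @param labels logical class labels.
#' @param cohorts cohort vector.
#' @param per_cohort_intercepts fit one intercept per cohort.
#' @return numeric vector of integrated probabilities for the training
#'   subjects, with attributes `weights` and `intercepts`; the attribute
#'   `model` holds a function `(newProbs, newCohorts) -> probabilities` for
#'   scoring new subjects.
#' @export
integratePredictions <- function(per_modality_probs, labels, cohorts,
                                 per_cohort_intercepts = TRUE) {
  P <- as.matrix(per_modality_probs)
  if (any(P < -1e-9 | P > 1 + 1e-9))
    stop("per-modality probabilities must lie in [0,1]")
  y <- as.numeric(as.logical(labels))
  cohorts <- as.character(cohorts)
  lev <- sort(unique(cohorts))
  if (!per_cohort_intercepts) lev <- "all"
  co_idx <- if (per_cohort_intercepts) match(cohorts, lev)
            else rep(1L, length(y))
  nm <- ncol(P)
  degenerate <- all(apply(P, 2L, sd) < 1e-10)
  if (degenerate) {
    .mlog("ptb", "degenerate integration inputs; equal-weight fallback")
    w <- rep(1 / nm, nm); a <- rep(0, length(lev))
  } else {
    wts <- balancedWeights(y)
    nll <- function(par) {
      w <- par[seq_len(nm)]; a <- par[nm + seq_along(lev)]
      eta <- as.numeric(P %*% w) + a[co_idx]
      -sum(wts * (y * eta - log1p(exp(eta)))) + 1e-4 * sum(par^2)
    }
    opt <- optim(c(rep(1, nm), rep(0, length(lev))), nll,
                 method = "L-BFGS-B",
                 lower = c(rep(0, nm), rep(-Inf, length(lev))))
    w <- opt$par[seq_len(nm)]; a <- opt$par[nm + seq_along(lev)]
  }
  model <- function(newP, newCohorts) {
    newP <- as.matrix(newP)
    ai <- if (per_cohort_intercepts) {
      i <- match(as.character(newCohorts), lev)
      ifelse(is.na(i), mean(a), a[i])
    } else rep(a[1L], nrow(newP))
    plogis(as.numeric(newP %*% w) + ai)
  }
  out <- model(P, if (per_cohort_intercepts) cohorts else rep("all", length(y)))
  attr(out, "weights") <- setNames(w, colnames(P))
  attr(out, "intercepts") <- setNames(a, lev)
  attr(out, "model") <- model
  out
}

## Leave-one-out engine shared by the full cohort-adjusted pipeline and the
## plain stacked-generalization comparator.
loocvEngine <- function(dataset, labels, config, cohort_adjusted = TRUE,
                        parts = c("zscore", "select", "intercept")) {
  if (!cohort_adjusted) parts <- character()
  use_z <- "zscore" %in% parts
  use_sel <- "select" %in% parts
  use_int <- "intercept" %in% parts
  s <- subjectTable(dataset)
  n <- nSubjects(dataset)
  mods <- modalities(dataset)
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  cohorts <- s$cohort
  Xs <- lapply(mods, function(m) assayValues(modalityMatrix(dataset, m)))
  names(Xs) <- mods
  oof <- matrix(NA_real_, n, length(mods) + 1L,
                dimnames = list(s$subject_id, c(mods, "integrated")))
  selected <- lapply(mods, function(m) vector("list", n))
  names(selected) <- mods
  wsum <- numeric(length(mods)); n_pooled <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    lambda_used <- numeric(length(mods))
    Xz_list <- vector("list", length(mods))
    psel_list <- vector("list", length(mods))
    for (mi in seq_along(mods)) {
      Xz <- cohortZScore(Xs[[mi]], cohorts, tr, by_cohort = use_z)
      Xz_list[[mi]] <- Xz
      scr <- rankSumScreen(Xz[tr, , drop = FALSE], y[tr])
      ord <- order(scr$p, -abs(scr$effect), colnames(Xz))
      psel <- colnames(Xz)[ord][seq_len(min(config$k_top, ncol(Xz)))]
      psel_list[[mi]] <- psel
      sel <- if (use_sel)
        cohortRestrictedFeatureSelection(Xz[tr, , drop = FALSE], y[tr],
                                         cohorts[tr], cohorts[i],
                                         config$k_top)
      else psel
      if (isTRUE(attr(sel, "pooled"))) n_pooled <- n_pooled + 1L
      selected[[mi]][[i]] <- as.character(sel)
      fid <- innerFoldId(length(tr), config$inner_folds,
                         childSeed(config$seed, 400L + 7L * i + mi),
                         strata = y[tr])
      lambda_used[mi] <- chooseRidgeLambda(Xz[tr, sel, drop = FALSE],
                                           y[tr], fid)
      oof[i, mi] <- ridgeLogistic(Xz[tr, sel, drop = FALSE], y[tr],
                                  Xz[i, sel, drop = FALSE],
                                  lambda_used[mi])
    }
    ## training-only stacking layer: inner out-of-fold probabilities.
    ## z-scoring stats and the pooled screen come from the full outer
    ## training set - labels of the inner test folds enter only the screen,
    ## never the held-out subject's models, so the outer subject stays blind.
    sfid <- innerFoldId(length(tr), config$inner_folds,
                        childSeed(config$seed, 500L + i), strata = y[tr])
    Z <- matrix(NA_real_, length(tr), length(mods))
    for (g in sort(unique(sfid))) {
      itr <- tr[sfid != g]; ite <- tr[sfid == g]
      for (mi in seq_along(mods)) {
        Xz <- Xz_list[[mi]]; isel <- psel_list[[mi]]
        Z[sfid == g, mi] <- ridgeLogistic(Xz[itr, isel, drop = FALSE],
                                          y[itr],
                                          Xz[ite, isel, drop = FALSE],
                                          lambda_used[mi])
      }
    }
    integ <- integratePredictions(Z, y[tr], cohorts[tr],
                                  per_cohort_intercepts = use_int)
    wsum <- wsum + attr(integ, "weights")
    oof[i, "integrated"] <-
      attr(integ, "model")(oof[i, seq_along(mods), drop = FALSE],
                           cohorts[i])
  }
  list(oof = oof, weights = setNames(wsum / n, mods), selected = selected,
       n_pooled = n_pooled, labels = y)
}

#' AUROC with a stratified bootstrap confidence interval
#'
#' AUROC is the scaled Mann-Whitney statistic
#' `P(score_case > score_control) + 0.5 P(equal)`. The 95 percent interval
#' resamples cases and controls separately (`config$n_boot` replicates,
#' percentile 2.5/97.5).
#'
#' @param scores numeric scores.
#' @param labels logical labels (both classes present).
#' @param config an [analysisConfig()].
#' @return list with `auroc`, `ci_low`, `ci_high`.
#' @examples
#' aurocWithCI(c(.1, .4, .35, .8), c(FALSE, FALSE, TRUE, TRUE),
#'             analysisConfig(n_boot = 200))
#' @export
aurocWithCI <- function(scores, labels, config = analysisConfig()) {
  labels <- as.logical(labels)
  auc <- aurocStat(scores, labels)
  ic <- which(labels); inc <- which(!labels)
  set.seed(childSeed(config$seed, 77L))
  boot <- vapply(seq_len(config$n_boot), function(b) {
    bi <- c(sample(ic, replace = TRUE), sample(inc, replace = TRUE))
    aurocStat(scores[bi], labels[bi])
  }, 0)
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  list(auroc = auc, ci_low = ci[1L], ci_high = ci[2L])
}

#' Leave-one-out cross-validated preterm-birth classification
#'
#' For each held-out subject and each modality: features are z-scored with
#' per-cohort training statistics, the feature space is limited to the top
#' `k_top` features of the held-out subject's cohort by univariate Wilcoxon
#' testing ([cohortRestrictedFeatureSelection()]), and an L2-regularized
#' logistic model (penalty by inner 5-fold cross-validation) produces the
#' held-out probability. A weighted integration layer with non-negative
#' modality weights and per-cohort intercepts ([integratePredictions()]),
#' fit only on out-of-fold probabilities generated inside the training set,
#' combines the modalities. Per-fold selected features are recorded and each
#' model's AUROC is reported with a stratified bootstrap CI.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @param config an [analysisConfig()].
#' @param labels optional logical label override (defaults to the subject
#'   table's `ptb` column; used by permutation controls and leak tests).
#' @return A [PredictionResult-class] with task `"ptb"`.
#' @export
loocvPredict <- function(dataset, config = analysisConfig(), labels = NULL) {
  s <- subjectTable(dataset)
  if (is.null(labels)) labels <- s$ptb
  eng <- loocvEngine(dataset, labels, config, cohort_adjusted = TRUE)
  buildPTBResult(dataset, eng, config)
}

buildPTBResult <- function(dataset, eng, config) {
  s <- subjectTable(dataset)
  perf <- do.call(rbind, lapply(colnames(eng$oof), function(mn) {
    a <- aurocWithCI(eng$oof[, mn], eng$labels, config)
    data.frame(model = mn, auroc = a$auroc, ci_low = a$ci_low,
               ci_high = a$ci_high, row.names = NULL)
  }))
  med <- vapply(eng$selected, function(lst)
    median(vapply(lst, length, 0L)), 0)
  perf$median_features <- c(med, NA_real_)
  preds <- data.frame(subject_id = s$subject_id, truth = eng$labels,
                      as.data.frame(eng$oof), row.names = NULL,
                      check.names = FALSE)
  res <- new("PredictionResult", task = "ptb", predictions = preds,
             performance = perf, weights = eng$weights,
             selectedFeatures = eng$selected)
  attr(res, "n_pooled_fallback") <- eng$n_pooled
  res
}

#' Random-label permutation control for the preterm pipeline
#'
#' Re-runs the full leave-one-out pipeline (selection, per-modality models,
#' integration) on class-size-preserving permutations of the preterm labels.
#' A sound pipeline centres at AUROC 0.5 here; systematic departure reveals
#' information leakage or overfitting.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @param n_reps number of label permutations (>= 1).
#' @param config an [analysisConfig()].
#' @return list with `auroc` (reps x models matrix), `mean` and `sd` per
#'   model.
#' @export
randomLabelControl <- function(dataset, n_reps = 20L,
                               config = analysisConfig()) {
  stopifnot(n_reps >= 1L)
  y <- subjectTable(dataset)$ptb
  mods <- c(modalities(dataset), "integrated")
  out <- matrix(NA_real_, n_reps, length(mods),
                dimnames = list(NULL, mods))
  for (r in seq_len(n_reps)) {
    set.seed(childSeed(config$seed, 9000L + r))
    yp <- sample(y)  # preserves the case/control split exactly
    cfg <- config; cfg$seed <- childSeed(config$seed, 9500L + r)
    eng <- loocvEngine(dataset, yp, cfg, cohort_adjusted = TRUE)
    out[r, ] <- vapply(mods, function(mn) aurocStat(eng$oof[, mn], yp), 0)
  }
  list(auroc = out, mean = colMeans(out), sd = apply(out, 2L, sd))
}

## Merged-features LOOCV baseline with a chosen learner.
loocvMerged <- function(dataset, labels, config,
                        learner = c("ridge", "lasso", "rf")) {
  learner <- match.arg(learner)
  s <- subjectTable(dataset)
  n <- nSubjects(dataset)
  y <- as.logical(labels)
  X <- do.call(cbind, lapply(modalities(dataset), function(m)
    assayValues(modalityMatrix(dataset, m))))
  oof <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Xz <- cohortZScore(X, s$cohort, tr, by_cohort = FALSE)
    scr <- rankSumScreen(Xz[tr, , drop = FALSE], y[tr])
    ord <- order(scr$p, -abs(scr$effect), colnames(Xz))
    sel <- colnames(Xz)[ord][seq_len(min(3L * config$k_top, ncol(Xz)))]
    Xtr <- Xz[tr, sel, drop = FALSE]; Xte <- Xz[i, sel, drop = FALSE]
    oof[i] <- switch(learner,
      ridge = {
        fid <- innerFoldId(length(tr), config$inner_folds,
                           childSeed(config$seed, 600L + i), strata = y[tr])
        ridgeLogistic(Xtr, y[tr], Xte, chooseRidgeLambda(Xtr, y[tr], fid))
      },
      lasso = {
        fid <- innerFoldId(length(tr), config$inner_folds,
                           childSeed(config$seed, 700L + i), strata = y[tr])
        cv <- suppressWarnings(
          glmnet::cv.glmnet(Xtr, factor(y[tr]), family = "binomial",
                            alpha = 1, foldid = fid, nlambda = 40,
                            weights = balancedWeights(y[tr]),
                            standardize = FALSE))
        as.numeric(predict(cv, Xte, s = "lambda.min", type = "response"))
      },
      rf = {
        df <- data.frame(y = factor(y[tr]), Xtr, check.names = FALSE)
        fit <- ranger::ranger(y ~ ., data = df, num.trees = config$rf_trees,
                              probability = TRUE,
                              case.weights = balancedWeights(y[tr]),
                              seed = childSeed(config$seed, 800L + i),
                              num.threads = 1L, verbose = FALSE)
        predict(fit, data.frame(Xte, check.names = FALSE),
                num.threads = 1L)$predictions[, "TRUE"]
      })
  }
  oof
}

#' Compare integration strategies under the same LOOCV protocol
#'
#' Runs, on identical leave-one-out splits: `merging` (one ridge-logistic
#' model on the concatenated standardized features), `lasso` and
#' `random_forest` single learners on the merged features, `stacked`
#' (per-modality models plus integration but without any cohort
#' conditioning), and `cohort_adjusted` (the full pipeline of
#' [loocvPredict()]). On data whose preterm signal is partly
#' cohort-specific, `cohort_adjusted` is expected to lead, `stacked` to beat
#' `merging`, and the gap between `cohort_adjusted` and `stacked` to vanish
#' when the signal is fully shared.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @param config an [analysisConfig()].
#' @param labels optional label override.
#' @return data.frame (`strategy`, `auroc`).
#' @export
baselineComparison <- function(dataset, config = analysisConfig(),
                               labels = NULL) {
  s <- subjectTable(dataset)
  if (is.null(labels)) labels <- s$ptb
  y <- as.logical(labels)
  strat <- list()
  strat$merging <- loocvMerged(dataset, y, config, "ridge")
  strat$lasso <- loocvMerged(dataset, y, config, "lasso")
  strat$random_forest <- loocvMerged(dataset, y, config, "rf")
  strat$stacked <- loocvEngine(dataset, y, config,
                               cohort_adjusted = FALSE)$oof[, "integrated"]
  strat$cohort_adjusted <- loocvEngine(dataset, y, config,
                                       cohort_adjusted = TRUE)$oof[, "integrated"]
  data.frame(strategy = names(strat),
             auroc = vapply(strat, function(sc) aurocStat(sc, y), 0),
             row.names = NULL)
}

#' Screen clinical covariates against the integrated preterm probability
#'
#' Spearman correlation of the integrated out-of-fold probability with every
#' numeric covariate; categorical covariates enter as one-vs-rest indicator
#' rows (point-biserial on ranks). P-values are Benjamini-Hochberg adjusted
#' across all rows. A model driven by outcome biology should correlate with
#' delivery age and birthweight and with nothing else.
#'
#' @param result a [PredictionResult-class] from [loocvPredict()].
#' @param subjects subject data.frame aligned with the result.
#' @return data.frame (`covariate`, `rho`, `p`, `p_adj`).
#' @export
covariateConfoundingScreen <- function(result, subjects) {
  stopifnot(result@task == "ptb")
  prob <- predictions(result)$integrated
  sid <- predictions(result)$subject_id
  subjects <- subjects[match(sid, subjects$subject_id), , drop = FALSE]
  skip <- c("subject_id", "ptb")
  cand <- setdiff(names(subjects), skip)
  if (length(cand) < 3L) stop("need at least 3 covariates")
  rows <- list()
  for (cv in cand) {
    v <- subjects[[cv]]
    if (is.numeric(v)) {
      if (sd(v) == 0) { .mlog("ptb", "skipping constant covariate %s", cv); next }
      st <- spearmanTest(prob, v)
      rows[[cv]] <- data.frame(covariate = cv, rho = st$rho, p = st$p)
    } else {
      for (lv in sort(unique(as.character(v)))) {
        ind <- as.numeric(v == lv)
        if (sd(ind) == 0) next
        st <- spearmanTest(prob, ind)
        key <- sprintf("%s=%s", cv, lv)
        rows[[key]] <- data.frame(covariate = key, rho = st$rho, p = st$p)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}
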