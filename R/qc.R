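## Structural quality control: modality complexity, cohort-signature and
## storage-time confound detection, and the global feature correlation
## network embedding.

#' Number of principal components capturing a variance fraction
#'
#' Features are standardized internally (zero-variance features dropped) and
#' the smallest number of principal components whose cumulative explained
#' variance reaches `variance_fraction` is returned. A modality with many
#' but internally correlated features (low effective rank) needs few
#' components despite its size.
#'
#' @param x a [FeatureMatrix-class] (or bare subjects x features matrix).
#' @param variance_fraction target cumulative explained-variance fraction.
#' @return integer component count.
#' @examples
#' m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("S", 1:8),
#'                                              paste0("F", 1:5)))
#' modalityComplexity(featureMatrix(m, "proteomics"))
#' @export
modalityComplexity <- function(x, variance_fraction = 0.9) {
  stopifnot(variance_fraction > 0, variance_fraction <= 1)
  X <- if (is(x, "FeatureMatrix")) assayValues(x) else x
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  X <- dropZeroVar(X)
  if (ncol(X) == 0L) stop("all features have zero variance")
  X <- scale(X)
  ev <- prcomp(X, center = FALSE, scale. = FALSE)$sdev^2
  ev <- ev[ev > 1e-12]
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= variance_fraction - 1e-12)[1L])
}

## Standardized concatenation of the requested modalities.
concatModalities <- function(dataset, use_modalities = NULL) {
  if (is.null(use_modalities)) use_modalities <- modalities(dataset)
  mats <- lapply(use_modalities, function(m) {
    X <- dropZeroVar(assayValues(modalityMatrix(dataset, m)))
    scale(X)
  })
  X <- do.call(cbind, mats)
  attr(X, "modality") <- rep(use_modalities,
                             vapply(mats, ncol, 0L))
  X
}

#' Unsupervised 2-D PCA embedding of the cohort
#'
#' First two principal-component scores of the standardized concatenation of
#' the requested modalities. The sign of each axis is fixed so that the
#' largest-magnitude loading is positive, making the embedding fully
#' deterministic.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @param use_modalities modalities to concatenate (default all).
#' @return data.frame with `subject_id`, `PC1`, `PC2`.
#' @export
pcaEmbedding <- function(dataset, use_modalities = NULL) {
  if (nSubjects(dataset) < 3L) stop("need at least 3 subjects")
  X <- concatModalities(dataset, use_modalities)
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = 2L)
  for (j in 1:2) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  data.frame(subject_id = subjectTable(dataset)$subject_id,
             PC1 = pc$x[, 1L], PC2 = pc$x[, 2L], row.names = NULL)
}

#' Supervised 2-D linear-discriminant embedding
#'
#' Linear discriminant analysis of the standardized concatenated features
#' against a class label (cohort by default). Because the feature count far
#' exceeds the subject count, the within-class scatter matrix is shrunk
#' toward a scaled identity, `(1 - gamma) * Sw + gamma * mean(diag(Sw)) * I`,
#' before inversion.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @param labels class vector (default the cohort column); needs >= 3
#'   classes for two discriminant axes, each class with >= 2 members.
#' @param gamma shrinkage weight in `[0, 1]`.
#' @param use_modalities modalities to concatenate (default all).
#' @return data.frame with `subject_id`, `LD1`, `LD2`.
#' @export
ldaEmbedding <- function(dataset, labels = NULL, gamma = 0.1,
                         use_modalities = NULL) {
  if (is.null(labels)) labels <- subjectTable(dataset)$cohort
  labels <- factor(labels)
  if (nlevels(labels) < 3L)
    stop("need at least 3 classes for a 2-D discriminant embedding")
  if (min(table(labels)) < 2L)
    stop("every class needs at least 2 subjects")
  X <- concatModalities(dataset, use_modalities)
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    Xi <- X[idx, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, mi)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + length(idx) * tcrossprod(mi - mu)
  }
  Sw <- Sw / n
  Sb <- Sb / n
  Swr <- (1 - gamma) * Sw + gamma * mean(diag(Sw)) * diag(p)
  M <- solve(Swr, Sb)
  ed <- eigen(M)
  W <- Re(ed$vectors[, 1:2, drop = FALSE])
  for (j in 1:2) if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  sc <- X %*% W
  data.frame(subject_id = subjectTable(dataset)$subject_id,
             LD1 = sc[, 1L], LD2 = sc[, 2L], row.names = NULL)
}

## Cross-validated random forest, returning out-of-fold predictions.
rfCrossVal <- function(X, y, folds, trees, seed, classification) {
  oof <- if (classification) character(length(y)) else numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    df <- data.frame(y = if (classification) factor(y[tr]) else y[tr],
                     X[tr, , drop = FALSE], check.names = FALSE)
    fit <- ranger::ranger(y ~ ., data = df, num.trees = trees,
                          seed = childSeed(seed, f), num.threads = 1L,
                          verbose = FALSE)
    pred <- predict(fit, data.frame(X[!tr, , drop = FALSE],
                                    check.names = FALSE),
                    num.threads = 1L)$predictions
    oof[!tr] <- if (classification) as.character(pred) else pred
  }
  oof
}

#' Cross-validated cohort predictability of a modality
#'
#' Quantifies cohort-specific signatures: a random forest is trained under
#' stratified 5-fold cross-validation to predict the cohort label from the
#' feature matrix alone, and the out-of-fold accuracy is compared with a
#' label-permutation null. The add-one permutation p-value is
#' `(1 + #{perm accuracy >= observed}) / (1 + n_perm)`.
#'
#' @param x a [FeatureMatrix-class] or matrix.
#' @param labels cohort vector.
#' @param config an [analysisConfig()]; `n_perm` controls the null size.
#' @param folds cross-validation folds (reduced with a warning when the
#'   smallest cohort is smaller).
#' @return list with `accuracy`, `p`, and the permutation null `null`.
#' @export
cohortPredictability <- function(x, labels, config = analysisConfig(),
                                 folds = 5L) {
  X <- if (is(x, "FeatureMatrix")) assayValues(x) else x
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 cohorts")
  minc <- min(table(labels))
  if (minc < folds) {
    warning(sprintf("smallest cohort has %d subjects; reducing folds to %d",
                    minc, minc))
    folds <- max(2L, minc)
  }
  cvacc <- function(lab, seed) {
    fid <- makeFolds(nrow(X), folds, seed, strata = lab)
    oof <- rfCrossVal(X, lab, fid, config$rf_trees, seed,
                      classification = TRUE)
    mean(oof == lab)
  }
  acc <- cvacc(labels, childSeed(config$seed, 0L))
  null <- vapply(seq_len(config$n_perm), function(b) {
    set.seed(childSeed(config$seed, b))
    cvacc(sample(labels), childSeed(config$seed, b))
  }, 0)
  list(accuracy = acc, p = permPValue(acc, null), null = null)
}

#' Cross-validated storage-time predictability of a modality
#'
#' Detects sample-degradation confounds: a random forest regression on the
#' feature matrix predicts storage time (days between collection and assay)
#' under 5-fold cross-validation; reported are the Spearman correlation
#' between out-of-fold predictions and truth and its label-permutation
#' p-value.
#'
#' @param x a [FeatureMatrix-class] or matrix.
#' @param storage_days non-negative numeric vector (>= 3 distinct values).
#' @param config an [analysisConfig()].
#' @param folds cross-validation folds.
#' @return list with `spearman_r`, `p`, and the permutation null `null`.
#' @export
storageTimePredictability <- function(x, storage_days,
                                      config = analysisConfig(), folds = 5L) {
  X <- if (is(x, "FeatureMatrix")) assayValues(x) else x
  if (length(unique(storage_days)) < 3L)
    stop("storage_days needs at least 3 distinct values")
  cvr <- function(y, seed) {
    fid <- makeFolds(nrow(X), folds, seed)
    oof <- rfCrossVal(X, y, fid, config$rf_trees, seed,
                      classification = FALSE)
    cor(oof, y, method = "spearman")
  }
  r <- cvr(storage_days, childSeed(config$seed, 0L))
  null <- vapply(seq_len(config$n_perm), function(b) {
    set.seed(childSeed(config$seed, b))
    cvr(sample(storage_days), childSeed(config$seed, b))
  }, 0)
  list(spearman_r = r, p = permPValue(r, null), null = null)
}

## Exact (quadratic-time) t-SNE on a precomputed distance matrix.
## Perplexity calibration by bisection on the Gaussian bandwidths; early
## exaggeration and momentum gradient descent as in the reference algorithm.
tsneExact <- function(D, perplexity = 30, max_iter = 1000L, seed = 1L,
                      learning_rate = NULL) {
  n <- nrow(D)
  perplexity <- min(perplexity, (n - 1) / 3)
  if (perplexity < 2) perplexity <- 2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { hi <- beta; beta <- (lo + beta) / 2; next }
      pj <- w / sw
      H <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + beta) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  if (is.null(learning_rate)) learning_rate <- max(50, n / 12)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  exag <- 12; stop_exag <- min(100L, max_iter %/% 4L)
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= stop_exag) P * exag else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - learning_rate * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Correlation-network embedding of all features
#'
#' Computes pairwise Spearman correlations `rho` between every pair of
#' features across all modalities, turns them into the distance
#' `1 - |rho|`, and lays the features out in 2-D with t-SNE. Correlated
#' feature groups - within or across modalities - land close together.
#' Deterministic given the seed.
#'
#' @param dataset a [MultiOmicsDataset-class] with >= 4 subjects.
#' @param config an [analysisConfig()] (supplies the seed).
#' @param perplexity t-SNE perplexity, capped at `(n_features - 1) / 3`.
#' @param max_iter gradient-descent iterations.
#' @return data.frame with `feature_id`, `modality`, `x`, `y`.
#' @export
correlationNetworkEmbedding <- function(dataset, config = analysisConfig(),
                                        perplexity = 30, max_iter = 1000L) {
  if (nSubjects(dataset) < 4L) stop("need at least 4 subjects")
  X <- do.call(cbind, lapply(modalities(dataset), function(m)
    dropZeroVar(assayValues(modalityMatrix(dataset, m)))))
  mods <- unlist(lapply(modalities(dataset), function(m)
    rep(m, ncol(dropZeroVar(assayValues(modalityMatrix(dataset, m)))))))
  if (ncol(X) < 10L) stop("need at least 10 non-constant features")
  rho <- cor(X, method = "spearman")
  D <- 1 - abs(rho)
  D[D < 0] <- 0
  Y <- tsneExact(D, perplexity = perplexity, max_iter = max_iter,
                 seed = config$seed)
  data.frame(feature_id = colnames(X), modality = mods,
             x = Y[, 1L], y = Y[, 2L], row.names = NULL)
}
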