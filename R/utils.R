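## Internal helpers: logging, seed derivation, folds, vectorised rank tests.

.mlog <- function(stage, fmt, ...) {
  if (isTRUE(getOption("momics.verbose", FALSE)))
    message(sprintf("[momics|%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}

## Deterministic stream of child seeds, kept inside 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + 7919 * k) %% 2147483647) + 1L
}

## Fold assignment; stratified by `strata` when given so every fold sees all
## classes. Deterministic given seed.
makeFolds <- function(n, k, seed, strata = NULL) {
  set.seed(seed)
  fold <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (lv in unique(strata)) {
    idx <- which(strata == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

## Column-wise ranks; radix sort on the tie-free fast path.
colRanks <- function(X) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    o <- sort.list(x, method = "radix")
    if (anyDuplicated(x)) out[, j] <- rank(x)
    else out[o, j] <- seq_len(n)
  }
  out
}

## Vectorised two-sample Wilcoxon rank-sum over matrix columns (normal
## approximation with tie correction; used for feature screening where only
## the ordering and effect direction matter). Returns p and the rank-biserial
## effect size r = 2*AUC - 1.
rankSumScreen <- function(X, grp) {
  grp <- as.logical(grp)
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  stopifnot(n1 > 0L, n2 > 0L, nrow(X) == n)
  R <- colRanks(X)
  r1 <- colSums(R[grp, , drop = FALSE])
  U <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ## tie correction, only for columns that actually have ties
  tiecor <- numeric(ncol(X))
  tied <- which(vapply(seq_len(ncol(X)),
                       function(j) anyDuplicated(X[, j]) > 0L, TRUE))
  for (j in tied) {
    t <- tabulate(match(X[, j], unique(X[, j])))
    tiecor[j] <- sum(t^3 - t)
  }
  sig2 <- n1 * n2 / 12 * ((n + 1) - tiecor / (n * (n - 1)))
  ## continuity-corrected normal approximation
  z <- ifelse(sig2 > 0, pmax(abs(U - mu) - 0.5, 0) / sqrt(sig2), 0)
  p <- pmin(1, 2 * pnorm(-z))
  p[sig2 <= 0] <- 1
  effect <- U / (n1 * n2) * 2 - 1
  list(p = p, effect = effect)
}

## AUROC as the scaled Mann-Whitney statistic:
## P(score_case > score_control) + 0.5 * P(equal).
aurocStat <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Spearman correlation with p-value: exact permutation below n = 10,
## large-sample t approximation otherwise.
spearmanTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(x, y, method = "spearman")
  if (n < 10L) {
    perms <- combinat_perms(n)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(cor(rx, ry))
    cnt <- sum(apply(perms, 2L, function(pr) abs(cor(rx[pr], ry)) >= obs - 1e-12))
    p <- cnt / ncol(perms)
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2 + 1e-300))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = min(1, p))
}

## All permutations of 1..n as a matrix (n <= 9 only; used for the exact
## Spearman branch).
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- combinat_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (i in seq_len(ncol(sub))) for (pos in seq_len(n)) {
    k <- k + 1L
    out[, k] <- append(sub[, i], n, after = pos - 1L)
  }
  out
}

## Add-one permutation p-value: p = (1 + #{null >= obs}) / (1 + n_perm).
permPValue <- function(observed, null_values) {
  (1 + sum(null_values >= observed - 1e-12)) / (1 + length(null_values))
}

## Fast per-column mean/sd (avoids apply-with-sd in hot loops).
colStats <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  s2 <- if (n > 1L) (colSums(X * X) - n * mu^2) / (n - 1L) else rep(0, ncol(X))
  list(mean = mu, sd = sqrt(pmax(s2, 0)))
}

## Column z-scoring with training-derived statistics; zero-sd columns get
## sd 1 so they map to 0 rather than NaN.
zscoreApply <- function(X, center, scale) {
  scale[scale <= 0 | !is.finite(scale)] <- 1
  sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
}

## Drop zero-variance columns, returning the reduced matrix; attribute
## "dropped" lists removed feature ids.
dropZeroVar <- function(X) {
  v <- apply(X, 2L, var)
  keep <- is.finite(v) & v > 0
  out <- X[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(X)[!keep]
  out
}

## Mean silhouette width of a labelling on 2-D coordinates.
silhouetteScore <- function(coords, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) return(NA_real_)
  s <- cluster::silhouette(labels, dist(coords))
  mean(s[, "sil_width"])
}
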