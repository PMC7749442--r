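## Univariate preterm feature statistics with cohort as a random effect,
## correlated-module detection, and hypergeometric pathway enrichment.

#' Mixed-effect test of a feature against preterm status
#'
#' Fits the linear mixed model `value ~ ptb + (1 | cohort)` by restricted
#' maximum likelihood and returns the preterm coefficient with its Wald
#' p-value. With `standardize = TRUE` (default) the values are scaled to
#' unit variance first, so the coefficient reads as a standardized mean
#' difference between preterm and term pregnancies. When the fitted cohort
#' variance collapses to zero (singular fit) the model is refit by ordinary
#' least squares and flagged.
#'
#' @param values numeric feature vector.
#' @param ptb logical preterm indicator.
#' @param cohorts cohort vector (>= 2 levels).
#' @param standardize divide values by their sd before fitting.
#' @return list with `coefficient`, `p`, and `singular` (logical flag for
#'   the OLS fallback).
#' @examples
#' set.seed(1)
#' co <- rep(c("A", "B"), each = 20)
#' pt <- rep(c(TRUE, FALSE), 20)
#' v <- rnorm(40) + 0.8 * pt + rnorm(2)[factor(co)]
#' mixedEffectFeatureTest(v, pt, co, standardize = FALSE)
#' @export
mixedEffectFeatureTest <- function(values, ptb, cohorts, standardize = TRUE) {
  ptb <- as.logical(ptb)
  if (length(unique(ptb)) < 2L) stop("both classes must be present")
  if (length(unique(cohorts)) < 2L) stop("need at least 2 cohorts")
  if (standardize) {
    s <- sd(values)
    if (s == 0) stop("constant feature")
    values <- values / s
  }
  df <- data.frame(y = values, ptb = ptb, cohort = factor(cohorts))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ ptb + (1 | cohort), data = df, REML = TRUE)))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    ols <- stats::lm(y ~ ptb, data = df)
    sm <- summary(ols)$coefficients
    return(list(coefficient = unname(sm["ptbTRUE", "Estimate"]),
                p = unname(sm["ptbTRUE", "Pr(>|t|)"]), singular = TRUE))
  }
  sm <- summary(fit)$coefficients
  z <- sm["ptbTRUE", "t value"]
  list(coefficient = unname(sm["ptbTRUE", "Estimate"]),
       p = 2 * pnorm(-abs(z)), singular = FALSE)
}

#' Two-sided Wilcoxon rank-sum test of a feature against preterm status
#'
#' Exact enumeration when the smaller class has at most 8 members and there
#' are no ties; normal approximation with tie correction otherwise.
#'
#' @param values numeric feature vector.
#' @param ptb logical preterm indicator (both classes non-empty).
#' @return two-sided p-value.
#' @examples
#' wilcoxonFeatureTest(c(1, 2, 3, 4, 5, 6), c(rep(FALSE, 3), rep(TRUE, 3)))
#' @export
wilcoxonFeatureTest <- function(values, ptb) {
  ptb <- as.logical(ptb)
  n1 <- sum(ptb); n0 <- sum(!ptb)
  if (n1 < 1L || n0 < 1L) stop("both classes must be present")
  ties <- anyDuplicated(values) > 0L
  use_exact <- min(n1, n0) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(values[ptb], values[!ptb], exact = use_exact,
                correct = !use_exact, alternative = "two.sided"))
  min(1, wt$p.value)
}

#' Rank all features by cohort-adjusted preterm association
#'
#' Runs [mixedEffectFeatureTest()] and [wilcoxonFeatureTest()] on every
#' feature of every modality, adjusts each test with Benjamini-Hochberg
#' within its modality, and sorts by mixed-model p ascending (ties broken by
#' feature id). Constant features are skipped and logged.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @return data.frame (`feature_id`, `modality`, `coefficient`, `p_mixed`,
#'   `p_mixed_adj`, `p_wilcoxon`, `p_wilcoxon_adj`, `singular`).
#' @export
rankPTBFeatures <- function(dataset) {
  s <- subjectTable(dataset)
  out <- lapply(modalities(dataset), function(mod) {
    X <- assayValues(modalityMatrix(dataset, mod))
    keep <- apply(X, 2L, sd) > 0
    if (any(!keep))
      .mlog("feature_stats", "skipping %d constant feature(s) in %s",
            sum(!keep), mod)
    X <- X[, keep, drop = FALSE]
    res <- lapply(seq_len(ncol(X)), function(j)
      mixedEffectFeatureTest(X[, j], s$ptb, s$cohort))
    pw <- vapply(seq_len(ncol(X)), function(j)
      wilcoxonFeatureTest(X[, j], s$ptb), 0)
    data.frame(feature_id = colnames(X), modality = mod,
               coefficient = vapply(res, `[[`, 0, "coefficient"),
               p_mixed = vapply(res, `[[`, 0, "p"),
               p_mixed_adj = p.adjust(vapply(res, `[[`, 0, "p"), "BH"),
               p_wilcoxon = pw, p_wilcoxon_adj = p.adjust(pw, "BH"),
               singular = vapply(res, `[[`, TRUE, "singular"),
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  out[order(out$p_mixed, out$feature_id), , drop = FALSE]
}

#' Rank all features by Spearman correlation with gestational age
#'
#' Per-feature Spearman correlation with gestational age at sampling; the
#' significance flag marks `p < 0.05`. Sorted by `|rho|` descending, ties by
#' feature id. Constant features are excluded and logged.
#'
#' @param dataset a [MultiOmicsDataset-class] with >= 5 subjects.
#' @return data.frame (`feature_id`, `modality`, `rho`, `p`, `significant`).
#' @export
rankGAFeatures <- function(dataset) {
  if (nSubjects(dataset) < 5L) stop("need at least 5 subjects")
  ga <- subjectTable(dataset)$ga_sampling_weeks
  out <- lapply(modalities(dataset), function(mod) {
    X <- assayValues(modalityMatrix(dataset, mod))
    keep <- apply(X, 2L, sd) > 0
    if (any(!keep))
      .mlog("chronicity", "excluding %d constant feature(s) in %s",
            sum(!keep), mod)
    X <- X[, keep, drop = FALSE]
    st <- lapply(seq_len(ncol(X)), function(j) spearmanTest(X[, j], ga))
    data.frame(feature_id = colnames(X), modality = mod,
               rho = vapply(st, `[[`, 0, "rho"),
               p = vapply(st, `[[`, 0, "p"), row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p < 0.05
  out[order(-abs(out$rho), out$feature_id), , drop = FALSE]
}

#' Detect correlated feature modules among top features
#'
#' Builds a graph on `top_features` with an edge wherever the absolute
#' Spearman correlation between two features reaches `corr_threshold`;
#' modules are connected components with at least 3 members. Smaller
#' components stay unassigned.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @param top_features character vector of feature ids (>= 2), from any
#'   modality.
#' @param corr_threshold absolute-correlation edge threshold.
#' @return named character vector mapping feature id to module id
#'   (`"M1"`, `"M2"`, ...; `NA` for unassigned features). Module ids are
#'   numbered by decreasing module size.
#' @export
detectModules <- function(dataset, top_features, corr_threshold = 0.6) {
  if (length(top_features) < 2L) stop("need at least 2 features")
  cols <- lapply(modalities(dataset), function(mod) {
    X <- assayValues(modalityMatrix(dataset, mod))
    X[, intersect(top_features, colnames(X)), drop = FALSE]
  })
  X <- do.call(cbind, cols)
  missing_f <- setdiff(top_features, colnames(X))
  if (length(missing_f))
    stop(sprintf("unknown feature id(s): %s",
                 paste(head(missing_f, 5L), collapse = ", ")))
  X <- X[, top_features, drop = FALSE]
  rho <- cor(X, method = "spearman")
  adj <- abs(rho) >= corr_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep <- which(sizes >= 3L)
  keep <- keep[order(-sizes[keep])]
  module <- setNames(rep(NA_character_, length(top_features)), top_features)
  for (i in seq_along(keep))
    module[comp$membership == keep[i]] <- sprintf("M%d", i)
  module
}

#' Hypergeometric pathway over-representation test
#'
#' One-sided Fisher exact test per pathway: with universe size `N`, pathway
#' size `K`, module size `m` and overlap `k`, the p-value is the upper
#' hypergeometric tail `P(X >= k)`. Results are sorted by p ascending.
#'
#' @param module_features character set of feature ids (non-empty, subset of
#'   the universe).
#' @param pathways a [PathwayCollection-class].
#' @return data.frame (`pathway_id`, `description`, `overlap`, `module_size`,
#'   `pathway_size`, `universe_size`, `p`).
#' @examples
#' pw <- new("PathwayCollection",
#'           pathways = list(P1 = sprintf("F%d", 1:5)),
#'           descriptions = "toy", universe = sprintf("F%d", 1:20))
#' enrichPathways(sprintf("F%d", c(1:4, 10, 11)), pw)
#' @export
enrichPathways <- function(module_features, pathways) {
  module_features <- unique(as.character(module_features))
  if (length(module_features) == 0L) stop("empty module")
  universe <- pathwayUniverse(pathways)
  if (!all(module_features %in% universe))
    stop("module features must lie within the pathway universe")
  N <- length(universe); m <- length(module_features)
  res <- lapply(seq_along(pathways@pathways), function(i) {
    members <- pathways@pathways[[i]]
    K <- length(members)
    k <- length(intersect(module_features, members))
    p <- phyper(k - 1L, K, N - K, m, lower.tail = FALSE)
    data.frame(pathway_id = names(pathways@pathways)[i],
               description = pathways@descriptions[i],
               overlap = k, module_size = m, pathway_size = K,
               universe_size = N, p = min(1, p), row.names = NULL)
  })
  out <- do.call(rbind, res)
  out[order(out$p, out$pathway_id), , drop = FALSE]
}
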