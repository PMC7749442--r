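test_that("cohort-restricted selection ranks separating features first", {
  set.seed(51)
  n <- 24
  cohorts <- rep(c("A", "B"), each = 12)
  labels <- rep(c(TRUE, FALSE), 12)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("S%d", 1:n), sprintf("F%02d", 1:10)))
  ## F03 perfectly separates the classes inside cohort A only
  X[cohorts == "A", 3] <- ifelse(labels[cohorts == "A"], 5, -5) +
    rnorm(12, 0, 0.1)
  sel <- cohortRestrictedFeatureSelection(X, labels, cohorts, "A",
                                          k_top = 5L)
  expect_identical(sel[1], "F03")
  expect_false(isTRUE(attr(sel, "pooled")))

  one <- cohortRestrictedFeatureSelection(X, labels, cohorts, "A",
                                          k_top = 1L)
  expect_length(one, 1L)
  expect_error(cohortRestrictedFeatureSelection(X, labels, cohorts, "A",
                                                k_top = 0L), "k_top")

  ## identical features tie on p and effect; the id tie-break is stable
  X2 <- X; X2[, 5] <- X2[, 4]
  s1 <- cohortRestrictedFeatureSelection(X2, labels, cohorts, "B", 10L)
  s2 <- cohortRestrictedFeatureSelection(X2, labels, cohorts, "B", 10L)
  expect_identical(s1, s2)
  expect_lt(which(s1 == "F04"), which(s1 == "F05"))

  ## a cohort lacking both classes falls back to pooled selection
  labs1 <- labels; labs1[cohorts == "A"] <- TRUE
  selp <- cohortRestrictedFeatureSelection(X, labs1, cohorts, "A", 5L)
  expect_true(attr(selp, "pooled"))
})

test_that("AUROC equals the all-pairs Mann-Whitney enumeration", {
  cfg <- testConfig(seed = 52)
  a <- aurocWithCI(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE), cfg)
  expect_equal(a$auroc, 0.75)        # 3 of 4 case-control pairs concordant
  expect_equal(aurocWithCI(c(1, 2, 3, 10, 11), c(F, F, F, T, T), cfg)$auroc, 1)
  expect_equal(aurocWithCI(rep(0.5, 6), rep(c(TRUE, FALSE), 3), cfg)$auroc,
               0.5)
  set.seed(52)
  for (r in 1:15) {
    n <- sample(6:30, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # ties likely
    lb <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    expect_equal(momics:::aurocStat(sc, lb), aurocOracle(sc, lb))
  }
  expect_error(aurocWithCI(1:4, rep(TRUE, 4), cfg), "both classes")
})

test_that("bootstrap CI brackets the point estimate and narrows with n", {
  cfg <- testConfig(seed = 53)
  mk <- function(n, seed) {
    set.seed(seed)
    lb <- rep(c(TRUE, FALSE), n / 2)
    sc <- rnorm(n) + lb
    aurocWithCI(sc, lb, cfg)
  }
  small <- mk(40, 1); big <- mk(160, 1)
  for (a in list(small, big)) {
    expect_lte(a$ci_low, a$auroc)
    expect_gte(a$ci_high, a$auroc)
  }
  expect_lt(big$ci_high - big$ci_low, small$ci_high - small$ci_low)
})

test_that("integration layer weights an oracle modality and stays non-negative", {
  set.seed(54)
  n <- 40
  labels <- rep(c(TRUE, FALSE), n / 2)
  cohorts <- rep_len(c("A", "B"), n)
  P <- cbind(oracle = as.numeric(labels),
             junk1 = runif(n), junk2 = runif(n))
  out <- integratePredictions(P, labels, cohorts)
  w <- attr(out, "weights")
  expect_true(all(w >= 0))
  expect_gt(w["oracle"], max(w["junk1"], w["junk2"]))
  expect_equal(momics:::aurocStat(out, labels), 1)

  ## identical informative modalities: output is a monotone recalibration
  p_base <- plogis(2 * (as.numeric(labels) - 0.5) + rnorm(n))
  P2 <- cbind(a = p_base, b = p_base, c = p_base)
  out2 <- integratePredictions(P2, labels, cohorts,
                               per_cohort_intercepts = FALSE)
  expect_equal(order(as.numeric(out2)), order(p_base))

  ## constant inputs trigger the logged equal-weight fallback
  P3 <- matrix(0.5, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  out3 <- integratePredictions(P3, labels, cohorts)
  expect_equal(unname(attr(out3, "weights")), rep(1 / 3, 3))
  expect_error(integratePredictions(P3 + 2, labels, cohorts), "\\[0,1\\]")
})

test_that("loocvPredict emits one out-of-fold probability per subject", {
  ## minimal 8-subject dataset, two cohorts with both classes each
  set.seed(55)
  vals <- list(transcriptomics = matrix(rnorm(8 * 6), 8, 6),
               proteomics = matrix(rnorm(8 * 5), 8, 5))
  d <- manualDataset(vals, cohort = rep(c("A", "B"), each = 4),
                     ga_delivery = rep(c(34, 35, 40, 41), 2))
  cfg <- testConfig(seed = 55, k_top = 3L, inner_folds = 3L)
  res <- loocvPredict(d, cfg)
  pr <- predictions(res)
  expect_identical(nrow(pr), 8L)
  expect_identical(anyDuplicated(pr$subject_id), 0L)
  pm <- as.matrix(pr[, c("transcriptomics", "proteomics", "integrated")])
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(all(vapply(selectedFeatures(res)$transcriptomics,
                         length, 0L) <= 3L))
  expect_true(all(performance(res)$median_features[1:2] <= 3))
})

test_that("a held-out subject's label never reaches its own prediction", {
  sim <- tinyDataset(seed = 56, n = 20, n_cohorts = 2)
  d <- sim$dataset
  cfg <- testConfig(seed = 56, k_top = 10L, inner_folds = 3L)
  y <- subjectTable(d)$ptb
  base <- predictions(loocvPredict(d, cfg, labels = y))
  for (i in c(2L, 11L)) {
    y_mut <- y
    y_mut[i] <- !y_mut[i]
    mut <- predictions(loocvPredict(d, cfg, labels = y_mut))
    for (mn in c("transcriptomics", "proteomics", "metabolomics",
                 "integrated"))
      expect_identical(base[[mn]][i], mut[[mn]][i])
  }
})

test_that("covariate screen finds planted dependencies and respects nulls", {
  sim <- tinyDataset(seed = 57, n = 40, n_cohorts = 4)
  d <- sim$dataset
  cfg <- testConfig(seed = 57, k_top = 10L)
  res <- loocvPredict(d, cfg)
  s <- subjectTable(d)
  set.seed(57)
  s$noise_cov <- rnorm(nrow(s))
  s$self <- predictions(res)$integrated
  scr <- covariateConfoundingScreen(res, s)
  expect_equal(scr$rho[scr$covariate == "self"], 1)
  expect_gt(scr$p_adj[scr$covariate == "noise_cov"], 0.05)
  expect_true(all(scr$p_adj >= scr$p - 1e-12))
  ## constant covariates are silently dropped
  s$const <- 1
  scr2 <- covariateConfoundingScreen(res, s)
  expect_false("const" %in% scr2$covariate)
})

test_that("baselineComparison runs every strategy on shared splits", {
  sim <- tinyDataset(seed = 58, n = 20, n_cohorts = 2)
  cfg <- testConfig(seed = 58, k_top = 6L, inner_folds = 3L)
  cfg$rf_trees <- 60L
  tab <- baselineComparison(sim$dataset, cfg)
  expect_setequal(tab$strategy,
                  c("merging", "lasso", "random_forest", "stacked",
                    "cohort_adjusted"))
  expect_true(all(tab$auroc >= 0 & tab$auroc <= 1))
  ## deterministic given the seed
  expect_identical(tab, baselineComparison(sim$dataset, cfg))
})
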