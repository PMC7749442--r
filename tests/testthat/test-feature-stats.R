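test_that("wilcoxon test: exact branch, degenerate and tie behaviour", {
  ## {1,2,3} vs {4,5,6}: the two most extreme of the C(6,3)=20 equally
  ## likely rank assignments give two-sided p = 2/20 = 0.1 exactly
  expect_equal(wilcoxonFeatureTest(c(4, 5, 6, 1, 2, 3),
                                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               0.1)
  ## identical groups carry no evidence
  expect_equal(wilcoxonFeatureTest(rep(c(1, 2), 4),
                                   rep(c(TRUE, FALSE), each = 4)), 1)
  expect_error(wilcoxonFeatureTest(1:4, rep(TRUE, 4)), "both classes")
})

test_that("wilcoxon exact and normal-approximation branches agree at n=8+8", {
  set.seed(31)
  for (r in 1:20) {
    v <- rnorm(16)
    g <- rep(c(TRUE, FALSE), each = 8)
    p_exact <- wilcoxonFeatureTest(v, g)          # min class = 8 -> exact
    p_approx <- momics:::rankSumScreen(matrix(v, 16, 1), g)$p
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("mixed-effect test reduces to OLS without cohort variance", {
  set.seed(5)
  n <- 60
  ptb <- rep(c(TRUE, FALSE), n / 2)
  cohorts <- rep_len(c("A", "B", "C"), n)
  v <- rnorm(n) + 0.9 * ptb          # no cohort effect at all
  res <- mixedEffectFeatureTest(v, ptb, cohorts, standardize = FALSE)
  ols <- coef(summary(lm(v ~ ptb)))["ptbTRUE", "Estimate"]
  expect_true(res$singular)
  expect_equal(res$coefficient, unname(ols), tolerance = 1e-6)
})

test_that("mixed-effect test recovers a planted effect with cohort intercepts", {
  set.seed(6)
  reps <- vapply(1:20, function(r) {
    n <- 200
    cohorts <- rep_len(sprintf("C%d", 1:5), n)
    ptb <- rep(c(TRUE, FALSE), n / 2)
    v <- rnorm(5)[factor(cohorts)] + 0.8 * ptb + rnorm(n)
    mixedEffectFeatureTest(v, ptb, cohorts,
                           standardize = FALSE)$coefficient
  }, 0)
  expect_lt(abs(mean(reps) - 0.8), 0.15)
})

test_that("standardized coefficients are scaled raw coefficients", {
  set.seed(8)
  n <- 80
  cohorts <- rep_len(c("A", "B"), n)
  ptb <- rep(c(TRUE, FALSE), n / 2)
  v <- rnorm(2)[factor(cohorts)] + 0.5 * ptb + rnorm(n)
  raw <- mixedEffectFeatureTest(v, ptb, cohorts, standardize = FALSE)
  std <- mixedEffectFeatureTest(v, ptb, cohorts, standardize = TRUE)
  expect_equal(std$coefficient, raw$coefficient / sd(v), tolerance = 1e-8)
  expect_equal(std$p, raw$p, tolerance = 1e-8)
})

test_that("mixed-model p-values are uniform when no effect exists", {
  set.seed(99)
  ps <- vapply(1:200, function(r) {
    n <- 120
    cohorts <- rep_len(sprintf("C%d", 1:5), n)
    ptb <- rep(c(TRUE, FALSE), n / 2)
    v <- rnorm(5)[factor(cohorts)] + rnorm(n)   # cohort effects, no ptb
    mixedEffectFeatureTest(v, ptb, cohorts)$p
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.05)
})

test_that("hypergeometric enrichment matches brute-force tail enumeration", {
  pw <- new("PathwayCollection",
            pathways = list(P1 = sprintf("G%02d", 1:5)),
            descriptions = "toy", universe = sprintf("G%02d", 1:20))
  res <- enrichPathways(sprintf("G%02d", c(1:4, 10, 11)), pw)
  expect_equal(res$p, 540 / 38760, tolerance = 1e-12)   # N=20,K=5,m=6,k=4
  expect_identical(res$overlap, 4L)

  ## randomized cross-check against independent enumeration, N <= 60
  set.seed(9)
  for (r in 1:25) {
    N <- sample(10:60, 1)
    K <- sample(2:(N - 2), 1)
    m <- sample(2:(N - 2), 1)
    uni <- sprintf("U%03d", 1:N)
    members <- sample(uni, K)
    mod <- sample(uni, m)
    pc <- new("PathwayCollection", pathways = list(P = members),
              descriptions = "r", universe = uni)
    p_pkg <- enrichPathways(mod, pc)$p
    k <- length(intersect(mod, members))
    expect_equal(p_pkg, hyperTailOracle(k, K, N, m), tolerance = 1e-12)
  }

  ## zero overlap spans the whole distribution
  res0 <- enrichPathways(sprintf("G%02d", 6:9), pw)
  expect_equal(res0$p[res0$overlap == 0], 1)
  ## module = pathway = universe is deterministic overlap
  pcu <- new("PathwayCollection", pathways = list(P = sprintf("G%02d", 1:20)),
             descriptions = "all", universe = sprintf("G%02d", 1:20))
  expect_equal(enrichPathways(sprintf("G%02d", 1:20), pcu)$p, 1)
  expect_error(enrichPathways(character(), pw), "empty")
})

test_that("detectModules finds planted correlated blocks", {
  set.seed(12)
  n <- 40
  base1 <- rnorm(n); base2 <- rnorm(n)
  tx <- sapply(1:4, function(i) base1 + rnorm(n, 0, 0.2))
  me <- sapply(1:4, function(i) base2 + rnorm(n, 0, 0.2))
  noise <- matrix(rnorm(n * 4), n, 4)
  d <- manualDataset(list(transcriptomics = cbind(tx, noise),
                          metabolomics = me))
  feats <- c(sprintf("TR_F%02d", 1:8), sprintf("ME_F%02d", 1:4))
  mod <- detectModules(d, feats, corr_threshold = 0.6)
  expect_identical(length(unique(na.omit(mod))), 2L)
  expect_identical(length(unique(mod[sprintf("TR_F%02d", 1:4)])), 1L)
  expect_identical(length(unique(mod[sprintf("ME_F%02d", 1:4)])), 1L)
  ## modules are numbered by size: the two 4-blocks tie, noise unassigned
  expect_true(all(is.na(mod[sprintf("TR_F%02d", 5:8)])))

  ## an impossible threshold yields no modules
  mod2 <- detectModules(d, feats, corr_threshold = 1.01)
  expect_true(all(is.na(mod2)))

  ## duplicated features join the same module at a near-1 threshold
  dup <- cbind(base1, base1, base1, noise)
  d2 <- manualDataset(list(transcriptomics = dup))
  m3 <- detectModules(d2, sprintf("TR_F%02d", 1:3), corr_threshold = 0.99)
  expect_identical(unname(m3), rep("M1", 3))
})

test_that("rankPTBFeatures is deterministic and BH-monotone", {
  d <- tinyDataset(seed = 13)$dataset
  r1 <- rankPTBFeatures(d)
  r2 <- rankPTBFeatures(d)
  expect_identical(r1, r2)
  expect_true(all(r1$p_mixed_adj >= r1$p_mixed - 1e-12))
  expect_true(all(r1$p_wilcoxon_adj >= r1$p_wilcoxon - 1e-12))
  expect_true(all(r1$p_mixed > 0 & r1$p_mixed <= 1))
  expect_false(is.unsorted(r1$p_mixed))
})
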