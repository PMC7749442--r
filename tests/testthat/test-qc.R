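test_that("modalityComplexity agrees with a cumulative-eigenvalue oracle", {
  ## rank-1 data collapses to a single component
  u <- rnorm(12); v <- rnorm(6)
  X1 <- outer(u, v)
  dimnames(X1) <- list(sprintf("S%d", 1:12), sprintf("F%d", 1:6))
  expect_identical(modalityComplexity(X1), 1L)

  ## three-factor data with shares near {0.52, 0.43, 0.05}: two components
  ## reach 90 percent
  set.seed(21)
  n <- 400
  S <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  L <- diag(c(sqrt(5.5), sqrt(4.5), sqrt(0.5))) %*% matrix(rnorm(3 * 12), 3, 12)
  X3 <- S %*% L * sqrt(n)
  dimnames(X3) <- list(sprintf("S%d", 1:n), sprintf("F%d", 1:12))
  oracle <- function(X, f) {
    Z <- scale(X[, apply(X, 2, sd) > 0])
    ev <- sort(eigen(cov(Z), symmetric = TRUE)$values, decreasing = TRUE)
    ev <- ev[ev > 1e-12]
    which(cumsum(ev) / sum(ev) >= f - 1e-12)[1]
  }
  expect_identical(modalityComplexity(X3), as.integer(oracle(X3, 0.9)))
  expect_identical(modalityComplexity(X3), 2L)

  ## random matrices: exact agreement with the independent oracle
  set.seed(22)
  for (r in 1:10) {
    X <- matrix(rnorm(200), 20, 10)
    dimnames(X) <- list(sprintf("S%d", 1:20), sprintf("F%d", 1:10))
    f <- runif(1, 0.5, 0.99)
    expect_identical(modalityComplexity(X, f), as.integer(oracle(X, f)))
  }

  ## the full spectrum at fraction 1: min(subjects - 1, features)
  Xf <- matrix(rnorm(100), 10, 10,
               dimnames = list(sprintf("S%d", 1:10), sprintf("F%d", 1:10)))
  expect_identical(modalityComplexity(Xf, 1.0), 9L)
  expect_error(modalityComplexity(matrix(1, 5, 3,
    dimnames = list(sprintf("S%d", 1:5), sprintf("F%d", 1:3)))), "variance")
})

test_that("pcaEmbedding matches an eigendecomposition oracle and is deterministic", {
  set.seed(23)
  shift <- rep(c(0, 6), each = 10)
  X <- matrix(rnorm(20 * 15), 20, 15) + shift
  d <- manualDataset(list(proteomics = X),
                     cohort = rep_len(c("A", "B"), 20))
  emb <- pcaEmbedding(d)
  ## PC1 separates the two planted clusters
  expect_true(all(emb$PC1[shift == 0] < 0) != all(emb$PC1[shift == 0] > 0))
  expect_gt(abs(mean(emb$PC1[shift == 6]) - mean(emb$PC1[shift == 0])), 4)
  ## oracle: direct eigendecomposition of the standardized covariance
  Z <- scale(X)
  sc <- Z %*% eigen(cov(Z), symmetric = TRUE)$vectors[, 1:2]
  expect_equal(abs(emb$PC1), abs(sc[, 1]), tolerance = 1e-6)
  expect_equal(abs(emb$PC2), abs(sc[, 2]), tolerance = 1e-6)

  ## duplicated subject rows land on identical coordinates
  X2 <- X; X2[2, ] <- X2[1, ]
  d2 <- manualDataset(list(proteomics = X2),
                      cohort = rep_len(c("A", "B"), 20))
  emb2 <- pcaEmbedding(d2)
  expect_equal(unlist(emb2[1, c("PC1", "PC2")]),
               unlist(emb2[2, c("PC1", "PC2")]), tolerance = 1e-8)
})

test_that("ldaEmbedding separates labelled groups and enforces class rules", {
  set.seed(24)
  n <- 30
  centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  lab <- rep_len(c("A", "B", "C"), n)
  X <- centers[factor(lab), ] + matrix(rnorm(n * 2, 0, 0.5), n, 2)
  X <- cbind(X, matrix(rnorm(n * 10), n, 10))
  d <- manualDataset(list(metabolomics = X), cohort = lab)
  emb <- ldaEmbedding(d)
  co <- as.matrix(emb[, c("LD1", "LD2")])
  between <- dist(rowsum(co, lab) / as.vector(table(lab)))
  within <- mean(vapply(unique(lab), function(l)
    mean(dist(co[lab == l, ])), 0))
  expect_gt(min(between) / within, 3)

  ## shuffled labels give near-chance separation
  set.seed(25)
  labs <- sample(lab)
  embs <- ldaEmbedding(d, labels = labs)
  cos <- as.matrix(embs[, c("LD1", "LD2")])
  bet_s <- dist(rowsum(cos, labs) / as.vector(table(labs)))
  with_s <- mean(vapply(unique(labs), function(l)
    mean(dist(cos[labs == l, ])), 0))
  expect_lt(min(bet_s) / with_s, 1)

  expect_error(ldaEmbedding(d, labels = rep_len(c("A", "B"), n)),
               "at least 3")
  expect_error(ldaEmbedding(d, labels = c("Z", lab[-1])), "at least 2")
})

test_that("permutation p-values follow the add-one formula", {
  sim <- tinyDataset(seed = 26)
  d <- sim$dataset
  cfg <- testConfig(seed = 26)
  cfg$n_perm <- 1L
  cfg$rf_trees <- 30L
  res <- cohortPredictability(modalityMatrix(d, "proteomics"),
                              subjectTable(d)$cohort, cfg)
  expect_true(res$p %in% c(0.5, 1))
  expect_equal(res$p, (1 + sum(res$null >= res$accuracy - 1e-12)) / 2)
})

test_that("cohort predictability detects planted batch structure and not its absence", {
  cfg <- testConfig(seed = 27)
  cfg$rf_trees <- 150L
  ## strong batch effect: near-perfect cohort recovery
  simb <- generateDataset(generatorConfig(seed = 27, cohort_effect_sd = 2))
  rb <- cohortPredictability(modalityMatrix(simb$dataset, "proteomics"),
                             subjectTable(simb$dataset)$cohort, cfg)
  expect_gt(rb$accuracy, 0.9)
  expect_lte(rb$p, 0.05)
  ## no batch effect: accuracy within 3 binomial SDs of chance
  sim0 <- generateDataset(generatorConfig(seed = 28, cohort_effect_sd = 0))
  r0 <- cohortPredictability(modalityMatrix(sim0$dataset, "proteomics"),
                             subjectTable(sim0$dataset)$cohort, cfg)
  n <- nSubjects(sim0$dataset)
  chance <- 1 / 5
  expect_lt(r0$accuracy, chance + 3 * sqrt(chance * (1 - chance) / n))
  expect_gt(r0$p, 0.05)
})

test_that("storage-time predictability flags only the confounded modality", {
  cfg <- testConfig(seed = 29)
  cfg$rf_trees <- 150L
  sim <- generateDataset(generatorConfig(seed = 29))
  st <- subjectTable(sim$dataset)$storage_days
  rm_ <- storageTimePredictability(modalityMatrix(sim$dataset, "metabolomics"),
                                   st, cfg)
  rt <- storageTimePredictability(modalityMatrix(sim$dataset, "transcriptomics"),
                                  st, cfg)
  expect_lte(rm_$p, 0.05)
  expect_gt(rt$p, 0.05)
  ## with the confound disabled, metabolomics is clean too
  sim0 <- generateDataset(generatorConfig(seed = 30, storage_confound_sd = 0))
  r0 <- storageTimePredictability(modalityMatrix(sim0$dataset, "metabolomics"),
                                  subjectTable(sim0$dataset)$storage_days, cfg)
  expect_gt(r0$p, 0.05)
  expect_error(storageTimePredictability(
    modalityMatrix(sim$dataset, "metabolomics"), rep(1, 81), cfg),
    "distinct")
})

test_that("correlation-network embedding is seeded and groups correlated features", {
  set.seed(32)
  n <- 24
  b1 <- rnorm(n); b2 <- rnorm(n)
  blockA <- sapply(1:8, function(i) b1 + rnorm(n, 0, 0.3))
  blockB <- sapply(1:8, function(i) b2 + rnorm(n, 0, 0.3))
  d <- manualDataset(list(transcriptomics = blockA, metabolomics = blockB))
  cfg <- testConfig(seed = 33)
  emb <- correlationNetworkEmbedding(d, cfg, perplexity = 4, max_iter = 250)
  expect_identical(emb, correlationNetworkEmbedding(d, cfg, perplexity = 4,
                                                    max_iter = 250))
  expect_identical(nrow(emb), 16L)
  sil <- momics:::silhouetteScore(as.matrix(emb[, c("x", "y")]),
                                  emb$modality)
  expect_gt(sil, 0)

  ## duplicated features sit at distance ~0 in the embedding
  dup <- cbind(b1, b1, blockA, blockB[, 1:2])
  d2 <- manualDataset(list(proteomics = dup))
  emb2 <- correlationNetworkEmbedding(d2, cfg, perplexity = 3,
                                      max_iter = 250)
  dd <- as.matrix(dist(as.matrix(emb2[, c("x", "y")])))
  expect_lt(dd[1, 2], quantile(dd[upper.tri(dd)], 0.1))
})
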