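## Synthetic multi-cohort multi-omics generator. Emulates the statistical
## structure the downstream analysis assumes: modality-specific latent-factor
## correlation, subtle per-cohort batch shifts, a gestational-age-correlated
## feature module shared across cohorts, a partially cohort-specific
## preterm-birth module, and a storage-time confound restricted to the urine
## metabolome. Ground truth about every planted signal is returned for
## recovery testing.

#' Generator configuration
#'
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 81 subjects in 5 cohorts with 39 preterm deliveries, maternal age
#' 24.8 (5.3) years, median sampling at 13.6 weeks, and (full preset) assay
#' dimensionalities 20659 / 1002 / 6630 for transcriptomics / proteomics /
#' metabolomics. The fast preset (200 / 100 / 150 features) is statistically
#' identical and is the default for tests and examples.
#'
#' @param preset `"fast"` or `"full"` feature dimensionalities.
#' @param n_subjects,n_ptb,n_cohorts cohort design; exactly `n_ptb` subjects
#'   deliver before 37 weeks, by construction.
#' @param dims named integer vector of feature counts per modality
#'   (overrides `preset`).
#' @param latent_rank named integer vector: latent factor count per modality.
#'   Transcriptomics has the lowest effective rank, so it needs the fewest
#'   principal components despite having the most features.
#' @param latent_strength named numeric vector: sd of the latent-factor
#'   component per feature. Together with `noise_sd` this sets each
#'   modality's internal-correlation share (transcriptomics strongest, so
#'   its latent block alone crosses the 90 percent variance mark).
#' @param cohort_effect_sd sd of the per-(cohort, feature) batch shift.
#' @param ga_n,ga_effect number of gestational-age-informative features per
#'   modality and their common coefficient magnitude (units: abundance per
#'   week, applied to the centred sampling age).
#' @param ptb_n,ptb_effect,cohort_heterogeneity number of preterm-informative
#'   (module) features per modality; the separation of the module's
#'   subject-level activity between preterm and term pregnancies, in
#'   activity-sd units; and the fraction of that separation drawn per cohort
#'   (0 = fully shared, 1 = fully cohort-specific). The same fraction scales
#'   cohort-specific baselines of the module activity.
#' @param storage_confound_sd effect of standardized storage time on a
#'   random 10 percent of metabolomics features (other modalities are never
#'   confounded).
#' @param noise_sd iid Gaussian noise sd.
#' @param maternal_age_mean,maternal_age_sd maternal age distribution, years.
#' @param ga_sampling_median centre of the sampling-age distribution, weeks.
#' @param seed integer; identical seeds give bit-identical datasets.
#' @return list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(preset = c("fast", "full"),
                            n_subjects = 81L, n_ptb = 39L, n_cohorts = 5L,
                            dims = NULL,
                            latent_rank = c(transcriptomics = 3L,
                                            proteomics = 8L,
                                            metabolomics = 15L),
                            latent_strength = c(transcriptomics = 2.2,
                                                proteomics = 1.35,
                                                metabolomics = 1.0),
                            cohort_effect_sd = 0.3,
                            ga_n = c(transcriptomics = 20L, proteomics = 10L,
                                     metabolomics = 20L),
                            ga_effect = 0.3,
                            ptb_n = c(transcriptomics = 20L, proteomics = 8L,
                                      metabolomics = 15L),
                            ptb_effect = 2.5,
                            cohort_heterogeneity = 0.5,
                            storage_confound_sd = 0.6,
                            noise_sd = 0.6,
                            maternal_age_mean = 24.8, maternal_age_sd = 5.3,
                            ga_sampling_median = 13.6,
                            seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(dims)) {
    dims <- if (preset == "full")
      c(transcriptomics = 20659L, proteomics = 1002L, metabolomics = 6630L)
    else
      c(transcriptomics = 200L, proteomics = 100L, metabolomics = 150L)
  }
  stopifnot(identical(sort(names(dims)), sort(MODALITIES)),
            n_ptb < n_subjects, n_ptb >= 1L, n_cohorts >= 2L,
            cohort_effect_sd >= 0, storage_confound_sd >= 0, noise_sd >= 0,
            cohort_heterogeneity >= 0, cohort_heterogeneity <= 1,
            all(dims[MODALITIES] >= pmax(ga_n[MODALITIES], ptb_n[MODALITIES])))
  structure(list(preset = preset, n_subjects = as.integer(n_subjects),
                 n_ptb = as.integer(n_ptb), n_cohorts = as.integer(n_cohorts),
                 dims = dims[MODALITIES], latent_rank = latent_rank[MODALITIES],
                 latent_strength = latent_strength[MODALITIES],
                 cohort_effect_sd = cohort_effect_sd,
                 ga_n = ga_n[MODALITIES], ga_effect = ga_effect,
                 ptb_n = ptb_n[MODALITIES], ptb_effect = ptb_effect,
                 cohort_heterogeneity = cohort_heterogeneity,
                 storage_confound_sd = storage_confound_sd,
                 noise_sd = noise_sd,
                 maternal_age_mean = maternal_age_mean,
                 maternal_age_sd = maternal_age_sd,
                 ga_sampling_median = ga_sampling_median,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

## Truncated normal draws by inverse-CDF so that truncation never rejects.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  if (any(phi - plo < 1e-12))
    stop("infeasible truncation bounds in the generator")
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic multi-cohort multi-omics dataset
#'
#' Draws, in order: balanced cohort assignment; gestational age at delivery
#' with exactly `n_ptb` subjects below 37 weeks (preterm block
#' Normal(34, 1.5) truncated below 37; term block Normal(39.5, 1) truncated
#' at or above 37); sampling age Normal(median, 3) truncated to
#' (8, delivery - 4); storage time Uniform(100, 1000) days; then per
#' modality a latent-factor backbone plus cohort batch shifts, the planted
#' gestational-age and preterm modules, the metabolomics-only storage
#' confound, and iid noise. Delivery age and storage time are drawn
#' independently, so they are uncorrelated by construction. Maternal age and
#' a delivery-age-derived birthweight complete the subject table. The
#' proteomics panel names one gestational-age-informative feature `PGF`
#' (placental growth factor) for the urine-surrogate analysis.
#'
#' @param config a [generatorConfig()] list.
#' @return list with elements `dataset` (a [MultiOmicsDataset-class]) and
#'   `truth` (per-modality planted feature ids and coefficients, latent
#'   loadings, and the confounded metabolite set).
#' @examples
#' sim <- generateDataset(generatorConfig(seed = 7))
#' sim$dataset
#' @export
generateDataset <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  n <- config$n_subjects
  subject_id <- sprintf("S%03d", seq_len(n))
  cohort <- sample(rep_len(sprintf("C%d", seq_len(config$n_cohorts)), n))
  is_ptb <- sample(rep(c(TRUE, FALSE), c(config$n_ptb, n - config$n_ptb)))
  ga_delivery <- numeric(n)
  ga_delivery[is_ptb] <- rtnorm(sum(is_ptb), 34, 1.5, upper = 37 - 1e-9)
  ga_delivery[!is_ptb] <- rtnorm(sum(!is_ptb), 39.5, 1, lower = 37)
  ga_sampling <- vapply(ga_delivery, function(gd)
    rtnorm(1L, config$ga_sampling_median, 3, lower = 8, upper = gd - 4),
    0)
  storage_days <- runif(n, 100, 1000)
  maternal_age <- rnorm(n, config$maternal_age_mean, config$maternal_age_sd)
  birthweight <- 3300 - 180 * pmax(0, 40 - ga_delivery) + rnorm(n, 0, 250)

  ga_c <- ga_sampling - mean(ga_sampling)
  storage_z <- as.numeric(scale(storage_days))
  cohorts <- sort(unique(cohort))
  matrices <- list(); truth <- list()
  for (mod in MODALITIES) {
    p <- config$dims[[mod]]
    r <- config$latent_rank[[mod]]
    fid <- sprintf("%s_%05d", toupper(substr(mod, 1, 2)), seq_len(p))
    scores <- matrix(rnorm(n * r), n, r)
    loadings <- matrix(rnorm(p * r, sd = config$latent_strength[[mod]] / sqrt(r)),
                       p, r)
    vals <- scores %*% t(loadings)
    ## subtle per-(cohort, feature) batch shift
    shift <- matrix(rnorm(length(cohorts) * p, 0, config$cohort_effect_sd),
                    length(cohorts), p)
    vals <- vals + shift[match(cohort, cohorts), , drop = FALSE]
    ## gestational-age module: shared across cohorts
    ga_idx <- sample.int(p, config$ga_n[[mod]])
    ga_beta <- config$ga_effect * sample(c(-1, 1), length(ga_idx), TRUE)
    vals[, ga_idx] <- vals[, ga_idx] + outer(ga_c, ga_beta)
    ## preterm module: a correlated block of markers driven by one latent
    ## module activity per modality (for example an inflammatory axis).
    ## Cases' activity is shifted by ptb_effect, with a cohort_heterogeneity
    ## fraction of the shift drawn per cohort; cohorts also differ in the
    ## module's baseline activity (scaled by the same fraction), emulating
    ## site-specific marker baselines. Univariate case contrasts are strong,
    ## but the multivariate information is bounded by the activity
    ## separation, as in a real correlated marker module. h = 0 gives a
    ## fully shared, baseline-free module.
    ptb_idx <- sample.int(p, config$ptb_n[[mod]])
    h <- config$cohort_heterogeneity
    dsep <- config$ptb_effect
    lam <- sample(c(-1, 1), length(ptb_idx), TRUE) *
      runif(length(ptb_idx), 0.6, 1) * config$latent_strength[[mod]]
    zeta <- rnorm(length(cohorts))
    case_shift <- (1 - h) * dsep + h * dsep * zeta         # per cohort
    base_act <- rnorm(length(cohorts), 0, h * dsep)        # per cohort
    activity <- rnorm(n) + base_act[match(cohort, cohorts)] +
      case_shift[match(cohort, cohorts)] * is_ptb
    vals[, ptb_idx] <- vals[, ptb_idx] + outer(activity, lam)
    delta <- outer(lam, case_shift)                        # feature-level
    dimnames(delta) <- list(fid[ptb_idx], cohorts)
    ## storage-time confound: metabolomics only, random 10% of features
    st_idx <- integer(0)
    if (mod == "metabolomics" && config$storage_confound_sd > 0) {
      st_idx <- sample.int(p, max(1L, round(0.1 * p)))
      st_sign <- sample(c(-1, 1), length(st_idx), TRUE)
      vals[, st_idx] <- vals[, st_idx] +
        outer(storage_z, config$storage_confound_sd * st_sign)
    }
    vals <- vals + matrix(rnorm(n * p, 0, config$noise_sd), n, p)
    if (mod == "proteomics") fid[ga_idx[1L]] <- "PGF"
    dimnames(vals) <- list(subject_id, fid)
    matrices[[mod]] <- featureMatrix(vals, mod)
    truth[[mod]] <- list(
      ga_features = setNames(ga_beta, fid[ga_idx]),
      ptb_features = delta,
      loadings = loadings,
      storage_features = fid[st_idx])
  }
  subjects <- data.frame(
    subject_id = subject_id, cohort = cohort,
    ga_sampling_weeks = ga_sampling, ga_delivery_weeks = ga_delivery,
    ptb = ga_delivery < 37, storage_days = storage_days,
    maternal_age_years = maternal_age, birthweight_g = birthweight,
    stringsAsFactors = FALSE)
  dataset <- new("MultiOmicsDataset", subjects = subjects,
                 matrices = matrices)
  list(dataset = dataset,
       truth = structure(truth, seed = config$seed, config = config))
}

#' Generate a pathway fixture with one planted enriched pathway
#'
#' Builds `n_pathways` member sets over the metabolomics feature universe.
#' The first pathway (`PW_planted`) contains at least 70 percent of the
#' preterm-informative metabolite features from `truth`; the remainder are
#' drawn uniformly, with sizes between 10 and 50.
#'
#' @param truth ground-truth record from [generateDataset()].
#' @param n_pathways number of pathways (>= 1).
#' @param seed integer seed.
#' @return A [PathwayCollection-class] whose universe is the metabolomics
#'   feature set.
#' @export
generatePathways <- function(truth, n_pathways = 20L, seed = 1L) {
  stopifnot(n_pathways >= 1L)
  cfg <- attr(truth, "config")
  universe <- sprintf("ME_%05d", seq_len(cfg$dims[["metabolomics"]]))
  if (length(universe) < 50L)
    stop("metabolomics universe smaller than the maximum pathway size")
  set.seed(seed)
  planted_members <- rownames(truth$metabolomics$ptb_features)
  n_in <- max(1L, ceiling(0.7 * length(planted_members)))
  members <- sample(planted_members, n_in)
  size <- max(10L, min(50L, length(members) + 5L))
  if (length(members) < size)
    members <- c(members,
                 sample(setdiff(universe, members), size - length(members)))
  pw <- list(PW_planted = members)
  desc <- "planted preterm metabolite module"
  if (n_pathways > 1L) {
    for (i in seq_len(n_pathways - 1L)) {
      sz <- sample(10:50, 1L)
      pw[[sprintf("PW_%03d", i)]] <- sample(universe, sz)
      desc <- c(desc, sprintf("random pathway %d", i))
    }
  }
  new("PathwayCollection", pathways = pw, descriptions = desc,
      universe = universe)
}
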