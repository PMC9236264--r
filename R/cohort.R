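# Synthetic cohort generator.
#
# Generative model: per class, features are multivariate normal with equal
# covariance. Within each schema group tag (the 8 statistics of one
# parcellation, the 4 measures of one tract, ...) features share an
# exchangeable correlation `block_correlation`, emulating the within-region
# dependence of real morphometrics. Planted features differ between classes
# by `effect_size` standard deviations (Cohen's d), with deterministic
# alternating directions; all other features are exchangeable between
# classes. Fatigue scores are constructed so that label_improvement()
# reproduces the intended class assignment exactly.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study's cohort geometry: 22 fatigue improvers and
#' 32 non-improvers. `effect_size` is the standardized between-class mean
#' difference planted on `planted_features`; `block_correlation` is the
#' within-group-tag feature correlation; baseline Chalder Fatigue Scale
#' scores are drawn uniformly on `cfs_range` (default 4-11, above the
#' eligibility floor of 3).
#'
#' @param schema A [build_schema()] object.
#' @param n_improvers,n_nonimprovers Class sizes.
#' @param planted_features Integer feature indices carrying the class effect.
#' @param effect_size Cohen's d on the planted features.
#' @param block_correlation Within-block correlation in \[0, 1).
#' @param noise_sd Feature standard deviation.
#' @param cfs_range Baseline score range (integer, within the 0-11 scale).
#' @param threshold Improvement cut-off passed to [label_improvement()].
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(schema,
                          n_improvers = 22, n_nonimprovers = 32,
                          planted_features = integer(0),
                          effect_size = 1.5,
                          block_correlation = 0.3,
                          noise_sd = 1,
                          cfs_range = c(4, 11),
                          threshold = 2,
                          seed = 1) {
  stopifnot(inherits(schema, "feature_schema"))
  d <- length(schema$feature_names)
  if (!is_count(n_improvers) || !is_count(n_nonimprovers)) {
    stop_ganest("class counts must be positive integers")
  }
  planted_features <- as.integer(planted_features)
  if (length(planted_features) &&
      (any(planted_features < 1) || any(planted_features > d))) {
    stop_ganest("planted feature index out of range [1, ", d, "]")
  }
  if (anyDuplicated(planted_features)) {
    stop_ganest("duplicate planted feature indices")
  }
  if (block_correlation < 0 || block_correlation >= 1) {
    stop_ganest("block_correlation must be in [0, 1)")
  }
  if (noise_sd <= 0) stop_ganest("noise_sd must be positive")
  if (cfs_range[1] < threshold || cfs_range[2] > 11 ||
      cfs_range[1] > cfs_range[2]) {
    stop_ganest("impossible score construction: cfs_range must lie within [",
                threshold, ", 11]")
  }
  structure(list(schema = schema, n_improvers = n_improvers,
                 n_nonimprovers = n_nonimprovers,
                 planted_features = planted_features,
                 effect_size = effect_size,
                 block_correlation = block_correlation,
                 noise_sd = noise_sd, cfs_range = cfs_range,
                 threshold = threshold, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `table` (a
#'   [feature_table()]), `labels` (an [label_improvement()] object) and
#'   `truth` (class `ground_truth`: planted indices, per-feature effect
#'   direction, intended class per subject). The direction is the sign of
#'   (non-improver mean - improver mean), alternating +, - across planted
#'   features.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  schema <- config$schema
  d <- length(schema$feature_names)
  n1 <- config$n_improvers
  n0 <- config$n_nonimprovers
  n <- n1 + n0
  improver <- c(rep(TRUE, n1), rep(FALSE, n0))

  set.seed(config$seed)
  tags <- match(schema$group_tags, unique(schema$group_tags))
  rho <- config$block_correlation
  block <- matrix(stats::rnorm(n * max(tags)), n, max(tags))
  noise <- matrix(stats::rnorm(n * d), n, d)
  values <- (sqrt(rho) * block[, tags, drop = FALSE] +
             sqrt(1 - rho) * noise) * config$noise_sd

  direction <- integer(d)
  if (length(config$planted_features)) {
    direction[config$planted_features] <-
      rep_len(c(1L, -1L), length(config$planted_features))
    shift <- config$effect_size * config$noise_sd / 2
    for (j in config$planted_features) {
      values[improver, j] <- values[improver, j] - direction[j] * shift
      values[!improver, j] <- values[!improver, j] + direction[j] * shift
    }
  }
  if (schema$modality == "clinical" && "sex" %in% schema$feature_names) {
    j <- match("sex", schema$feature_names)
    values[, j] <- as.numeric(values[, j] > 0)
  }

  rng <- config$cfs_range
  baseline <- sample(rng[1]:rng[2], n, replace = TRUE)
  drop <- integer(n)
  for (i in seq_len(n)) {
    if (improver[i]) {
      cand <- config$threshold:min(config$threshold + 2, baseline[i])
    } else {
      cand <- (-1):(config$threshold - 1)
      cand <- cand[baseline[i] - cand <= 11 & baseline[i] - cand >= 0]
    }
    drop[i] <- sample_one(cand)
  }
  followup <- baseline - drop

  ids <- sprintf("s%03d", seq_len(n))
  labels <- label_improvement(baseline, followup, threshold = config$threshold,
                              subject_ids = ids)
  stopifnot(identical(labels$improver, improver))
  table <- feature_table(values, schema, ids)
  truth <- structure(list(planted_features = config$planted_features,
                          direction = direction,
                          improver = improver),
                     class = "ground_truth")
  structure(list(table = table, labels = labels, truth = truth,
                 config = config),
            class = "cohort")
}

#' Generate a null cohort (no class effect)
#'
#' Equivalent to [generate_cohort()] with `effect_size` forced to 0 and an
#' empty planted set: every feature is exchangeable between classes, so any
#' downstream classifier should perform at chance.
#'
#' @param config A [cohort_config()].
#' @return As [generate_cohort()]; `truth$planted_features` is empty.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$effect_size <- 0
  config$planted_features <- integer(0)
  generate_cohort(config)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d x %d (%s), %d improvers / %d non-improvers, %d planted, d = %g\n",
    nrow(x$table$values), ncol(x$table$values), x$table$schema$modality,
    x$labels$n_improver, x$labels$n_nonimprover,
    length(x$truth$planted_features), x$config$effect_size))
  invisible(x)
}
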