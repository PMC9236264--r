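# Nested, repeated cross-validation around GA selection and classification.
#
# Outer loop: stratified 5-fold CV, re-randomized on every repeat (100
# repeats at full scale). Per outer fold: the GA selects a chromosome on the
# training rows only; the classifier (LSLD directly, SVMs via an inner
# stratified 5-fold grid search on the training rows) is fit on the
# chromosome's features; predictions and decision scores are emitted for the
# held-out rows. No statistic of any kind touches test rows before
# prediction. Selection frequencies are counted over all repeats x folds
# fold-fits (denominator 500 at full scale).

#' Stratified fold assignment
#'
#' Partitions subjects into `k` folds so that fold sizes differ by at most
#' one per class and at most one overall (class remainders are placed on the
#' currently smallest folds).
#'
#' @param labels An `outcome_labels` object, or a +/-1 (or logical) vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param strict Error when a class has fewer members than `k` (default);
#'   with `strict = FALSE` such a class is spread one subject per fold
#'   (leave-one-out within that class) with a message.
#' @return Integer fold id (1..k) per subject.
#' @export
make_folds <- function(labels, k = 5, seed = 1, strict = TRUE) {
  y <- if (inherits(labels, "outcome_labels")) labels$improver else labels > 0
  n <- length(y)
  set.seed(seed)
  fold <- integer(n)
  totals <- numeric(k)
  for (cls in c(FALSE, TRUE)) {
    idx <- which(y == cls)
    nc <- length(idx)
    if (nc < k) {
      if (strict) {
        stop_ganest("class with ", nc, " members is smaller than k = ", k)
      }
      message("class with ", nc, " members < k = ", k,
              ": leave-one-out within that class")
    }
    base <- nc %/% k
    rem <- nc %% k
    counts <- rep(base, k)
    if (rem > 0) {
      # extras go to the folds currently smallest; ties broken at random
      extra <- order(totals + stats::runif(k) * 1e-9)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    idx <- idx[sample.int(nc)]
    fold[idx] <- rep.int(seq_len(k), counts)
    totals <- totals + counts
  }
  fold
}

.fit_fold_classifier <- function(X_train, y_train, classifier, spec,
                                 chromosome, seed) {
  Xc <- X_train[, chromosome, drop = FALSE]
  switch(classifier,
         "lsld" = fit_lsld(Xc, y_train, feature_indices = chromosome),
         "svm-linear" = tune_svm(Xc, y_train,
                                 spec %||% svm_spec("linear"),
                                 seed = seed, feature_indices = chromosome),
         "svm-rbf" = tune_svm(Xc, y_train,
                              spec %||% svm_spec("rbf"),
                              seed = seed, feature_indices = chromosome),
         stop_ganest("unknown classifier '", classifier, "'"))
}

#' Run one outer fold: GA selection, fit, held-out prediction
#'
#' @param table A [feature_table()].
#' @param labels Aligned `outcome_labels`.
#' @param train_idx,test_idx Disjoint row indices.
#' @param classifier `"lsld"`, `"svm-linear"` or `"svm-rbf"`.
#' @param ga_config A [ga_config()]; its `seed` drives the GA for this fold.
#' @param spec Optional [svm_spec()] for the SVM classifiers.
#' @param inner_seed Seed for the inner tuning folds (SVMs only).
#' @return A list of class `fold_result`: `chromosome`, `classifier`,
#'   `hyperparameters`, `test_ids`, `y_true`, `y_pred`, `scores`,
#'   `ga_best_fitness`.
#' @export
run_fold <- function(table, labels, train_idx, test_idx,
                     classifier = c("lsld", "svm-linear", "svm-rbf"),
                     ga_config = NULL, spec = NULL,
                     inner_seed = 1) {
  classifier <- match.arg(classifier)
  ga_config <- ga_config %||% ganest::ga_config()
  if (length(intersect(train_idx, test_idx))) {
    stop_ganest("train and test rows overlap")
  }
  y <- labels_pm1(labels)
  X_train <- table$values[train_idx, , drop = FALSE]
  y_train <- y[train_idx]
  if (length(unique(y_train)) < 2) {
    stop_ganest("both classes required in the training partition")
  }
  ga <- run_ga(X_train, y_train, ga_config)
  chrom <- ga$best_chromosome
  model <- .fit_fold_classifier(X_train, y_train, classifier, spec,
                                chrom, seed = inner_seed)
  X_test <- table$values[test_idx, chrom, drop = FALSE]
  scores <- decision_values(model, X_test)
  hyper <- if (inherits(model, "ganest_svm")) {
    list(C = model$C, gamma = model$gamma)
  } else {
    list()
  }
  structure(list(chromosome = chrom,
                 classifier = classifier,
                 hyperparameters = hyper,
                 test_ids = table$subject_ids[test_idx],
                 y_true = y[test_idx],
                 y_pred = ifelse(scores > 0, 1, -1),
                 scores = scores,
                 ga_best_fitness = ga$best_fitness),
            class = "fold_result")
}

#' Repeated nested cross-validation
#'
#' Runs `repeats` independently re-randomized stratified `k`-fold outer
#' loops. Performance is computed per repeat from that repeat's pooled
#' out-of-fold predictions (every subject is tested exactly once per
#' repeat), then averaged across repeats with a 95% CI from the
#' across-repeat distribution. Feature selection frequencies are counted
#' over all `repeats * k` fold-fits.
#'
#' @param table A [feature_table()].
#' @param labels Aligned `outcome_labels`.
#' @param classifier `"lsld"`, `"svm-linear"` or `"svm-rbf"`.
#' @param ga_config A [ga_config()] (its `seed` field is ignored here; all
#'   randomness derives from `seed`).
#' @param spec Optional [svm_spec()].
#' @param repeats Number of repeats (study scale: 100).
#' @param k Outer folds (default 5).
#' @param seed Master seed; per-repeat/fold child seeds are derived from it.
#' @return A list of class `cv_report`: `folds` (all fold results),
#'   `per_repeat` (data.frame of per-repeat metrics), `overall` (means and
#'   95% CIs across repeats), `frequency` (selection-frequency table),
#'   `rocs` (per-repeat [roc_points()]), and the run configuration.
#' @export
run_nested_cv <- function(table, labels,
                          classifier = c("lsld", "svm-linear", "svm-rbf"),
                          ga_config = NULL, spec = NULL,
                          repeats = 100, k = 5, seed = 1) {
  classifier <- match.arg(classifier)
  ga_config <- ga_config %||% ganest::ga_config()
  stopifnot(inherits(table, "feature_table"),
            inherits(labels, "outcome_labels"))
  n <- nrow(table$values)
  if (length(labels$improver) != n) stop_ganest("labels/table size mismatch")
  y <- labels_pm1(labels)

  folds_out <- vector("list", repeats * k)
  per_repeat <- vector("list", repeats)
  rocs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    assign_r <- make_folds(labels, k = k, seed = derive_seed(seed, r, 101L))
    pred <- numeric(n)
    score <- numeric(n)
    for (f in seq_len(k)) {
      gc_f <- ga_config
      gc_f$seed <- derive_seed(seed, r, f, 202L)
      fr <- run_fold(table, labels,
                     train_idx = which(assign_r != f),
                     test_idx = which(assign_r == f),
                     classifier = classifier, ga_config = gc_f, spec = spec,
                     inner_seed = derive_seed(seed, r, f, 303L))
      fr$repeat_idx <- r
      fr$fold_idx <- f
      folds_out[[(r - 1) * k + f]] <- fr
      pred[assign_r == f] <- fr$y_pred
      score[assign_r == f] <- fr$scores
    }
    perf <- summarize_performance(y, pred)
    roc <- roc_points(score, y)
    rocs[[r]] <- roc
    per_repeat[[r]] <- data.frame(
      repeat_idx = r,
      balanced_accuracy = perf$balanced_accuracy,
      sensitivity = perf$sensitivity, specificity = perf$specificity,
      ppv = perf$ppv, npv = perf$npv, auc = roc$auc)
  }
  per_repeat <- do.call(rbind, per_repeat)

  ci <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(c(NA_real_, NA_real_))
    m <- mean(v); se <- stats::sd(v) / sqrt(length(v))
    c(m - 1.96 * se, m + 1.96 * se)
  }
  metrics <- c("balanced_accuracy", "sensitivity", "specificity",
               "ppv", "npv", "auc")
  overall <- lapply(metrics, function(m) {
    list(mean = mean(per_repeat[[m]], na.rm = TRUE),
         ci95 = ci(per_repeat[[m]]))
  })
  names(overall) <- metrics

  report <- structure(list(folds = folds_out, per_repeat = per_repeat,
                           overall = overall, rocs = rocs,
                           classifier = classifier,
                           repeats = repeats, k = k, seed = seed,
                           chromosome_length = ga_config$chromosome_length,
                           feature_names = table$schema$feature_names,
                           group_tags = table$schema$group_tags),
                      class = "cv_report")
  report$frequency <- aggregate_frequency(report)
  report
}

#' Feature selection-frequency ranking of a CV report
#'
#' Counts, for every feature, the number of fold-fits (out of
#' `repeats * k`; 500 at full scale) whose selected chromosome contains it,
#' and ranks features by count (ties by feature order). Percentages use the
#' fold-fit denominator.
#'
#' @param report A [run_nested_cv()] report.
#' @return A data.frame of class `feature_frequency`: `feature`, `name`,
#'   `group_tag`, `count`, `percentage`, sorted by descending count, with
#'   the denominator in `attr(, "denominator")`.
#' @export
aggregate_frequency <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  if (!length(report$folds)) stop_ganest("empty report")
  d <- length(report$feature_names)
  counts <- tabulate(unlist(lapply(report$folds, `[[`, "chromosome")),
                     nbins = d)
  denom <- report$repeats * report$k
  out <- data.frame(feature = seq_len(d),
                    name = report$feature_names,
                    group_tag = report$group_tags,
                    count = counts,
                    percentage = 100 * counts / denom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$feature), ]
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  class(out) <- c("feature_frequency", "data.frame")
  out
}

#' @export
print.cv_report <- function(x, ...) {
  o <- x$overall
  pct <- function(m) sprintf("%.1f%% [%.1f, %.1f]",
                             100 * m$mean, 100 * m$ci95[1], 100 * m$ci95[2])
  cat(sprintf("<cv_report> %s, %d repeats x %d folds (L = %d)\n",
              x$classifier, x$repeats, x$k, x$chromosome_length))
  cat("  Acc ", pct(o$balanced_accuracy),
      " | Sens ", pct(o$sensitivity),
      " | Spec ", pct(o$specificity), "\n", sep = "")
  cat(sprintf("  AUC %.3f | top feature: %s (%d/%d)\n",
              o$auc$mean, x$frequency$name[1], x$frequency$count[1],
              attr(x$frequency, "denominator")))
  invisible(x)
}

#' Export a CV report as delimited tables plus a run manifest
#'
#' Writes `folds.csv` (one row per fold-fit with its chromosome and held-out
#' predictions), `frequency.csv`, `per_repeat.csv`, `summary.csv`, and
#' `manifest.json` (configuration and master seed) under `dir`.
#'
#' @param report A [run_nested_cv()] report.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cv_report <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fold_rows <- lapply(report$folds, function(f) {
    data.frame(repeat_idx = f$repeat_idx, fold_idx = f$fold_idx,
               chromosome = paste(f$chromosome, collapse = ";"),
               subject_id = f$test_ids, y_true = f$y_true,
               y_pred = f$y_pred, score = f$scores,
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, fold_rows), file.path(dir, "folds.csv"))
  data.table::fwrite(report$frequency, file.path(dir, "frequency.csv"))
  data.table::fwrite(report$per_repeat, file.path(dir, "per_repeat.csv"))
  o <- report$overall
  summary_df <- data.frame(
    metric = names(o),
    mean = vapply(o, function(m) m$mean, numeric(1)),
    ci_lower = vapply(o, function(m) m$ci95[1], numeric(1)),
    ci_upper = vapply(o, function(m) m$ci95[2], numeric(1)))
  data.table::fwrite(summary_df, file.path(dir, "summary.csv"))
  manifest <- list(classifier = report$classifier, repeats = report$repeats,
                   k = report$k, seed = report$seed,
                   chromosome_length = report$chromosome_length,
                   n_features = length(report$feature_names),
                   denominator = attr(report$frequency, "denominator"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
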