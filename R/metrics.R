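# Performance metrics, ROC aggregation and univariate trend annotation.
#
# The positive class is the fatigue improver (+1). Balanced accuracy — the
# study's headline "accuracy" — is the mean of sensitivity and specificity,
# robust to the 22/32 class imbalance.

#' Confusion-based performance summary
#'
#' `Sens = TP/(TP+FN)`, `Spec = TN/(TN+FP)`, balanced accuracy
#' `(Sens+Spec)/2`, `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`. A rate whose
#' denominator is 0 is returned as `NA` and named in `$undefined`.
#'
#' @param y_true,y_pred Label vectors; positive class is `+1` (improver),
#'   anything else counts as negative. `outcome_labels` objects accepted.
#' @return A list of class `performance_summary` with the five rates and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
summarize_performance <- function(y_true, y_pred) {
  if (inherits(y_true, "outcome_labels")) y_true <- labels_pm1(y_true)
  if (!length(y_true)) stop_ganest("empty input")
  if (length(y_true) != length(y_pred)) stop_ganest("length mismatch")
  pos_t <- y_true > 0
  pos_p <- y_pred > 0
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p); fp <- sum(!pos_t & pos_p)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  npv <- rate(tn, tn + fn)
  out <- list(sensitivity = sens, specificity = spec,
              balanced_accuracy = mean(c(sens, spec)),
              ppv = ppv, npv = npv,
              tp = tp, fp = fp, tn = tn, fn = fn)
  out$undefined <- names(which(vapply(out[c("sensitivity", "specificity",
                                            "ppv", "npv")], is.na, logical(1))))
  structure(out, class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<performance> Acc %s | Sens %s | Spec %s | PPV %s | NPV %s\n",
              fmt(x$balanced_accuracy), fmt(x$sensitivity),
              fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' ROC curve by threshold sweep, with trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores (ties cross
#' simultaneously, producing diagonal segments), anchored at (0,0) and
#' (1,1). The AUC is the trapezoidal area, equal to the tie-adjusted
#' rank statistic (probability that a random positive outscores a random
#' negative, ties half-weighted).
#'
#' @param scores Continuous decision scores (higher = more improver-like).
#' @param y_true Labels, positive class `+1`; `outcome_labels` accepted.
#' @return A list of class `roc_points`: `fpr`, `tpr` (monotone
#'   non-decreasing point set) and `auc`.
#' @export
roc_points <- function(scores, y_true) {
  if (inherits(y_true, "outcome_labels")) y_true <- labels_pm1(y_true)
  pos <- y_true > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_ganest("ROC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group tied scores so they cross the threshold together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_points")
}

#' Vertical averaging of per-repeat ROC curves
#'
#' Interpolates each curve's TPR on a fixed 101-point FPR grid, averages
#' across repeats, and forms a normal-approximation 95% band
#' (`mean +/- 1.96 * SE` across repeats, clipped to \[0, 1\]); a percentile
#' band is available via `band = "percentile"`. The averaged curve is
#' anchored at (0,0) and (1,1). The summary AUC is the mean of the
#' per-repeat trapezoidal AUCs.
#'
#' @param rocs List of [roc_points()] objects (one per repeat, >= 2).
#' @param band `"normal"` (default) or `"percentile"`.
#' @return A list of class `roc_summary`: `fpr_grid`, `mean_tpr`,
#'   `lower`, `upper`, `mean_auc`, `n_repeats`.
#' @export
mean_roc <- function(rocs, band = c("normal", "percentile")) {
  band <- match.arg(band)
  if (!length(rocs)) stop_ganest("no ROC curves to average")
  grid <- seq(0, 1, length.out = 101)
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$fpr, r$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(101))
  tprs <- matrix(tprs, nrow = 101)
  tprs[1, ] <- 0
  tprs[101, ] <- 1
  m <- rowMeans(tprs)
  nr <- length(rocs)
  if (band == "normal") {
    se <- apply(tprs, 1, stats::sd) / sqrt(nr)
    lower <- pmax(0, m - 1.96 * se)
    upper <- pmin(1, m + 1.96 * se)
  } else {
    lower <- apply(tprs, 1, stats::quantile, probs = 0.025)
    upper <- apply(tprs, 1, stats::quantile, probs = 0.975)
  }
  structure(list(fpr_grid = grid, mean_tpr = m, lower = lower, upper = upper,
                 mean_auc = mean(vapply(rocs, `[[`, numeric(1), "auc")),
                 n_repeats = nr),
            class = "roc_summary")
}

#' @export
plot.roc_summary <- function(x, ...) {
  graphics::plot(x$fpr_grid, x$mean_tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Mean ROC (AUC = %.3f, %d repeats)",
                                x$mean_auc, x$n_repeats), ...)
  graphics::polygon(c(x$fpr_grid, rev(x$fpr_grid)), c(x$lower, rev(x$upper)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Two-sample t-test trend annotation per feature
#'
#' For each requested feature, tests non-improvers against improvers with a
#' two-sided two-sample t-test (pooled variance by default, Welch via
#' `welch = TRUE`) and reports the trend sign: `"+"` if the feature is
#' increased in non-improvers relative to improvers, `"-"` if decreased,
#' `"none"` if the means are equal. No multiple-testing correction is
#' applied; this is an annotation, not an inference procedure. Zero pooled
#' variance is flagged with `NA` statistics.
#'
#' @param table A [feature_table()].
#' @param labels An `outcome_labels` object aligned with the table.
#' @param features Integer feature indices (default: all).
#' @param welch Use the Welch unequal-variance test.
#' @return A data.frame: `feature`, `name`, `sign`, `t`, `p`,
#'   `mean_improver`, `mean_nonimprover`.
#' @export
trend_ttest <- function(table, labels, features = NULL, welch = FALSE) {
  stopifnot(inherits(table, "feature_table"),
            inherits(labels, "outcome_labels"))
  features <- features %||% seq_len(ncol(table$values))
  imp <- labels$improver
  if (sum(imp) < 2 || sum(!imp) < 2) {
    stop_ganest("both classes need >= 2 members")
  }
  rows <- lapply(features, function(j) {
    xi <- table$values[imp, j]
    xn <- table$values[!imp, j]
    diff <- mean(xn) - mean(xi)
    if (stats::sd(xi) == 0 && stats::sd(xn) == 0) {
      t_stat <- NA_real_; p <- NA_real_
      if (diff == 0) { t_stat <- 0; p <- 1 } # identical constant groups
    } else {
      tt <- stats::t.test(xn, xi, var.equal = !welch)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(feature = j,
               name = table$schema$feature_names[j],
               sign = if (diff > 0) "+" else if (diff < 0) "-" else "none",
               t = t_stat, p = p,
               mean_improver = mean(xi), mean_nonimprover = mean(xn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
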