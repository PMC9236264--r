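# Soft-margin and RBF support vector machines.
#
# The quadratic program is solved by libsvm (via e1071); this module owns the
# contracts around it: +/-1 labelling, score orientation (positive =
# improver), the hyperparameter grids, and inner-CV tuning by balanced
# accuracy on the training partition only.

#' Hyperparameter grid specification for the SVMs
#'
#' Default grids are the nine integer powers of two from 2^-4 to 2^4, for
#' both the regularization constant C and (RBF only) the kernel width gamma.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C_grid Positive reals.
#' @param gamma_grid Positive reals (RBF only).
#' @return A list of class `svm_spec`.
#' @export
svm_spec <- function(kernel = c("linear", "rbf"),
                     C_grid = 2^(-4:4),
                     gamma_grid = 2^(-4:4)) {
  kernel <- match.arg(kernel)
  if (any(C_grid <= 0)) stop_ganest("C grid must be positive")
  if (kernel == "rbf" && any(gamma_grid <= 0)) {
    stop_ganest("gamma grid must be positive")
  }
  structure(list(kernel = kernel, C_grid = C_grid,
                 gamma_grid = if (kernel == "rbf") gamma_grid else NULL),
            class = "svm_spec")
}

#' Fit a soft-margin SVM
#'
#' @param X Numeric matrix (subjects x selected features).
#' @param y +/-1 labels or an `outcome_labels` object.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Regularization constant (> 0).
#' @param gamma RBF kernel width (> 0); required iff `kernel = "rbf"`.
#' @param feature_indices Optional parent-table column indices, recorded.
#' @return An object of class `ganest_svm` wrapping the fitted model with
#'   its score orientation and hyperparameters.
#' @export
fit_svm <- function(X, y, kernel = c("linear", "rbf"), C = 1, gamma = NULL,
                    feature_indices = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (inherits(y, "outcome_labels")) y <- labels_pm1(y)
  if (!all(y %in% c(-1, 1))) stop_ganest("labels must be coded -1 / +1")
  if (length(unique(y)) < 2) stop_ganest("training labels are single-class")
  if (!is.numeric(C) || length(C) != 1 || C <= 0) {
    stop_ganest("C must be a positive real")
  }
  if (kernel == "rbf") {
    if (is.null(gamma) || gamma <= 0) {
      stop_ganest("rbf kernel requires a positive gamma")
    }
  } else {
    gamma <- NULL
  }
  yf <- factor(y, levels = c(-1, 1))
  n <- nrow(X)
  sds <- sqrt(colSums((X - rep(colMeans(X), each = n))^2) / max(1, n - 1))
  args <- list(x = X, y = yf, scale = sds > 0,
               kernel = if (kernel == "rbf") "radial" else "linear",
               cost = C, type = "C-classification", fitted = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  model <- do.call(e1071::svm, args)
  # libsvm orients decision values toward the first training label it sees
  # (model$labels[1]); flip once so positive scores always mean "improver"
  flip <- if (model$levels[model$labels[1]] == "1") 1 else -1
  structure(list(model = model, flip = flip, kernel = kernel,
                 C = C, gamma = gamma,
                 feature_indices = feature_indices %||% seq_len(ncol(X)),
                 kind = paste0("svm-", kernel)),
            class = "ganest_svm")
}

#' @export
decision_values.ganest_svm <- function(model, X) {
  X <- as.matrix(X)
  p <- stats::predict(model$model, X, decision.values = TRUE)
  unname(drop(attr(p, "decision.values"))) * model$flip
}

#' @export
print.ganest_svm <- function(x, ...) {
  cat(sprintf("<svm> kernel %s, C = %g%s, %d support vectors\n",
              x$kernel, x$C,
              if (!is.null(x$gamma)) sprintf(", gamma = %g", x$gamma) else "",
              x$model$tot.nSV))
  invisible(x)
}

#' Tune an SVM by inner stratified cross-validation
#'
#' Evaluates every point of the grid in `spec` by `inner_k`-fold stratified
#' cross-validation restricted to the supplied (training) rows, scoring by
#' balanced accuracy of the pooled inner out-of-fold predictions, then refits
#' the winner on all rows. Ties are broken toward smaller C, then smaller
#' gamma. If a class has fewer members than `inner_k`, its members are
#' spread one per fold (leave-one-out within that class) with a message.
#'
#' @param X,y Training rows only.
#' @param spec An [svm_spec()].
#' @param inner_k Number of inner folds (default 5).
#' @param seed Integer seed for the inner fold assignment.
#' @param feature_indices Optional parent-table column indices, recorded.
#' @return The winning `ganest_svm`, with the evaluated grid (one row per
#'   candidate with its inner balanced accuracy) attached as
#'   `$tuning_grid` and the chosen point as `$C` / `$gamma`.
#' @export
tune_svm <- function(X, y, spec = svm_spec(), inner_k = 5, seed = 1,
                     feature_indices = NULL) {
  stopifnot(inherits(spec, "svm_spec"))
  X <- as.matrix(X)
  if (inherits(y, "outcome_labels")) y <- labels_pm1(y)
  folds <- make_folds(y, k = inner_k, seed = seed, strict = FALSE)
  grid <- if (spec$kernel == "rbf") {
    expand.grid(C = sort(spec$C_grid), gamma = sort(spec$gamma_grid))
  } else {
    data.frame(C = sort(spec$C_grid), gamma = NA_real_)
  }
  # gamma varies fastest in expand.grid; reorder so C is the outer loop and
  # the first strict maximum realizes the smaller-C-then-smaller-gamma tie rule
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- numeric(length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next # inner fold left one class empty
      m <- fit_svm(X[tr, , drop = FALSE], y[tr], kernel = spec$kernel,
                   C = grid$C[g],
                   gamma = if (spec$kernel == "rbf") grid$gamma[g] else NULL)
      s <- decision_values(m, X[!tr, , drop = FALSE])
      pred[!tr] <- ifelse(s > 0, 1, -1)
    }
    perf <- summarize_performance(y, pred)
    score[g] <- perf$balanced_accuracy
  }
  best <- which.max(score) # first maximum = smallest C, then smallest gamma
  fit <- fit_svm(X, y, kernel = spec$kernel, C = grid$C[best],
                 gamma = if (spec$kernel == "rbf") grid$gamma[best] else NULL,
                 feature_indices = feature_indices)
  fit$tuning_grid <- cbind(grid, balanced_accuracy = score)
  fit$inner_balanced_accuracy <- score[best]
  fit
}
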