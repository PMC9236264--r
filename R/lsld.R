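# Least-squares linear discriminant (LSLD).
#
# The decision function is y = sum_n w_n x_n + b over the L selected
# features; (w, b) minimize the mean squared error of y against +/-1 class
# targets (+1 = improver). On singular designs (L >= n, collinear or
# constant columns) the minimum-norm least-squares solution is returned, via
# the SVD pseudoinverse of the bias-augmented design.

# standardization statistics from training rows only; zero-variance columns
# get scale 0 and are zeroed out after centering
.standardizer <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  xc <- X - rep(center, each = n)
  scale <- sqrt(colSums(xc^2) / max(1, n - 1))
  list(center = center, scale = scale)
}

.apply_standardizer <- function(X, std) {
  n <- nrow(X)
  xc <- X - rep(std$center, each = n)
  s <- ifelse(std$scale > 0, std$scale, Inf) # zero-variance -> column of zeros
  xc / rep(s, each = n)
}

# minimum-norm least squares of A z ~ y through the SVD pseudoinverse
.min_norm_lstsq <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
  keep <- sv$d > tol
  if (!any(keep)) return(numeric(ncol(A)))
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
}

# fast internal path shared with the GA fitness: returns list(w, b, mse)
.lsld_core <- function(X, y, standardize = TRUE) {
  std <- NULL
  if (standardize) {
    std <- .standardizer(X)
    X <- .apply_standardizer(X, std)
  }
  A <- cbind(X, 1)
  z <- .min_norm_lstsq(A, y)
  L <- ncol(X)
  fitted <- drop(A %*% z)
  list(w = z[seq_len(L)], b = z[L + 1L], std = std,
       mse = mean((fitted - y)^2))
}

#' Fit a least-squares linear discriminant
#'
#' Fits the linear decision function `y = sum(w * x) + b` by minimizing mean
#' squared error against the +/-1 class targets. Features are z-scored using
#' training-row statistics (stored in the model and re-applied at
#' prediction); zero-variance features are zeroed out with a message. When
#' the normal equations are singular the minimum-norm solution is returned.
#'
#' @param X Numeric matrix (subjects x selected features).
#' @param y +/-1 numeric labels, or an `outcome_labels` object.
#' @param feature_indices Optional indices of `X`'s columns in the parent
#'   table, recorded for bookkeeping.
#' @param standardize Standardize within the fit (default TRUE). Disable to
#'   fit on the raw scale.
#' @return An object of class `lsld`: `w`, `b`, `feature_indices`,
#'   `standardizer`, `training_mse`.
#' @examples
#' m <- fit_lsld(matrix(c(-1, 1)), c(-1, 1), standardize = FALSE)
#' c(m$w, m$b, m$training_mse)  # 1 0 0
#' @export
fit_lsld <- function(X, y, feature_indices = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  if (inherits(y, "outcome_labels")) y <- labels_pm1(y)
  if (nrow(X) < 2) stop_ganest("need at least 2 training rows")
  if (length(y) != nrow(X)) stop_ganest("label length mismatch")
  if (!all(y %in% c(-1, 1))) stop_ganest("labels must be coded -1 / +1")
  if (length(unique(y)) < 2) stop_ganest("training labels are single-class")
  fit <- .lsld_core(X, y, standardize = standardize)
  if (standardize && any(fit$std$scale == 0)) {
    message("zero-variance feature column(s) standardized to zero: ",
            paste(which(fit$std$scale == 0), collapse = ", "))
  }
  structure(list(w = fit$w, b = fit$b,
                 feature_indices = feature_indices %||% seq_len(ncol(X)),
                 standardizer = fit$std,
                 training_mse = fit$mse,
                 kind = "lsld"),
            class = "lsld")
}

#' @export
print.lsld <- function(x, ...) {
  cat(sprintf("<lsld> %d features, b = %.4g, training MSE = %.4g\n",
              length(x$w), x$b, x$training_mse))
  invisible(x)
}

#' Continuous decision scores of a fitted classifier
#'
#' Returns one real score per row of `X`; `sign(score)` is the predicted
#' class (positive = improver) and the scores are usable as ROC inputs.
#' Scores exactly 0 predict the negative (non-improver) class.
#'
#' @param model A fitted classifier (`lsld` or `ganest_svm`).
#' @param X Matrix restricted to the model's features (same columns, same
#'   order, as at fit time).
#' @return Numeric score vector.
#' @export
decision_values <- function(model, X) UseMethod("decision_values")

#' @export
decision_values.lsld <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) {
    stop_ganest("X has ", ncol(X), " columns; model expects ", length(model$w))
  }
  if (!is.null(model$standardizer)) {
    X <- .apply_standardizer(X, model$standardizer)
  }
  drop(X %*% model$w) + model$b
}

#' Predicted +/-1 classes from decision scores
#'
#' @inheritParams decision_values
#' @return Vector of -1/+1 predictions; ties (score exactly 0) go to -1.
#' @export
predict_class <- function(model, X) {
  ifelse(decision_values(model, X) > 0, 1, -1)
}
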