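# Linear soft-margin SVM training and recursive feature elimination.
# The ranking criterion is the squared weight w_i^2 of the linear decision
# function, the standard surrogate for the margin change caused by removing
# feature i.

#' Train a linear soft-margin SVM
#'
#' Fits a C-classification SVM with a linear kernel on binary (or numeric)
#' features. The decision function is `D(x) = w . x + b`, positive for the
#' positive class. The fit is deterministic for fixed inputs.
#'
#' @param x Numeric matrix of patterns (rows) by features (columns).
#' @param y 0/1 labels, one per row.
#' @param cost Soft-margin penalty C (default 1).
#' @param tolerance Solver termination tolerance (default 1e-6).
#' @return An object of class `linear_svm` with elements `weights`, `bias`,
#'   `margin` (`2 / ||w||`) and `cost`.
#' @export
train_linear_svm <- function(x, y, cost = 1, tolerance = 1e-6) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) abort("training data must contain both classes")
  fit <- e1071::svm(x = x, y = factor(y, levels = c(1L, 0L)),
                    kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = tolerance)
  # with scale = FALSE the SV matrix keeps every column of x; libsvm's
  # decision value is positive for whichever class appeared first in the
  # data, so orient it toward the positive class (factor level "1")
  weights <- as.numeric(drop(crossprod(fit$coefs, fit$SV)))
  bias <- -fit$rho
  if (fit$labels[1] != 1L) {
    weights <- -weights
    bias <- -bias
  }
  structure(
    list(weights = weights, bias = bias,
         margin = 2 / sqrt(sum(weights^2)), cost = cost, fit = fit),
    class = "linear_svm"
  )
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, C = %g, margin = %.4g\n",
              length(x$weights), x$cost, x$margin))
  invisible(x)
}

#' Decision values of a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Pattern matrix.
#' @param type `"decision"` for `w . x + b`, `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return Numeric decision values or integer labels.
#' @export
predict.linear_svm <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  d <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  if (type == "decision") d else as.integer(d > 0)
}

#' @method glance linear_svm
#' @export
glance.linear_svm <- function(x, ...) {
  tibble(n_features = length(x$weights), cost = x$cost,
         margin = x$margin, n_support = nrow(x$fit$SV))
}

#' Rank features by SVM recursive feature elimination
#'
#' Repeatedly trains a linear SVM and removes the feature with the smallest
#' squared weight (the one whose removal changes the margin least), until
#' `k` features survive. Ties are broken by the lowest feature index. The
#' surviving features are then ranked by the final model's squared weights.
#'
#' @param x Pattern matrix, or an [encoded_dataset()] (its labels are used
#'   and `y` must be omitted).
#' @param y 0/1 labels (ignored when `x` is an encoded dataset).
#' @param k Number of features to keep.
#' @param cost Soft-margin penalty passed to [train_linear_svm()].
#' @param step Features eliminated per round (default 1; larger values
#'   trade ranking resolution for speed).
#' @return An object of class `feature_ranking`: `selected` (the k kept
#'   features, most informative first), `order` (all features, first
#'   eliminated first), and `meanings` when available.
#' @export
rfe_rank <- function(x, y = NULL, k, cost = 1, step = 1L) {
  meanings <- NULL
  if (inherits(x, "encoded_dataset")) {
    meanings <- x$meanings
    y <- x$labels
    x <- x$patterns
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  if (k <= 0L) abort("k must be positive")
  if (k > p) abort(sprintf("k = %d exceeds the %d available features", k, p))
  remaining <- seq_len(p)
  eliminated <- integer(0)
  while (length(remaining) > k) {
    fit <- train_linear_svm(x[, remaining, drop = FALSE], y, cost = cost)
    crit <- fit$weights^2
    n_drop <- min(step, length(remaining) - k)
    worst <- remaining[order(crit, remaining)][seq_len(n_drop)]
    eliminated <- c(eliminated, worst)
    remaining <- setdiff(remaining, worst)
  }
  fit <- train_linear_svm(x[, remaining, drop = FALSE], y, cost = cost)
  crit <- fit$weights^2
  selected <- remaining[order(-crit, remaining)]
  structure(
    list(selected = selected,
         order = c(eliminated, rev(selected)),
         criterion = stats::setNames(crit, remaining),
         meanings = meanings),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> top %d of %d features: %s\n",
              length(x$selected), length(x$order),
              paste(head(x$selected, 10), collapse = ", ")))
  invisible(x)
}

#' @method tidy feature_ranking
#' @export
tidy.feature_ranking <- function(x, ...) {
  out <- tibble(rank = seq_along(x$selected), variable = x$selected)
  if (!is.null(x$meanings)) {
    out$meaning <- x$meanings$description[match(out$variable, x$meanings$index)]
  }
  out
}

#' Restrict an encoded dataset to the selected features
#'
#' Keeps the columns chosen by [rfe_rank()], in their original column
#' order, so cube positions still read left to right along the window.
#' Distinct full-width patterns often collapse to the same reduced pattern;
#' run [clean_dataset()] afterwards to merge duplicates and resolve the
#' contradictions this can create.
#'
#' @param ds An [encoded_dataset()].
#' @param ranking A `feature_ranking` (or an integer vector of column
#'   indices).
#' @return An [encoded_dataset()] over the selected variables; the meanings
#'   keep the original variable indices and gain the RFE rank.
#' @export
project_dataset <- function(ds, ranking) {
  stopifnot(inherits(ds, "encoded_dataset"))
  sel <- if (inherits(ranking, "feature_ranking")) ranking$selected else as.integer(ranking)
  if (any(sel < 1L | sel > ncol(ds$patterns))) abort("selected indices out of range")
  cols <- sort(unique(sel))
  meanings <- ds$meanings[cols, , drop = FALSE]
  if (inherits(ranking, "feature_ranking")) {
    meanings$rfe_rank <- match(cols, ranking$selected)
  }
  encoded_dataset(ds$patterns[, cols, drop = FALSE], ds$labels,
                  meanings = meanings,
                  multiplicity = ds$multiplicity,
                  provenance = ds$provenance)
}
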