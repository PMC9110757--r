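#' Radial basis function kernel
#'
#' `exp(-gamma * ||ei - ej||^2)`. Symmetric, bounded in (0, 1]; gamma = 0 is
#' allowed for the degenerate check (value 1 for every pair).
#'
#' @param ei,ej numeric vectors of equal length.
#' @param gamma non-negative kernel width parameter.
#' @return scalar kernel value.
#' @export
rbf_kernel <- function(ei, ej, gamma) {
  if (length(ei) != length(ej)) stop_invalid("rbf_kernel: dimension mismatch")
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  exp(-gamma * sum((ei - ej)^2))
}

#' Log-base-2 hyperparameter grid for the RBF support vector machine
#'
#' The defaults place cost at 2^-5, 2^-3, ..., 2^15 (exponent step 2) and
#' gamma at 2^-15, 2^-14, ..., 2^-5 (exponent step 1), the standard libsvm
#' search grid for this problem.
#'
#' @param c_exponents integer exponents for the cost parameter.
#' @param gamma_exponents integer exponents for gamma.
#' @param base grid base (> 1).
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(c_exponents = seq(-5, 15, by = 2),
                      gamma_exponents = seq(-15, -5, by = 1),
                      base = 2) {
  if (length(c_exponents) == 0 || length(gamma_exponents) == 0 || base <= 1) {
    stop_invalid("grid_spec: non-empty exponent ranges and base > 1 required")
  }
  structure(list(c_values = base^c_exponents, gamma_values = base^gamma_exponents,
                 c_exponents = c_exponents, gamma_exponents = gamma_exponents,
                 base = base),
            class = "grid_spec")
}

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    stop_invalid("labels must be 'positive'/'negative'")
  }
  factor(labels, levels = c("negative", "positive"))
}

#' Train a soft-margin RBF support vector machine
#'
#' Thin wrapper over [e1071::svm()] (libsvm) storing the cost and gamma used.
#' Features are taken as-is (no internal rescaling), so gamma acts on raw
#' feature distances as in the kernel definition.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels parallel "positive"/"negative" labels.
#' @param cost soft-margin cost parameter (> 0).
#' @param gamma RBF width (> 0).
#' @param seed integer seed (libsvm training itself is deterministic; the seed
#'   is stored for provenance).
#' @return a `svm_model` object with a [predict()] method.
#' @export
train_svm <- function(features, labels, cost = 1, gamma = 1 / ncol(features), seed = 1) {
  if (cost <= 0 || gamma <= 0) stop_invalid("cost and gamma must be positive")
  y <- as_label_factor(labels)
  if (length(unique(y)) < 2) stop_invalid("training labels contain a single class")
  if (nrow(features) != length(y)) stop_invalid("features/labels length mismatch")
  fit <- e1071::svm(x = features, y = y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(kind = "svm", fit = fit, cost = cost, gamma = gamma,
                 dim = ncol(features), seed = seed),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("svm_model: RBF, cost=%g, gamma=%g, input dim %d\n",
              x$cost, x$gamma, x$dim))
  invisible(x)
}

#' Predict labels and decision scores
#'
#' Scores are the (orientation-fixed) libsvm decision values: higher means
#' more positive-like; hard labels are the score thresholded at 0.
#'
#' @param object a `svm_model`.
#' @param features numeric matrix with the training dimensionality.
#' @param ... unused.
#' @return list with `labels` ("positive"/"negative") and numeric `scores`.
#' @export
predict.svm_model <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != object$dim) {
    stop_invalid("feature dimension %d does not match training dimension %d",
                 ncol(features), object$dim)
  }
  pred <- predict(object$fit, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[, 1]
  # libsvm orients the decision value toward the first class named in the
  # column header; flip so that positive scores mean the positive class
  pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  if (pair[1] == "negative") score <- -score
  list(labels = unname(ifelse(score > 0, "positive", "negative")),
       scores = unname(score))
}

#' Exhaustive cross-validated grid search for SVM hyperparameters
#'
#' Evaluates mean stratified k-fold cross-validation accuracy for every
#' (cost, gamma) cell and returns the best cell; ties are broken toward
#' smaller cost, then smaller gamma. The full score table is returned for
#' mesh-surface plots.
#'
#' @param features,labels training data.
#' @param grid a `grid_spec`.
#' @param cv_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `best_cost`, `best_gamma`, `best_accuracy` and `table`
#'   (data.frame cost/gamma/accuracy).
#' @export
grid_search <- function(features, labels, grid = grid_spec(), cv_folds = 5, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  y <- as_label_factor(labels)
  folds <- stratified_folds(y, cv_folds, seed)
  cells <- expand.grid(cost = grid$c_values, gamma = grid$gamma_values,
                       KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(cells)), function(i) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      test <- folds == f
      m <- train_svm(features[!test, , drop = FALSE], as.character(y[!test]),
                     cost = cells$cost[i], gamma = cells$gamma[i], seed = seed)
      p <- predict(m, features[test, , drop = FALSE])
      correct <- correct + sum(p$labels == as.character(y[test]))
    }
    correct / length(y)
  }, numeric(1))
  cells$accuracy <- acc
  ord <- order(-cells$accuracy, cells$cost, cells$gamma)
  best <- cells[ord[1], ]
  list(best_cost = best$cost, best_gamma = best$gamma,
       best_accuracy = best$accuracy, table = cells)
}

#' Binary cross-entropy loss
#'
#' Mean over samples of `-(y log h + (1-y) log(1-h))`; predictions are clipped
#' to `[eps, 1-eps]` so boundary values stay finite.
#'
#' @param labels 0/1 (or "negative"/"positive") vector.
#' @param predictions probabilities in (0,1), same length.
#' @param eps clipping constant (default 1e-12).
#' @return scalar loss (nats).
#' @export
bce_loss <- function(labels, predictions, eps = 1e-12) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as_label_factor(labels)) - 1L
  }
  if (length(labels) != length(predictions)) stop_invalid("bce_loss: length mismatch")
  if (!all(labels %in% c(0, 1))) stop_invalid("bce_loss: labels must be binary")
  h <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(h) + (1 - labels) * log(1 - h))
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain ratio of a feature split
#'
#' Information gain of the class labels given the split, divided by the
#' split's intrinsic value; entropies in bits. Degenerate splits (fewer than
#' two non-empty groups, or zero intrinsic value) return 0 by convention.
#'
#' @param labels class labels (any two-level vector).
#' @param split group assignment of each sample (factor-like).
#' @return scalar gain ratio in `[0, 1]`.
#' @export
gain_ratio <- function(labels, split) {
  if (length(labels) != length(split)) stop_invalid("gain_ratio: length mismatch")
  if (length(labels) < 2) stop_invalid("gain_ratio: need at least 2 samples")
  split <- factor(split)
  groups <- levels(droplevels(split))
  if (length(groups) < 2) return(0)
  n <- length(labels)
  h0 <- entropy_bits(table(labels))
  cond <- sum(vapply(groups, function(g) {
    idx <- split == g
    sum(idx) / n * entropy_bits(table(labels[idx]))
  }, numeric(1)))
  gain <- h0 - cond
  iv <- entropy_bits(table(split))
  if (iv <= 0) return(0)
  gain / iv
}
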