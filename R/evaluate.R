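# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds
stratified_folds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  if (min(table(labels)) < folds) stop_invalid("fewer samples in a class than folds")
  assign <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Confusion counts of a binary prediction
#'
#' @param labels_true,labels_pred parallel "positive"/"negative" vectors.
#' @return a `confusion_counts` list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels_true, labels_pred) {
  if (length(labels_true) == 0) stop_invalid("empty input")
  if (length(labels_true) != length(labels_pred)) stop_invalid("length mismatch")
  t <- as.character(labels_true); p <- as.character(labels_pred)
  ok <- c("positive", "negative")
  if (!all(t %in% ok) || !all(p %in% ok)) stop_invalid("labels must be positive/negative")
  structure(list(
    TP = sum(t == "positive" & p == "positive"),
    TN = sum(t == "negative" & p == "negative"),
    FP = sum(t == "negative" & p == "positive"),
    FN = sum(t == "positive" & p == "negative")
  ), class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Sen = TP/(TP+FN), Spe = TN/(TN+FP), Acc = (TP+TN)/total, and the Matthews
#' correlation coefficient MCC = (TP*TN - FP*FN) /
#' sqrt((TP+FN)(TN+FN)(TP+FP)(TN+FP)). When any factor of the MCC denominator
#' is zero the MCC is reported as 0 with `mcc_degenerate = TRUE` (the common
#' convention for a constant margin).
#'
#' @param cc a `confusion_counts` (or list with TP/TN/FP/FN).
#' @return list with Sen, Spe, Acc, MCC and the `mcc_degenerate` flag.
#' @export
classification_metrics <- function(cc) {
  # numeric, not integer: the MCC denominator product overflows 32-bit ints
  TP <- as.numeric(cc$TP); TN <- as.numeric(cc$TN)
  FP <- as.numeric(cc$FP); FN <- as.numeric(cc$FN)
  total <- TP + TN + FP + FN
  if (total == 0) stop_invalid("empty confusion table")
  den2 <- (TP + FN) * (TN + FN) * (TP + FP) * (TN + FP)
  degenerate <- den2 == 0
  mcc <- if (degenerate) 0 else (TP * TN - FP * FN) / sqrt(den2)
  list(
    Sen = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    Spe = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    Acc = (TP + TN) / total,
    MCC = mcc,
    mcc_degenerate = degenerate
  )
}

#' ROC and precision-recall curves with AUROC and AUPR
#'
#' Thresholds sweep the unique score values (ties collapse into a single
#' threshold). AUROC is the trapezoidal area under the ROC curve; AUPR uses
#' step interpolation (the average-precision form: sum of precision times
#' recall increment).
#'
#' @param labels_true "positive"/"negative" vector; both classes required.
#' @param scores real-valued scores, higher = more positive-like.
#' @return list with `roc` (data.frame threshold/fpr/tpr), `pr` (data.frame
#'   threshold/recall/precision), `auroc`, `aupr`.
#' @export
roc_pr <- function(labels_true, scores) {
  y <- as.character(labels_true)
  if (length(y) != length(scores)) stop_invalid("length mismatch")
  P <- sum(y == "positive"); N <- sum(y == "negative")
  if (P == 0 || N == 0) stop_invalid("both classes required for ROC/PR")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  cum_tp <- cumsum(ys == "positive")
  cum_fp <- cumsum(ys == "negative")
  # index of the last sample at each unique threshold
  last <- cumsum(as.vector(table(factor(ss, levels = thr))))
  tp <- cum_tp[last]; fp <- cum_fp[last]
  tpr <- tp / P; fpr <- fp / N
  precision <- tp / (tp + fp)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
               data.frame(threshold = thr, fpr = fpr, tpr = tpr))
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  pr <- data.frame(threshold = thr, recall = tpr, precision = precision)
  aupr <- sum(diff(c(0, tpr)) * precision)
  list(roc = roc[, c("threshold", "fpr", "tpr")], pr = pr, auroc = auroc, aupr = aupr)
}

fit_model_spec <- function(spec, features, labels, seed) {
  kind <- if (is.null(spec$kind)) "svm" else spec$kind
  if (kind != "svm") stop_invalid("unsupported model kind: %s", kind)
  cost <- if (is.null(spec$cost)) 1 else spec$cost
  gamma <- if (is.null(spec$gamma)) 1 / ncol(features) else spec$gamma
  train_svm(features, labels, cost = cost, gamma = gamma, seed = seed)
}

#' Repeated stratified cross-validation
#'
#' Runs `repeats` independent rounds of stratified k-fold cross-validation
#' (folds reshuffled per round from the seed). Within one round, held-out
#' predictions of all folds are pooled and the threshold metrics plus
#' AUROC/AUPR computed once on the pooled predictions; the report gives the
#' per-round values and their mean and standard deviation across rounds.
#'
#' @param features numeric matrix.
#' @param labels "positive"/"negative" vector.
#' @param model_spec list describing the model, e.g.
#'   `list(kind = "svm", cost = 2^9, gamma = 2^-5)`.
#' @param repeats number of rounds (default 10).
#' @param folds folds per round (default 5).
#' @param seed integer seed.
#' @return a `metrics_report`: list with `per_repeat` (data.frame), `mean`,
#'   `sd`, and the pooled predictions of the first round (`first_round`).
#' @export
repeated_cv <- function(features, labels, model_spec = list(kind = "svm"),
                        repeats = 10, folds = 5, seed = 1) {
  y <- as.character(labels)
  rows <- vector("list", repeats)
  first <- NULL
  for (r in seq_len(repeats)) {
    seed_r <- (as.numeric(seed) * 1000 + r) %% 2147483647
    fold_assign <- stratified_folds(y, folds, seed = seed_r)
    scores <- numeric(length(y))
    pred <- character(length(y))
    for (f in seq_len(folds)) {
      test <- fold_assign == f
      m <- fit_model_spec(model_spec, features[!test, , drop = FALSE], y[!test],
                          seed = seed_r)
      p <- predict(m, features[test, , drop = FALSE])
      scores[test] <- p$scores
      pred[test] <- p$labels
    }
    cc <- confusion_counts(y, pred)
    met <- classification_metrics(cc)
    curves <- roc_pr(y, scores)
    rows[[r]] <- data.frame(repeat_id = r, Sen = met$Sen, Spe = met$Spe,
                            Acc = met$Acc, MCC = met$MCC,
                            AUROC = curves$auroc, AUPR = curves$aupr)
    if (r == 1) first <- list(labels = y, pred = pred, scores = scores)
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("Sen", "Spe", "Acc", "MCC", "AUROC", "AUPR")
  structure(list(
    per_repeat = per_repeat,
    mean = colMeans(per_repeat[metric_cols]),
    sd = apply(per_repeat[metric_cols], 2, stats::sd),
    repeats = repeats, folds = folds, first_round = first
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d x %d-fold cross-validation\n", x$repeats, x$folds))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Specificity as a function of sequence length (resolution analysis)
#'
#' Samples negative-only sequences of each requested length from an
#' independent non-peak pool, encodes and classifies them, and reports the
#' fraction predicted negative (Spe). Used to probe how short an input the
#' region-level model still handles reliably.
#'
#' @param model a trained classifier (e.g. `svm_model` or `hmc_classifier`).
#' @param genome named character vector or DNAStringSet.
#' @param negative_pool interval data.frame of negative regions; must be
#'   region-disjoint from the training negatives.
#' @param multik embeddings used for encoding (ignored when `model` is an
#'   `hmc_classifier`, which carries its own).
#' @param length_grid integer vector of sequence lengths to probe.
#' @param n_per_length samples per length (default 50).
#' @param seed integer seed.
#' @param training_negatives optional interval data.frame; when supplied, any
#'   regional intersection with `negative_pool` is an error (information-leak
#'   guard).
#' @return data.frame with columns length, Spe, n (skipped lengths omitted,
#'   with a warning).
#' @export
resolution_analysis <- function(model, genome, negative_pool, multik = NULL,
                                length_grid = c(100, 200, 500, 1000, 2000, 4000),
                                n_per_length = 50, seed = 1,
                                training_negatives = NULL) {
  genome <- as_genome(genome)
  negative_pool <- check_intervals(negative_pool)
  if (!is.null(training_negatives)) {
    tn <- check_intervals(training_negatives)
    for (i in seq_len(nrow(negative_pool))) {
      if (overlaps_any(negative_pool$chrom[i], negative_pool$start[i],
                       negative_pool$end[i], tn)) {
        stop_invalid("negative pool intersects training negatives (region '%s')",
                     negative_pool$name[i])
      }
    }
  }
  if (inherits(model, "hmc_classifier")) {
    multik <- model$multik
  }
  if (is.null(multik)) stop_invalid("multik embeddings required")
  set.seed(seed)
  out <- list()
  for (len in sort(length_grid)) {
    feas <- pmax(0L, (negative_pool$end - negative_pool$start) - len + 1L)
    if (sum(feas) == 0) {
      warning(sprintf("no pool region can host length %d; skipped", len))
      next
    }
    seqs <- character(n_per_length)
    for (j in seq_len(n_per_length)) {
      pick <- sample.int(sum(feas), 1L)
      g <- which(cumsum(feas) >= pick)[1]
      offset <- pick - c(0L, cumsum(feas))[g] - 1L
      iv <- list(chrom = negative_pool$chrom[g],
                 start = negative_pool$start[g] + offset,
                 end = negative_pool$start[g] + offset + len,
                 strand = negative_pool$strand[g])
      seqs[j] <- extract_sequence(genome, iv)
    }
    enc <- encode_dataset(seqs, multik)
    p <- if (inherits(model, "hmc_classifier")) {
      predict(model$svm, enc$features)
    } else {
      predict(model, enc$features)
    }
    out[[length(out) + 1]] <- data.frame(length = len,
                                         Spe = mean(p$labels == "negative"),
                                         n = n_per_length)
  }
  do.call(rbind, out)
}
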