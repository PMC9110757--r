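test_that("confusion tallies are exhaustive and symmetric under label swap", {
  y <- rep(c("positive", "negative"), each = 5)
  cc <- confusion_counts(y, y)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 5, TN = 5, FP = 0, FN = 0))

  pred <- c(rep("negative", 5), rep("positive", 5))  # everything wrong
  cc2 <- confusion_counts(y, pred)
  expect_equal(cc2$FN, cc$TP)
  expect_equal(cc2$FP, cc$TN)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 10)
  expect_error(confusion_counts(character(0), character(0)), "empty")
  expect_error(confusion_counts(y, y[1:3]), "mismatch")
})

test_that("metrics match hand-computed values and the brute-force oracle", {
  perfect <- classification_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(perfect[c("Sen", "Spe", "Acc", "MCC")],
               list(Sen = 1, Spe = 1, Acc = 1, MCC = 1))

  m <- classification_metrics(list(TP = 40, FN = 10, TN = 35, FP = 15))
  expect_equal(m$Sen, 0.8)
  expect_equal(m$Spe, 0.7)
  expect_equal(m$Acc, 0.75)
  expect_equal(m$MCC, (40 * 35 - 15 * 10) / sqrt(50 * 45 * 55 * 50))
  expect_equal(round(m$MCC, 4), 0.5025)

  no_assoc <- classification_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(no_assoc$MCC, 0)

  degen <- classification_metrics(list(TP = 10, TN = 0, FP = 10, FN = 0))
  expect_equal(degen$MCC, 0)
  expect_true(degen$mcc_degenerate)

  # independent brute-force oracle on 1000 random confusion tables
  oracle <- function(tp, tn, fp, fn) {
    sen <- tp / (tp + fn); spe <- tn / (tn + fp)
    acc <- (tp + tn) / (tp + tn + fp + fn)
    den <- sqrt(tp + fn) * sqrt(tn + fn) * sqrt(tp + fp) * sqrt(tn + fp)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    c(sen, spe, acc, mcc)
  }
  set.seed(10)
  worst <- 0
  for (i in 1:1000) {
    v <- rpois(4, lambda = sample(c(1, 10, 100), 1))
    if (sum(v) == 0) v[1] <- 1  # at least one evaluated sample
    m <- classification_metrics(list(TP = v[1], TN = v[2], FP = v[3], FN = v[4]))
    o <- oracle(v[1], v[2], v[3], v[4])
    got <- c(m$Sen, m$Spe, m$Acc, m$MCC)
    d <- abs(got - o)
    worst <- max(worst, d[is.finite(d)])
    expect_identical(is.na(got), is.na(o))
  }
  expect_lt(worst, 1e-12)
})

test_that("accuracy is the prevalence-weighted combination of Sen and Spe", {
  set.seed(12)
  for (i in 1:50) {
    v <- rpois(4, 20) + 1
    m <- classification_metrics(list(TP = v[1], TN = v[2], FP = v[3], FN = v[4]))
    prev <- (v[1] + v[4]) / sum(v)
    expect_equal(m$Acc, prev * m$Sen + (1 - prev) * m$Spe)
  }
})

test_that("ROC/PR curves reproduce hand cases and pair-counting AUROC", {
  y <- c("positive", "negative", "positive", "negative")
  s <- c(0.9, 0.8, 0.3, 0.1)
  r <- roc_pr(y, s)
  expect_equal(r$auroc, 0.75)  # 3 of 4 positive-negative pairs ranked correctly

  perfect <- roc_pr(rep(c("positive", "negative"), each = 3), c(3, 2.5, 2, 1, 0.5, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$aupr, 1)

  anti <- roc_pr(rep(c("positive", "negative"), each = 3), c(0, 0.5, 1, 2, 2.5, 3))
  expect_equal(anti$auroc, 0)

  expect_error(roc_pr(rep("positive", 4), 1:4), "both classes")

  # Mann-Whitney pair counting on random tie-free scores
  set.seed(13)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    y <- sample(rep(c("positive", "negative"), length.out = n))
    s <- sample(seq_len(n)) / n  # tie-free
    pairs <- outer(s[y == "positive"], s[y == "negative"], ">")
    expect_equal(roc_pr(y, s)$auroc, mean(pairs))
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  set.seed(14)
  y <- sample(rep(c("positive", "negative"), 25))
  s <- rnorm(50) + (y == "positive")
  ours <- roc_pr(y, s)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y, c("negative", "positive")),
                                        predictor = s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("repeated CV partitions each round and reproduces under a seed", {
  set.seed(15)
  X <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 2), 40, 2))
  y <- rep(c("negative", "positive"), each = 40)
  rep1 <- repeated_cv(X, y, list(kind = "svm", cost = 1, gamma = 0.5),
                      repeats = 4, folds = 5, seed = 21)
  expect_equal(nrow(rep1$per_repeat), 4)
  expect_true(all(rep1$per_repeat$AUROC > 0.8))  # well-separated toy

  # every sample is tested exactly once per round: pooled preds cover all
  expect_length(rep1$first_round$scores, 80)
  expect_false(any(rep1$first_round$pred == ""))

  rep2 <- repeated_cv(X, y, list(kind = "svm", cost = 1, gamma = 0.5),
                      repeats = 4, folds = 5, seed = 21)
  expect_identical(rep1$per_repeat, rep2$per_repeat)

  expect_error(repeated_cv(X[1:6, ], y[c(1:3, 41:43)], folds = 5, seed = 1),
               "fewer samples")
})

test_that("stratified folds balance classes", {
  y <- rep(c("positive", "negative"), c(25, 25))
  f <- rna5hmc:::stratified_folds(y, 5, seed = 2)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == "positive"), 5)
    expect_equal(sum(f == k & y == "negative"), 5)
  }
})
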