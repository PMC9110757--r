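# End-to-end convenience layer: embeddings + encoder + SVM bundled into one
# region classifier object, plus the fixture pipeline the test-suite and the
# acceptance analyses run.

#' Train a region-level 5hmC classifier from a labeled dataset
#'
#' Encodes every sequence with the supplied multi-k embeddings, optionally
#' tunes (cost, gamma) by cross-validated grid search, and fits the final RBF
#' SVM on the full dataset.
#'
#' @param dataset a `labeled_dataset`.
#' @param multik a `multik_embeddings` object.
#' @param tune run [grid_search()] before the final fit (default TRUE).
#' @param grid a `grid_spec` (used when `tune = TRUE`).
#' @param cost,gamma hyperparameters used when `tune = FALSE`.
#' @param cv_folds folds for the tuning search.
#' @param seed integer seed.
#' @return an `hmc_classifier`: list with `multik`, `svm`, `cost`, `gamma`,
#'   `tuning` (grid-search result or NULL), `features`, `labels`.
#' @export
train_region_classifier <- function(dataset, multik, tune = TRUE,
                                    grid = grid_spec(), cost = 1, gamma = NULL,
                                    cv_folds = 5, seed = 1) {
  enc <- encode_dataset(dataset, multik)
  if (is.null(enc$labels)) stop_invalid("dataset must carry labels")
  tuning <- NULL
  if (tune) {
    tuning <- grid_search(enc$features, enc$labels, grid = grid,
                          cv_folds = cv_folds, seed = seed)
    cost <- tuning$best_cost
    gamma <- tuning$best_gamma
  } else if (is.null(gamma)) {
    gamma <- 1 / ncol(enc$features)
  }
  svm <- train_svm(enc$features, enc$labels, cost = cost, gamma = gamma, seed = seed)
  structure(list(multik = multik, svm = svm, cost = cost, gamma = gamma,
                 tuning = tuning, features = enc$features, labels = enc$labels),
            class = "hmc_classifier")
}

#' @export
print.hmc_classifier <- function(x, ...) {
  cat(sprintf("hmc_classifier: k = {%s}, dim %d, SVM cost=%g gamma=%g\n",
              paste(x$multik$ks, collapse = ","), x$multik$dim, x$cost, x$gamma))
  invisible(x)
}

#' @export
predict.hmc_classifier <- function(object, sequences, ...) {
  enc <- encode_dataset(sequences, object$multik)
  predict(object$svm, enc$features)
}

#' Run the full synthetic-fixture pipeline
#'
#' Generates a fixture benchmark, trains k-mer embeddings on the fixture
#' genome, encodes the benchmark, tunes and fits the SVM, and evaluates it by
#' repeated stratified cross-validation. The reduced defaults (k = 3..5,
#' dimension 20, window 5, 3 epochs) keep a full run at interactive speed
#' while exercising every stage.
#'
#' @param spec a `fixture_spec`.
#' @param ks,dim,window,epochs embedding-training configuration.
#' @param tune tune (cost, gamma) by grid search (default TRUE).
#' @param grid a `grid_spec` for the tuning search.
#' @param repeats,folds cross-validation protocol (default 10 x 5-fold).
#' @param seed integer seed (drives embeddings, tuning and fold shuffles).
#' @return list with `fixture`, `multik`, `classifier`, `report`
#'   (`metrics_report`) and `features`/`labels`.
#' @export
fixture_pipeline <- function(spec = fixture_spec(), ks = 3:5, dim = 20,
                             window = 5, epochs = 3, tune = TRUE,
                             grid = grid_spec(), repeats = 10, folds = 5,
                             seed = spec$seed) {
  fixture <- make_benchmark_fixture(spec)
  corpus <- build_corpus(fixture$genome, names(fixture$genome),
                         fragment_length = 10000, max_k = max(ks))
  multik <- train_multik_embeddings(corpus, ks = ks, dim = dim, window = window,
                                    epochs = epochs, seed = seed)
  classifier <- train_region_classifier(fixture$dataset, multik, tune = tune,
                                        grid = grid, seed = seed)
  report <- repeated_cv(classifier$features, classifier$labels,
                        model_spec = list(kind = "svm", cost = classifier$cost,
                                          gamma = classifier$gamma),
                        repeats = repeats, folds = folds, seed = seed)
  list(fixture = fixture, multik = multik, classifier = classifier,
       report = report, features = classifier$features,
       labels = classifier$labels)
}
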