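# shared builders; heavyweight pipeline runs are memoised so several test
# files can share one result

random_table <- function(k, dim, seed = 1, vocab = NULL) {
  set.seed(seed)
  if (is.null(vocab)) vocab <- all_kmers(k)
  m <- matrix(rnorm(length(vocab) * dim), length(vocab), dim,
              dimnames = list(vocab, NULL))
  new_embedding_table(k, m)
}

random_multik <- function(ks = 3:5, dim = 20, seed = 1) {
  multik_embeddings(lapply(ks, function(k) random_table(k, dim, seed + k)))
}

random_rna <- function(n, len, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

.cache <- new.env(parent = emptyenv())

# the standard signal fixture pipeline (seed 1), shared across test files
signal_pipeline <- function() {
  if (is.null(.cache$signal)) {
    .cache$signal <- fixture_pipeline(fixture_spec(seed = 1), seed = 1, repeats = 3)
  }
  .cache$signal
}
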