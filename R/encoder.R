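#' Segment a sequence into overlapping k-mers
#'
#' A sequence of length l yields exactly l-k+1 tokens; token j covers
#' positions j..j+k-1.
#'
#' @param sequence RNA (or DNA) string.
#' @param k word length.
#' @return character vector of l-k+1 tokens.
#' @export
#' @examples
#' segment_kmers("AUAGC", 3) # "AUA" "UAG" "AGC"
segment_kmers <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1, k >= 1)
  l <- nchar(sequence)
  if (l < k) stop_invalid("sequence of length %d is too short for k=%d", l, k)
  tokenize_overlapping(sequence, k)
}

# vectorized lookup of many tokens; returns matrix rows for in-vocab tokens
lookup_rows <- function(table, tokens) {
  idx <- match(canonical_dna(tokens), rownames(table$vectors))
  idx[!is.na(idx)]
}

#' Encode a sequence with one embedding table (single k)
#'
#' Mean of the embedding vectors of the sequence's in-vocabulary overlapping
#' k-mers. Out-of-vocabulary tokens (including any containing N) are skipped
#' and the divisor reduced accordingly, so the result is always a mean over
#' the tokens actually used.
#'
#' @param sequence RNA string.
#' @param table an `embedding_table`.
#' @return numeric vector of length `table$dim`.
#' @export
embed_sequence_k <- function(sequence, table) {
  stopifnot(inherits(table, "embedding_table"))
  tokens <- segment_kmers(sequence, table$k)
  rows <- lookup_rows(table, tokens)
  if (length(rows) == 0) {
    stop_invalid("sequence has no in-vocabulary %d-mer; cannot encode", table$k)
  }
  colMeans(table$vectors[rows, , drop = FALSE])
}

#' Encode a sequence as the concatenated multi-k feature vector
#'
#' For each word length k (ascending) the sequence is segmented into
#' overlapping k-mers, their embedding vectors averaged, and the per-k means
#' concatenated. With k = 3..8 and dimension 100 the feature has length 600.
#'
#' @param sequence RNA string; must be at least as long as the largest k.
#' @param multik a `multik_embeddings` object.
#' @return numeric vector of length `sum(dim)` with names `k<k>_<j>`; the
#'   block layout is stored in attribute `layout`.
#' @export
encode_sequence <- function(sequence, multik) {
  stopifnot(inherits(multik, "multik_embeddings"))
  if (nchar(sequence) < max(multik$ks)) {
    stop_invalid("sequence of length %d shorter than max k (%d)",
                 nchar(sequence), max(multik$ks))
  }
  blocks <- lapply(multik$ks, function(k) {
    embed_sequence_k(sequence, multik$tables[[as.character(k)]])
  })
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- unlist(lapply(multik$ks, function(k) {
    sprintf("k%d_%d", k, seq_len(multik$dim))
  }))
  attr(out, "layout") <- data.frame(k = multik$ks, dim = multik$dim)
  out
}

#' Encode a labeled dataset into a feature matrix
#'
#' Row i is the multi-k encoding of sequence i; row order is preserved.
#' Sequences that cannot be encoded are collected and reported in a single
#' aggregated error rather than failing one at a time.
#'
#' @param dataset a `labeled_dataset` (or plain character vector of
#'   sequences).
#' @param multik a `multik_embeddings` object.
#' @return list with `features` (n x sum(dim) matrix) and `labels` (NULL for
#'   plain sequence input).
#' @export
encode_dataset <- function(dataset, multik) {
  if (inherits(dataset, "labeled_dataset")) {
    sequences <- dataset$sequences
    labels <- dataset$labels
    ids <- if (!is.null(dataset$provenance)) dataset$provenance$name else names(sequences)
  } else {
    sequences <- as.character(dataset)
    labels <- NULL
    ids <- names(sequences)
  }
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(sequences))
  rows <- vector("list", length(sequences))
  bad <- character(0)
  for (i in seq_along(sequences)) {
    rows[i] <- list(tryCatch(encode_sequence(sequences[i], multik),
                             error = function(e) NULL))
    if (is.null(rows[[i]])) bad <- c(bad, ids[i])
  }
  if (length(bad) > 0) {
    stop_invalid("unencodable sequence(s): %s", paste(bad, collapse = ", "))
  }
  features <- do.call(rbind, rows)
  rownames(features) <- ids
  list(features = features, labels = labels)
}
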