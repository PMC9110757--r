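#' Build a genome corpus for k-mer embedding training
#'
#' Splits the selected chromosomes into consecutive non-overlapping fragments.
#' Each fragment becomes one "sentence" for the skip-gram trainer; the final
#' shorter remainder of a chromosome is kept when it is still long enough to
#' yield at least one k-mer of the largest k to be trained.
#'
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param chromosomes character vector of chromosome ids to use.
#' @param fragment_length fragment size in nt (default 10000).
#' @param max_k largest k that will be trained on this corpus; remainders
#'   shorter than this are discarded (default 8).
#' @return an object of class `kmer_corpus`: list with `fragments` (character
#'   vector, uppercase DNA) and `source_chromosomes`.
#' @export
#' @examples
#' build_corpus(c(c1 = "ACGTACGT"), "c1", fragment_length = 4, max_k = 3)
build_corpus <- function(genome, chromosomes, fragment_length = 10000, max_k = 8) {
  genome <- as_genome(genome)
  if (length(chromosomes) == 0) stop_invalid("no chromosomes selected")
  missing <- setdiff(chromosomes, names(genome))
  if (length(missing) > 0) {
    stop_invalid("chromosome(s) not found in genome: %s", paste(missing, collapse = ", "))
  }
  if (fragment_length < max_k) {
    stop_invalid("fragment_length (%d) must be >= max_k (%d)", fragment_length, max_k)
  }
  fragments <- character(0)
  for (chrom in chromosomes) {
    s <- genome[[chrom]]
    l <- nchar(s)
    starts <- seq(1L, l, by = fragment_length)
    frags <- substring(s, starts, pmin(starts + fragment_length - 1L, l))
    frags <- frags[nchar(frags) >= max_k]
    fragments <- c(fragments, frags)
  }
  if (!all(grepl("^[ACGTN]*$", fragments))) {
    stop_invalid("corpus fragments contain characters outside ACGTN")
  }
  structure(
    list(fragments = fragments, source_chromosomes = chromosomes, max_k = max_k),
    class = "kmer_corpus"
  )
}

#' @export
print.kmer_corpus <- function(x, ...) {
  cat(sprintf(
    "kmer_corpus: %d fragments, %d nt total, chromosomes: %s\n",
    length(x$fragments), sum(nchar(x$fragments)),
    paste(x$source_chromosomes, collapse = ", ")
  ))
  invisible(x)
}

#' Construct an embedding table from a matrix of vectors
#'
#' @param k word length; every rowname of `vectors` must be a length-k word
#'   over ACGT.
#' @param vectors numeric matrix, one row per k-mer, rownames = tokens.
#' @param training_meta optional list recording training provenance.
#' @return an `embedding_table`.
#' @export
new_embedding_table <- function(k, vectors, training_meta = list()) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  toks <- rownames(vectors)
  if (any(nchar(toks) != k) || !all(grepl("^[ACGT]+$", toks))) {
    stop_invalid("embedding tokens must be length-%d words over ACGT", k)
  }
  structure(
    list(k = k, dim = ncol(vectors), vectors = vectors, training_meta = training_meta),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: k=%d, dim=%d, vocabulary %d/%d\n",
              x$k, x$dim, nrow(x$vectors), 4^x$k))
  invisible(x)
}

#' Train k-mer embeddings on a genome corpus
#'
#' Trains skip-gram-with-negative-sampling embeddings on the stream of
#' overlapping k-mers of each corpus fragment. k-mers containing N are dropped
#' from the stream (the vocabulary stays within the 4^k words over ACGT).
#' Training is single-threaded and bitwise-reproducible for a fixed seed.
#'
#' @param corpus a `kmer_corpus` from [build_corpus()].
#' @param k word length.
#' @param dim embedding dimension (default 100).
#' @param window maximum context window; the effective window per position is
#'   sampled uniformly from 1..window as in word2vec (default 10).
#' @param epochs passes over the corpus (default 10).
#' @param negative number of negative samples per positive pair (default 5).
#' @param alpha,min_alpha initial and final SGD learning rate.
#' @param seed integer seed for the trainer's own RNG.
#' @return an `embedding_table`: list with `k`, `dim`, `vectors` (matrix with
#'   k-mer rownames) and `training_meta`.
#' @export
train_kmer_embeddings <- function(corpus, k, dim = 100, window = 10, epochs = 10,
                                  negative = 5, alpha = 0.025, min_alpha = 1e-4,
                                  seed = 1) {
  stopifnot(inherits(corpus, "kmer_corpus"), k >= 1, dim >= 1)
  if (length(corpus$fragments) == 0) stop_invalid("corpus is empty")
  sent_tokens <- lapply(corpus$fragments, function(f) {
    toks <- tokenize_overlapping(f, k)
    toks[!grepl("N", toks, fixed = TRUE)]
  })
  sent_tokens <- sent_tokens[lengths(sent_tokens) > 0]
  if (length(sent_tokens) == 0) stop_invalid("corpus contains no valid %d-mer", k)
  vocab <- sort(unique(unlist(sent_tokens, use.names = FALSE)))
  counts <- table(factor(unlist(sent_tokens, use.names = FALSE), levels = vocab))
  sentences <- lapply(sent_tokens, function(t) match(t, vocab) - 1L)
  vec <- .sgns_train(sentences, length(vocab), as.numeric(counts),
                     as.integer(dim), as.integer(window), as.integer(negative),
                     as.integer(epochs), alpha, min_alpha, as.integer(seed))
  rownames(vec) <- vocab
  new_embedding_table(k, vec, training_meta = list(
    window = window, epochs = epochs, negative = negative, seed = seed,
    alpha = alpha, min_alpha = min_alpha
  ))
}

#' Train a set of embedding tables over several word lengths
#'
#' Each k gets an independent skip-gram model on its own overlapping k-mer
#' stream; the downstream encoder never mixes vectors of different k in one
#' arithmetic operation, so no joint space is needed.
#'
#' @inheritParams train_kmer_embeddings
#' @param ks ascending integer vector of word lengths (default 3:8).
#' @return a `multik_embeddings` object: list of `embedding_table`s keyed by k.
#' @export
train_multik_embeddings <- function(corpus, ks = 3:8, dim = 100, window = 10,
                                    epochs = 10, negative = 5, seed = 1) {
  ks <- sort(unique(as.integer(ks)))
  tables <- lapply(seq_along(ks), function(i) {
    train_kmer_embeddings(corpus, k = ks[i], dim = dim, window = window,
                          epochs = epochs, negative = negative,
                          seed = seed + ks[i])
  })
  names(tables) <- as.character(ks)
  multik_embeddings(tables)
}

#' Bundle embedding tables into a multi-k set
#'
#' @param tables named or unnamed list of `embedding_table`s.
#' @return `multik_embeddings` object with tables sorted by ascending k, all
#'   sharing one dimension.
#' @export
multik_embeddings <- function(tables) {
  stopifnot(length(tables) > 0, all(vapply(tables, inherits, logical(1), "embedding_table")))
  ks <- vapply(tables, `[[`, numeric(1), "k")
  if (anyDuplicated(ks)) stop_invalid("duplicate k in multik set")
  tables <- tables[order(ks)]
  names(tables) <- as.character(sort(ks))
  dims <- vapply(tables, `[[`, numeric(1), "dim")
  if (length(unique(dims)) != 1) stop_invalid("all tables must share one dimension")
  structure(list(tables = tables, ks = sort(ks), dim = dims[[1]]),
            class = "multik_embeddings")
}

#' @export
print.multik_embeddings <- function(x, ...) {
  cat(sprintf("multik_embeddings: k = {%s}, dim = %d\n",
              paste(x$ks, collapse = ","), x$dim))
  invisible(x)
}

#' Look up the embedding vector of a k-mer
#'
#' The token is canonicalized (uppercased, U replaced by T) before lookup, so
#' RNA words map onto the DNA-trained vocabulary. Out-of-vocabulary tokens —
#' including any containing N — return `NULL` rather than an error.
#'
#' @param table an `embedding_table`.
#' @param token a single k-mer string (RNA or DNA alphabet).
#' @return numeric vector of length `table$dim`, or `NULL` if absent.
#' @export
#' @examples
#' tab <- new_embedding_table(3, matrix(1:6, 2, 3,
#'   dimnames = list(c("ACG", "ATA"), NULL)))
#' embedding_lookup(tab, "AUA") # same as "ATA"
embedding_lookup <- function(table, token) {
  stopifnot(inherits(table, "embedding_table"), is.character(token), length(token) == 1)
  if (nchar(token) != table$k) {
    stop_invalid("token '%s' has length %d, table expects %d", token, nchar(token), table$k)
  }
  token <- canonical_dna(token)
  i <- match(token, rownames(table$vectors))
  if (is.na(i)) return(NULL)
  table$vectors[i, ]
}

#' Write an embedding table in word2vec text format
#'
#' Header line "vocab_size dim", then one line per token: the token followed by
#' `dim` numbers, space separated.
#'
#' @param table an `embedding_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  v <- table$vectors
  lines <- c(
    sprintf("%d %d", nrow(v), ncol(v)),
    paste(rownames(v), apply(v, 1, function(r) paste(format(r, digits = 9, trim = TRUE,
                                                            scientific = FALSE),
                                                     collapse = " ")))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an embedding table in word2vec text format
#'
#' @param path input file path.
#' @param k word length; inferred from the first token when `NULL`.
#' @return an `embedding_table`.
#' @export
read_embedding_table <- function(path, k = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_invalid("malformed embedding file: %s", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2 || anyNA(suppressWarnings(as.integer(header)))) {
    stop_invalid("malformed word2vec header in %s", path)
  }
  n <- as.integer(header[1]); d <- as.integer(header[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) stop_invalid("header announces %d rows, found %d", n, length(body))
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != d + 1)) {
    stop_invalid("row(s) with wrong number of fields (expected %d values per token)", d)
  }
  toks <- vapply(parts, `[[`, character(1), 1)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (d == 1) vec <- matrix(vec, ncol = 1)
  if (anyNA(vec)) stop_invalid("non-numeric embedding values in %s", path)
  rownames(vec) <- toks
  if (is.null(k)) k <- nchar(toks[1])
  new_embedding_table(k, vec)
}

#' Write / read a multi-k embedding set as a directory of word2vec files
#'
#' Files are named `k<k>.w2v` inside `dir`.
#'
#' @param multik a `multik_embeddings` object.
#' @param dir directory (created if missing).
#' @return `dir` (write) or a `multik_embeddings` (read).
#' @export
write_multik_embeddings <- function(multik, dir) {
  stopifnot(inherits(multik, "multik_embeddings"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in multik$ks) {
    write_embedding_table(multik$tables[[as.character(k)]],
                          file.path(dir, sprintf("k%d.w2v", k)))
  }
  invisible(dir)
}

#' @rdname write_multik_embeddings
#' @export
read_multik_embeddings <- function(dir) {
  files <- list.files(dir, pattern = "^k[0-9]+\\.w2v$", full.names = TRUE)
  if (length(files) == 0) stop_invalid("no embedding files (k<k>.w2v) in %s", dir)
  tables <- lapply(files, read_embedding_table)
  multik_embeddings(tables)
}
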