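#' @useDynLib rna5hmc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats predict
NULL

# shared low-level sequence helpers; user-facing sequence work goes through
# Biostrings, these exist for hot paths on plain character vectors

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Canonicalize a nucleotide string to uppercase DNA alphabet
#'
#' Uppercases and replaces uracil (U) with thymine (T) so that RNA input can be
#' looked up against embedding vocabularies trained on a DNA corpus.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A/C/G/T/N.
#' @keywords internal
canonical_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Convert DNA strings to RNA
#' @param x character vector of DNA strings.
#' @return character vector with T replaced by U.
#' @keywords internal
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# reverse complement on plain characters (DNA alphabet, N self-complementary)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all k-mers over the DNA alphabet
#'
#' @param k word length.
#' @return character vector of the `4^k` k-mers in lexicographic order.
#' @export
#' @examples
#' length(all_kmers(5)) # 1024
all_kmers <- function(k) {
  stopifnot(k >= 1)
  alph <- c("A", "C", "G", "T")
  out <- alph
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(outer(out, alph, paste0))
    }
  }
  sort(out)
}

# normalize a genome argument (named character vector or DNAStringSet) to a
# named uppercase character vector
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == "")) {
    stop_invalid("genome must be a named character vector or DNAStringSet")
  }
  toupper(genome)
}

# overlapping k-mer tokens of a plain DNA/RNA string
tokenize_overlapping <- function(seq, k) {
  l <- nchar(seq)
  if (l < k) return(character(0))
  substring(seq, seq_len(l - k + 1), k:l)
}
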