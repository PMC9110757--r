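# Intervals are plain data.frames in BED convention: columns chrom, start,
# end, name, score, strand; coordinates 0-based half-open.

#' Construct a genomic-interval table
#'
#' @param chrom chromosome ids.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" or "-".
#' @param name optional labels (auto-generated when NULL).
#' @param score numeric score column (BED6 compatibility; default 0).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+", name = NULL, score = 0) {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep_len(strand, n)
  if (any(start < 0) || any(start >= end)) {
    stop_invalid("intervals must satisfy 0 <= start < end")
  }
  if (!all(strand %in% c("+", "-"))) stop_invalid("strand must be '+' or '-'")
  if (is.null(name)) name <- sprintf("iv%d", seq_len(n))
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = as.character(name), score = rep_len(score, n),
             strand = strand, stringsAsFactors = FALSE)
}

check_intervals <- function(x) {
  need <- c("chrom", "start", "end", "strand")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop_invalid("expected an interval data.frame with columns %s",
                 paste(need, collapse = ", "))
  }
  if (nrow(x) > 0 && (any(x$start < 0) || any(x$start >= x$end))) {
    stop_invalid("intervals must satisfy 0 <= start < end")
  }
  if (is.null(x$name)) x$name <- sprintf("iv%d", seq_len(nrow(x)))
  if (is.null(x$score)) x$score <- 0
  x
}

#' Read / write BED6 interval files
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()] that
#' convert between `GRanges` (1-based) and the package's 0-based half-open
#' interval data.frames.
#'
#' @param path BED file path.
#' @return `read_bed`: interval data.frame. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else sprintf("iv%d", seq_along(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "+"
  df
}

#' @rdname read_bed
#' @param intervals interval data.frame.
#' @export
write_bed <- function(intervals, path) {
  intervals <- check_intervals(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = intervals$strand
  )
  gr$name <- intervals$name
  gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write genome FASTA
#'
#' @param path FASTA file path.
#' @return `read_genome`: named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_genome
#' @param genome named character vector of sequences.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Extract the RNA sequence of a stranded genomic interval
#'
#' Takes the substring `[start, end)`, reverse-complements it when the strand
#' is "-", and transliterates T to U last, so the result reads 5'->3' on the
#' annotated transcript strand.
#'
#' @param genome named character vector or DNAStringSet.
#' @param interval single-row interval data.frame (or a list with chrom,
#'   start, end, strand).
#' @return RNA string of length `end - start`.
#' @export
extract_sequence <- function(genome, interval) {
  genome <- as_genome(genome)
  chrom <- as.character(interval$chrom)
  if (!chrom %in% names(genome)) stop_invalid("unknown chromosome: %s", chrom)
  start <- as.integer(interval$start); end <- as.integer(interval$end)
  if (start < 0 || start >= end) stop_invalid("invalid interval [%d,%d)", start, end)
  l <- nchar(genome[[chrom]])
  if (end > l) {
    stop_invalid("interval [%d,%d) out of bounds for %s (length %d)", start, end, chrom, l)
  }
  s <- substr(genome[[chrom]], start + 1L, end)
  if (interval$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  dna_to_rna(s)
}

#' Keep only intervals on an allowed chromosome set
#'
#' Order-preserving filter used to restrict a benchmark to high-quality
#' chromosome assemblies.
#'
#' @param intervals interval data.frame.
#' @param allowed character vector of chromosome ids to keep.
#' @return subset of `intervals`, original order preserved.
#' @export
filter_chromosomes <- function(intervals, allowed) {
  intervals <- check_intervals(intervals)
  intervals[intervals$chrom %in% allowed, , drop = FALSE]
}

# overlap test on the 0-based half-open convention
overlaps_any <- function(chrom, start, end, other) {
  same <- other$chrom == chrom
  any(same & other$start < end & other$end > start)
}

# host transcript for a peak: greatest overlap, ties to leftmost start
host_transcript <- function(peak, transcripts) {
  same <- transcripts$chrom == peak$chrom
  ov <- pmax(0L, pmin(transcripts$end, peak$end) - pmax(transcripts$start, peak$start))
  ov[!same] <- 0L
  if (all(ov == 0L)) return(NA_integer_)
  cand <- which(ov == max(ov))
  cand[order(transcripts$start[cand])][1]
}

#' Sample length-matched negative intervals inside peak-carrying transcripts
#'
#' For each peak, draws one non-peak interval of identical length on the same
#' strand from the non-peak portion of the peak's host transcript (one-vs-one
#' cropping). Placement is uniform over all feasible start positions, seeded.
#' Peaks with no feasible placement are dropped with a warning, keeping the
#' one-vs-one pairing for the remainder.
#'
#' @param transcripts,peaks interval data.frames; each peak must lie within a
#'   transcript.
#' @param seed integer seed.
#' @param exclude optional interval data.frame of additional regions negatives
#'   must not intersect (used to keep independent pools region-disjoint).
#' @return interval data.frame of negatives, one row per retained peak, with a
#'   `paired_peak` column naming the matched peak.
#' @export
sample_negatives <- function(transcripts, peaks, seed = 1, exclude = NULL) {
  transcripts <- check_intervals(transcripts)
  peaks <- check_intervals(peaks)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  blocked <- peaks[, cols]
  if (!is.null(exclude)) {
    exclude <- check_intervals(exclude)
    blocked <- rbind(blocked, exclude[, cols])
  }
  set.seed(seed)
  out <- vector("list", nrow(peaks))
  dropped <- character(0)
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    L <- pk$end - pk$start
    h <- host_transcript(pk, transcripts)
    if (is.na(h)) {
      dropped <- c(dropped, pk$name)
      next
    }
    tr <- transcripts[h, ]
    # gaps = transcript minus every blocked region on this chromosome
    blk <- blocked[blocked$chrom == tr$chrom & blocked$start < tr$end & blocked$end > tr$start, ]
    bounds <- sort(unique(c(tr$start, tr$end, pmax(tr$start, blk$start), pmin(tr$end, blk$end))))
    gs <- bounds[-length(bounds)]; ge <- bounds[-1]
    keep <- vapply(seq_along(gs), function(j) {
      !overlaps_any(tr$chrom, gs[j], ge[j], blk)
    }, logical(1))
    gs <- gs[keep]; ge <- ge[keep]
    feas <- (ge - gs) - L + 1L
    feas[feas < 0L] <- 0L
    total <- sum(feas)
    if (total == 0L) {
      dropped <- c(dropped, pk$name)
      next
    }
    pick <- sample.int(total, 1L)
    g <- which(cumsum(feas) >= pick)[1]
    offset <- pick - c(0L, cumsum(feas))[g] - 1L
    nstart <- gs[g] + offset
    out[[i]] <- data.frame(
      chrom = tr$chrom, start = nstart, end = nstart + L,
      name = paste0("neg_", pk$name), score = 0, strand = pk$strand,
      paired_peak = pk$name, stringsAsFactors = FALSE
    )
  }
  if (length(dropped) > 0) {
    warning(sprintf("no feasible negative placement for %d peak(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Build a balanced positive/negative benchmark from peaks and transcripts
#'
#' Positives are the strand-aware RNA sequences of the peak regions; negatives
#' are equally long non-peak regions sampled within the peak-carrying
#' transcripts ([sample_negatives()]). Duplicate peak intervals are kept.
#'
#' @param genome named character vector or DNAStringSet.
#' @param peaks,transcripts interval data.frames.
#' @param allowed_chroms chromosomes to keep (default: all present in
#'   `genome`).
#' @param seed integer seed for negative placement.
#' @return a `labeled_dataset`: list with `sequences`, `labels`
#'   ("positive"/"negative") and `provenance` (interval data.frame).
#' @export
build_benchmark <- function(genome, peaks, transcripts,
                            allowed_chroms = NULL, seed = 1) {
  genome <- as_genome(genome)
  peaks <- check_intervals(peaks)
  transcripts <- check_intervals(transcripts)
  if (is.null(allowed_chroms)) allowed_chroms <- names(genome)
  peaks <- filter_chromosomes(peaks, allowed_chroms)
  transcripts <- filter_chromosomes(transcripts, allowed_chroms)
  if (nrow(peaks) == 0) {
    return(labeled_dataset(character(0), character(0),
                           genomic_intervals(character(0), integer(0), integer(0))[0, ]))
  }
  if (anyDuplicated(peaks[, c("chrom", "start", "end", "strand")])) {
    message("duplicate peak intervals present; kept as-is")
  }
  negatives <- sample_negatives(transcripts, peaks, seed = seed)
  keep <- peaks$name %in% negatives$paired_peak
  peaks <- peaks[keep, , drop = FALSE]
  pos_seq <- vapply(seq_len(nrow(peaks)), function(i) {
    extract_sequence(genome, peaks[i, ])
  }, character(1))
  neg_seq <- vapply(seq_len(nrow(negatives)), function(i) {
    extract_sequence(genome, negatives[i, ])
  }, character(1))
  prov <- rbind(
    cbind(peaks[, c("chrom", "start", "end", "name", "score", "strand")], role = "peak"),
    cbind(negatives[, c("chrom", "start", "end", "name", "score", "strand")], role = "negative")
  )
  labeled_dataset(
    sequences = c(pos_seq, neg_seq),
    labels = c(rep("positive", length(pos_seq)), rep("negative", length(neg_seq))),
    provenance = prov
  )
}

#' Construct a labeled sequence dataset
#'
#' @param sequences RNA strings.
#' @param labels parallel "positive"/"negative" labels.
#' @param provenance parallel interval data.frame (optional).
#' @return a `labeled_dataset` object.
#' @export
labeled_dataset <- function(sequences, labels, provenance = NULL) {
  if (length(sequences) != length(labels)) stop_invalid("sequences and labels differ in length")
  if (!all(labels %in% c("positive", "negative"))) {
    stop_invalid("labels must be 'positive' or 'negative'")
  }
  if (length(sequences) > 0 && any(nchar(sequences) == 0)) stop_invalid("empty sequence in dataset")
  if (!is.null(provenance) && nrow(provenance) != length(sequences)) {
    stop_invalid("provenance rows must match sequences")
  }
  structure(list(sequences = as.character(sequences), labels = as.character(labels),
                 provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d sequences (%d positive / %d negative), lengths %s\n",
              length(x$sequences), sum(x$labels == "positive"),
              sum(x$labels == "negative"),
              if (length(x$sequences)) paste0(min(nchar(x$sequences)), "-",
                                              max(nchar(x$sequences)), " nt") else "-"))
  invisible(x)
}

#' Per-class sequence-length distribution
#'
#' @param dataset a `labeled_dataset`.
#' @param binwidth histogram bin width in nt (default 500).
#' @return list with `histogram` (data.frame label/bin/count) and `range`
#'   (per-class min/max).
#' @export
length_distribution <- function(dataset, binwidth = 500) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(dataset$sequences) == 0) stop_invalid("empty dataset")
  len <- nchar(dataset$sequences)
  bin <- floor(len / binwidth) * binwidth
  hist <- as.data.frame(table(label = dataset$labels, bin = bin),
                        stringsAsFactors = FALSE)
  hist$bin <- as.integer(hist$bin)
  names(hist)[names(hist) == "Freq"] <- "count"
  rng <- do.call(rbind, lapply(split(len, dataset$labels), function(l) {
    data.frame(min = min(l), max = max(l))
  }))
  rng$label <- rownames(rng)
  list(histogram = hist[hist$count > 0, ], range = rng[, c("label", "min", "max")])
}

#' Write a labeled dataset as FASTA pair plus TSV manifest
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed). Writes `positives.fa`,
#'   `negatives.fa` and `manifest.tsv`.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- dataset$provenance
  ids <- if (!is.null(prov)) prov$name else sprintf("seq%d", seq_along(dataset$sequences))
  for (lab in c("positive", "negative")) {
    idx <- which(dataset$labels == lab)
    ss <- Biostrings::RNAStringSet(dataset$sequences[idx])
    names(ss) <- ids[idx]
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(lab, "s.fa")))
  }
  manifest <- data.frame(id = ids, label = dataset$labels, stringsAsFactors = FALSE)
  if (!is.null(prov)) {
    manifest <- cbind(manifest, prov[, c("chrom", "start", "end", "strand")])
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
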