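# Seeded generators for a synthetic genome, transcript/peak annotation and
# labeled benchmark so the whole pipeline is testable without downloads.

#' Specification of a synthetic benchmark fixture
#'
#' Defaults describe the emulated study conditions: a small multi-chromosome
#' genome, one hMeRIP-style peak per transcript, right-skewed peak lengths
#' spanning 200-8000 nt (region-level labels), and a plantable 100-nt element
#' that gives positives a recoverable signature.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome (nt).
#' @param gc_fraction genome GC content.
#' @param n_transcripts number of transcripts (= number of peaks).
#' @param peak_length_range min/max peak length (nt).
#' @param peak_length_meanlog,peak_length_sdlog lognormal parameters of the
#'   peak-length draw (truncated to `peak_length_range`); the defaults give a
#'   right-skewed distribution with median ~800 nt.
#' @param motif RNA string planted once per selected positive region; the
#'   default is a 100-nt element, the scale of one immunoprecipitated
#'   fragment, i.e. of the modified context inside a peak.
#' @param motif_rate probability that a given peak receives the motif.
#' @param seed integer seed.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(n_chromosomes = 4,
                         chromosome_length = 100000,
                         gc_fraction = 0.43,
                         n_transcripts = 50,
                         peak_length_range = c(200, 8000),
                         peak_length_meanlog = log(800),
                         peak_length_sdlog = 0.8,
                         motif = paste0("UGGACUUCGAUGGACUACCGAUUGGACUGCAUCGGACUUC",
                                        "ACGGAUCUGGACUAGCAUCGUUCGGACUAAGCUGGACUCA",
                                        "GGACUAUCCGAUGGACUUGC"),
                         motif_rate = 1,
                         seed = 1) {
  if (n_chromosomes < 1 || chromosome_length < 1 || n_transcripts < 1) {
    stop_invalid("fixture sizes must be positive")
  }
  if (gc_fraction < 0 || gc_fraction > 1 || motif_rate < 0 || motif_rate > 1) {
    stop_invalid("gc_fraction and motif_rate must lie in [0,1]")
  }
  if (peak_length_range[1] < nchar(motif) || peak_length_range[1] > peak_length_range[2]) {
    stop_invalid("peak_length_range must be ascending and not shorter than the motif")
  }
  structure(list(
    n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
    gc_fraction = gc_fraction, n_transcripts = n_transcripts,
    peak_length_range = peak_length_range,
    peak_length_meanlog = peak_length_meanlog,
    peak_length_sdlog = peak_length_sdlog, motif = toupper(motif),
    motif_rate = motif_rate, seed = seed
  ), class = "fixture_spec")
}

#' Generate a random genome
#'
#' Nucleotides are drawn i.i.d. with the requested GC fraction (C and G
#' equiprobable, likewise A and T); deterministic for a fixed spec seed.
#'
#' @param spec a `fixture_spec`.
#' @return named character vector of chromosome sequences (chr1, chr2, ...).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc_fraction) / 2, C = spec$gc_fraction / 2,
         G = spec$gc_fraction / 2, T = (1 - spec$gc_fraction) / 2)
  out <- vapply(seq_len(spec$n_chromosomes), function(i) {
    paste(sample(names(p), spec$chromosome_length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(out) <- paste0("chr", seq_len(spec$n_chromosomes))
  out
}

#' Generate transcript and peak annotation for a fixture genome
#'
#' Places one peak per transcript; peak lengths follow a truncated lognormal
#' over `peak_length_range`. Each transcript is sized to guarantee, by
#' construction, room for a disjoint same-length negative region (transcript
#' length >= 2 x peak length plus slack), so negative sampling is always
#' feasible. Strands are assigned at random; transcripts do not overlap.
#'
#' @param spec a `fixture_spec`.
#' @param genome genome from [generate_genome()].
#' @return list with `transcripts` and `peaks` interval data.frames.
#' @export
generate_annotation <- function(spec, genome) {
  stopifnot(inherits(spec, "fixture_spec"))
  genome <- as_genome(genome)
  set.seed(spec$seed + 1L)
  lo <- spec$peak_length_range[1]; hi <- spec$peak_length_range[2]
  cursor <- stats::setNames(rep(0L, length(genome)), names(genome))
  cap <- nchar(genome)
  tr <- list(); pk <- list()
  for (i in seq_len(spec$n_transcripts)) {
    L <- as.integer(round(stats::rlnorm(1, spec$peak_length_meanlog,
                                        spec$peak_length_sdlog)))
    L <- max(lo, min(hi, L))
    slack <- sample(300:2000, 1)
    Tlen <- 2L * L + slack
    remaining <- cap - cursor
    chrom <- names(which.max(remaining))
    if (remaining[[chrom]] < Tlen + 100L) {
      stop_invalid("fixture genome too small to host %d transcripts", spec$n_transcripts)
    }
    tstart <- cursor[[chrom]]
    cursor[[chrom]] <- tstart + Tlen + 100L
    strand <- sample(c("+", "-"), 1)
    # keep a clear same-length gap on one side of the peak
    if (sample(c(TRUE, FALSE), 1)) {
      pstart <- tstart + sample.int(Tlen - 2L * L + 1L, 1) - 1L   # gap on the right
    } else {
      pstart <- tstart + L + sample.int(Tlen - 2L * L + 1L, 1) - 1L  # gap on the left
    }
    tr[[i]] <- data.frame(chrom = chrom, start = tstart, end = tstart + Tlen,
                          name = sprintf("tx%d", i), score = 0, strand = strand,
                          stringsAsFactors = FALSE)
    pk[[i]] <- data.frame(chrom = chrom, start = pstart, end = pstart + L,
                          name = sprintf("peak%d", i), score = 0, strand = strand,
                          stringsAsFactors = FALSE)
  }
  list(transcripts = do.call(rbind, tr), peaks = do.call(rbind, pk))
}

#' Plant a motif inside peak regions
#'
#' Writes the motif (as DNA, strand-aware: reverse-complemented for "-"
#' peaks so the transcript-strand RNA carries the motif in sense orientation)
#' at a uniform random offset inside each peak selected with probability
#' `motif_rate`.
#'
#' @param genome named character vector.
#' @param peaks interval data.frame.
#' @param motif RNA or DNA string; must fit in the shortest peak.
#' @param motif_rate planting probability per peak.
#' @param seed integer seed.
#' @return list with the modified `genome` and `n_planted`.
#' @export
plant_signal <- function(genome, peaks, motif, motif_rate = 1, seed = 1) {
  genome <- as_genome(genome)
  peaks <- check_intervals(peaks)
  dna <- canonical_dna(motif)
  m <- nchar(dna)
  if (nrow(peaks) > 0 && m > min(peaks$end - peaks$start)) {
    stop_invalid("motif (%d nt) longer than shortest peak", m)
  }
  set.seed(seed)
  n_planted <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (stats::runif(1) > motif_rate) next
    L <- peaks$end[i] - peaks$start[i]
    offset <- sample.int(L - m + 1L, 1) - 1L
    ins <- if (peaks$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    } else {
      dna
    }
    s <- genome[[peaks$chrom[i]]]
    at <- peaks$start[i] + offset
    substr(s, at + 1L, at + m) <- ins
    genome[[peaks$chrom[i]]] <- s
    n_planted <- n_planted + 1L
  }
  list(genome = genome, n_planted = n_planted)
}

#' Build a complete synthetic benchmark fixture
#'
#' Chains [generate_genome()], [generate_annotation()], [plant_signal()] and
#' [build_benchmark()]; all intermediates are returned so the fixture can
#' also be written to disk as FASTA/BED/TSV for integration tests.
#'
#' @param spec a `fixture_spec`.
#' @return list with `genome`, `transcripts`, `peaks`, `dataset`
#'   (`labeled_dataset`), `n_planted` and `spec`.
#' @export
make_benchmark_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  genome <- generate_genome(spec)
  ann <- generate_annotation(spec, genome)
  planted <- plant_signal(genome, ann$peaks, spec$motif,
                          motif_rate = spec$motif_rate, seed = spec$seed + 2L)
  dataset <- build_benchmark(planted$genome, ann$peaks, ann$transcripts,
                             seed = spec$seed + 3L)
  list(genome = planted$genome, transcripts = ann$transcripts, peaks = ann$peaks,
       dataset = dataset, n_planted = planted$n_planted, spec = spec)
}

#' Write a fixture to disk as FASTA + BED6 + benchmark files
#'
#' @param fixture result of [make_benchmark_fixture()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(fixture$genome, file.path(dir, "genome.fa"))
  write_bed(fixture$transcripts, file.path(dir, "transcripts.bed"))
  write_bed(fixture$peaks, file.path(dir, "peaks.bed"))
  write_benchmark(fixture$dataset, dir)
  invisible(dir)
}

#' Non-peak pool intervals for the independent resolution analysis
#'
#' Returns the parts of the peak-carrying transcripts covered by neither a
#' peak nor a benchmark negative, guaranteeing no regional intersection with
#' either (information-leak guard for [resolution_analysis()]).
#'
#' @param transcripts,peaks interval data.frames.
#' @param negatives benchmark negative intervals to exclude.
#' @return interval data.frame of pool regions (strand from the transcript).
#' @export
negative_pool_intervals <- function(transcripts, peaks, negatives) {
  transcripts <- check_intervals(transcripts)
  blocked <- rbind(check_intervals(peaks)[, c("chrom", "start", "end")],
                   check_intervals(negatives)[, c("chrom", "start", "end")])
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    blk <- blocked[blocked$chrom == tr$chrom & blocked$start < tr$end &
                     blocked$end > tr$start, , drop = FALSE]
    bounds <- sort(unique(c(tr$start, tr$end,
                            pmax(tr$start, blk$start), pmin(tr$end, blk$end))))
    gs <- bounds[-length(bounds)]; ge <- bounds[-1]
    for (j in seq_along(gs)) {
      if (ge[j] > gs[j] && !overlaps_any(tr$chrom, gs[j], ge[j], blk)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = tr$chrom, start = gs[j], end = ge[j],
          name = sprintf("pool_%s_%d", tr$name, j), score = 0,
          strand = tr$strand, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(genomic_intervals(character(0), integer(0), integer(0))[0, ])
  }
  do.call(rbind, out)
}
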