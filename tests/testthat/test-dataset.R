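genome1 <- c(chrA = "AACGT")

test_that("extract_sequence is strand-aware and bounds-checked", {
  iv <- genomic_intervals("chrA", 1, 4, "+")
  expect_equal(extract_sequence(genome1, iv), "ACG")
  iv_m <- genomic_intervals("chrA", 1, 4, "-")
  expect_equal(extract_sequence(genome1, iv_m), "CGU")  # revcomp(ACG) = CGT -> RNA
  expect_equal(nchar(extract_sequence(genome1, iv)), iv$end - iv$start)
  expect_error(extract_sequence(genome1, genomic_intervals("chrA", 3, 9, "+")),
               "out of bounds")
  expect_error(extract_sequence(genome1, genomic_intervals("chrZ", 0, 2, "+")),
               "unknown chromosome")
})

test_that("minus-strand extraction equals reverse complement of plus-strand", {
  set.seed(11)
  g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""))
  for (i in 1:10) {
    s <- sample(0:150, 1); e <- s + sample(10:40, 1)
    plus <- extract_sequence(g, genomic_intervals("c1", s, e, "+"))
    minus <- extract_sequence(g, genomic_intervals("c1", s, e, "-"))
    manual <- paste(rev(strsplit(chartr("ACGU", "UGCA", plus), "")[[1]]), collapse = "")
    expect_equal(minus, manual)
  }
})

test_that("filter_chromosomes keeps order and drops disallowed chromosomes", {
  iv <- genomic_intervals(c("c2", "c1", "cH", "c1"), c(0, 5, 3, 9), c(4, 8, 9, 12))
  kept <- filter_chromosomes(iv, c("c1", "c2"))
  expect_equal(kept$chrom, c("c2", "c1", "c1"))
  expect_equal(kept$start, c(0, 5, 9))
  expect_equal(nrow(filter_chromosomes(iv, character(0))), 0)
  expect_equal(filter_chromosomes(iv, unique(iv$chrom)), iv)
})

test_that("sample_negatives produces length-matched in-transcript non-peak regions", {
  tx <- genomic_intervals("c1", 0, 1000, "+", name = "tx1")
  pk <- genomic_intervals("c1", 100, 300, "+", name = "p1")
  for (seed in 1:5) {
    neg <- sample_negatives(tx, pk, seed = seed)
    expect_equal(nrow(neg), 1)
    expect_equal(neg$end - neg$start, 200)
    expect_true(neg$start >= 0 && neg$end <= 1000)
    expect_true(neg$end <= 100 || neg$start >= 300)  # disjoint from the peak
    expect_equal(neg$strand, "+")
  }
  expect_identical(sample_negatives(tx, pk, seed = 3),
                   sample_negatives(tx, pk, seed = 3))
})

test_that("peaks with no feasible placement are dropped with a warning", {
  tx <- genomic_intervals("c1", 0, 200, "+", name = "tx1")
  pk <- genomic_intervals("c1", 0, 200, "+", name = "pfull")
  expect_warning(neg <- sample_negatives(tx, pk, seed = 1), "no feasible")
  expect_null(neg)
})

test_that("benchmark construction yields balanced, pairwise length-matched classes", {
  fx <- make_benchmark_fixture(fixture_spec(n_transcripts = 12, seed = 5))
  ds <- fx$dataset
  pos_len <- nchar(ds$sequences[ds$labels == "positive"])
  neg_len <- nchar(ds$sequences[ds$labels == "negative"])
  expect_equal(length(pos_len), length(neg_len))
  expect_equal(pos_len, neg_len)  # one-vs-one cropping preserves order

  # no negative interval intersects any peak interval
  prov <- ds$provenance
  negs <- prov[prov$role == "negative", ]
  for (i in seq_len(nrow(negs))) {
    expect_false(rna5hmc:::overlaps_any(negs$chrom[i], negs$start[i],
                                        negs$end[i], fx$peaks))
  }
})

test_that("empty peak set gives an empty dataset", {
  g <- c(c1 = paste(rep("ACGT", 100), collapse = ""))
  pk <- genomic_intervals(character(0), integer(0), integer(0))[0, ]
  tx <- genomic_intervals("c1", 0, 400, "+")
  ds <- build_benchmark(g, pk, tx)
  expect_equal(length(ds$sequences), 0)
})

test_that("length distribution matches the paired construction", {
  fx <- make_benchmark_fixture(fixture_spec(n_transcripts = 10, seed = 2))
  ld <- length_distribution(fx$dataset)
  pos <- ld$histogram[ld$histogram$label == "positive", c("bin", "count")]
  neg <- ld$histogram[ld$histogram$label == "negative", c("bin", "count")]
  expect_equal(pos$count[order(pos$bin)], neg$count[order(neg$bin)])
  expect_true(all(ld$range$min >= fx$spec$peak_length_range[1]))
  expect_true(all(ld$range$max <= fx$spec$peak_length_range[2]))

  single <- labeled_dataset("ACGU", "positive")
  ld1 <- length_distribution(single)
  expect_equal(nrow(ld1$histogram), 1)
})

test_that("BED6 and FASTA round-trip through rtracklayer/Biostrings", {
  iv <- genomic_intervals(c("c1", "c2"), c(0, 10), c(5, 25),
                          strand = c("+", "-"), name = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, f)
  back <- read_bed(f)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$strand, iv$strand)
  expect_equal(back$name, iv$name)

  g <- c(chr1 = "ACGTACGTNN", chr2 = "TTTTCCCC")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, fa)
  expect_equal(read_genome(fa), g)
})
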