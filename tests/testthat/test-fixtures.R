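test_that("genome generation respects length, GC content and the seed", {
  sp <- fixture_spec(n_chromosomes = 2, chromosome_length = 10000, seed = 41)
  g <- generate_genome(sp)
  expect_length(g, 2)
  expect_true(all(nchar(g) == 10000))
  expect_identical(g, generate_genome(sp))

  sp_gc <- fixture_spec(n_chromosomes = 1, chromosome_length = 1e6,
                        gc_fraction = 0.5, seed = 42)
  g1 <- generate_genome(sp_gc)[[1]]
  gc <- sum(strsplit(g1, "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.5), 0.005)  # 3 sigma of binomial(1e6, .5) is 0.0015
})

test_that("annotation places one in-range peak inside each transcript", {
  sp <- fixture_spec(n_transcripts = 20, seed = 43)
  g <- generate_genome(sp)
  ann <- generate_annotation(sp, g)
  expect_equal(nrow(ann$transcripts), 20)
  expect_equal(nrow(ann$peaks), 20)
  for (i in 1:20) {
    tr <- ann$transcripts[i, ]; pk <- ann$peaks[i, ]
    expect_equal(pk$chrom, tr$chrom)
    expect_true(pk$start >= tr$start && pk$end <= tr$end)
    L <- pk$end - pk$start
    expect_true(L >= sp$peak_length_range[1] && L <= sp$peak_length_range[2])
    expect_equal(pk$strand, tr$strand)
  }
  # transcripts never overlap
  for (i in 1:19) for (j in (i + 1):20) {
    a <- ann$transcripts[i, ]; b <- ann$transcripts[j, ]
    expect_false(a$chrom == b$chrom && a$start < b$end && b$start < a$end)
  }
})

test_that("plant_signal honours the planting rate and the strand", {
  sp <- fixture_spec(n_transcripts = 15, seed = 44)
  g <- generate_genome(sp)
  ann <- generate_annotation(sp, g)

  none <- plant_signal(g, ann$peaks, sp$motif, motif_rate = 0, seed = 1)
  expect_equal(none$n_planted, 0L)
  expect_identical(none$genome, g)

  all_p <- plant_signal(g, ann$peaks, sp$motif, motif_rate = 1, seed = 1)
  expect_equal(all_p$n_planted, 15L)
  for (i in 1:15) {
    rna <- extract_sequence(all_p$genome, ann$peaks[i, ])
    expect_true(grepl(sp$motif, rna, fixed = TRUE))  # motif in sense orientation
  }

  expect_error(plant_signal(g, genomic_intervals("chr1", 0, 50, "+"),
                            sp$motif, 1, 1), "longer than")
})

test_that("planting count under a partial rate stays within the binomial band", {
  sp <- fixture_spec(n_transcripts = 50, chromosome_length = 200000, seed = 45)
  g <- generate_genome(sp)
  ann <- generate_annotation(sp, g)
  counts <- vapply(1:4, function(s) {
    plant_signal(g, ann$peaks, sp$motif, motif_rate = 0.5, seed = s)$n_planted
  }, integer(1))
  # each count ~ Binomial(50, .5): 3 sigma band is 25 +- 10.6
  expect_true(all(counts >= 14 & counts <= 36))
})

test_that("the complete fixture inherits every benchmark invariant", {
  fx <- make_benchmark_fixture(fixture_spec(n_transcripts = 15, seed = 46))
  ds <- fx$dataset
  expect_equal(sum(ds$labels == "positive"), sum(ds$labels == "negative"))
  pos_len <- nchar(ds$sequences[ds$labels == "positive"])
  neg_len <- nchar(ds$sequences[ds$labels == "negative"])
  expect_equal(pos_len, neg_len)
  expect_equal(fx$n_planted, 15L)

  fx2 <- make_benchmark_fixture(fixture_spec(n_transcripts = 15, seed = 46))
  expect_identical(fx$dataset$sequences, fx2$dataset$sequences)
})

test_that("fixture files round-trip as FASTA/BED/TSV", {
  fx <- make_benchmark_fixture(fixture_spec(n_transcripts = 6, seed = 47))
  d <- withr::local_tempdir()
  write_fixture(fx, d)
  expect_true(all(file.exists(file.path(d, c("genome.fa", "transcripts.bed",
                                             "peaks.bed", "positives.fa",
                                             "negatives.fa", "manifest.tsv")))))
  g <- read_genome(file.path(d, "genome.fa"))
  expect_identical(g, fx$genome)
  pk <- read_bed(file.path(d, "peaks.bed"))
  expect_equal(pk$start, fx$peaks$start)
  man <- read.delim(file.path(d, "manifest.tsv"))
  expect_equal(nrow(man), length(fx$dataset$sequences))
})

test_that("independent negative pools are region-disjoint from training intervals", {
  fx <- make_benchmark_fixture(fixture_spec(n_transcripts = 10, seed = 48))
  prov <- fx$dataset$provenance
  negs <- prov[prov$role == "negative", ]
  pool <- negative_pool_intervals(fx$transcripts, fx$peaks, negs)
  expect_gt(nrow(pool), 0)
  for (i in seq_len(nrow(pool))) {
    expect_false(rna5hmc:::overlaps_any(pool$chrom[i], pool$start[i],
                                        pool$end[i], fx$peaks))
    expect_false(rna5hmc:::overlaps_any(pool$chrom[i], pool$start[i],
                                        pool$end[i], negs))
  }
})
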