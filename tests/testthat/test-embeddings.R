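test_that("corpus fragmentation follows the non-overlapping split with remainder rule", {
  cp <- build_corpus(c(c1 = "ACGTACGT"), "c1", fragment_length = 4, max_k = 3)
  expect_equal(cp$fragments, c("ACGT", "ACGT"))

  # 10 nt, fragment 4, max k 3: remainder of 2 < max_k is dropped
  cp <- build_corpus(c(c1 = "ACGTACGTAC"), "c1", fragment_length = 4, max_k = 3)
  expect_equal(nchar(cp$fragments), c(4L, 4L))

  # remainder kept when >= max_k
  cp <- build_corpus(c(c1 = "ACGTACGTACG"), "c1", fragment_length = 4, max_k = 3)
  expect_equal(nchar(cp$fragments), c(4L, 4L, 3L))

  expect_error(build_corpus(c(c1 = "ACGT"), "c9"), "not found")
  expect_error(build_corpus(c(c1 = "ACGT"), character(0)), "no chromosomes")
})

test_that("training vocabulary is exactly the observed valid k-mers", {
  cp <- build_corpus(c(c1 = "ACGACGACG"), "c1", fragment_length = 9, max_k = 3)
  tab <- train_kmer_embeddings(cp, k = 3, dim = 4, epochs = 1, seed = 1)
  expect_setequal(rownames(tab$vectors), c("ACG", "CGA", "GAC"))
  expect_equal(tab$dim, 4)

  # N-containing k-mers never enter the vocabulary
  cp_n <- build_corpus(c(c1 = "ACGNACG"), "c1", fragment_length = 7, max_k = 3)
  tab_n <- train_kmer_embeddings(cp_n, k = 3, dim = 4, epochs = 1, seed = 1)
  expect_false(any(grepl("N", rownames(tab_n$vectors))))

  cp_all_n <- build_corpus(c(c1 = "NNNNNN"), "c1", fragment_length = 6, max_k = 3)
  expect_error(train_kmer_embeddings(cp_all_n, k = 3, dim = 4), "no valid")
})

test_that("training is bitwise deterministic under a fixed seed", {
  cp <- build_corpus(c(c1 = paste(rep("ACGTTGCA", 50), collapse = "")), "c1",
                     fragment_length = 100, max_k = 4)
  a <- train_kmer_embeddings(cp, k = 3, dim = 8, epochs = 2, seed = 42)
  b <- train_kmer_embeddings(cp, k = 3, dim = 8, epochs = 2, seed = 42)
  expect_identical(a$vectors, b$vectors)
  c <- train_kmer_embeddings(cp, k = 3, dim = 8, epochs = 2, seed = 43)
  expect_false(identical(a$vectors, c$vectors))
})

test_that("co-occurring tokens end up closer than never-co-occurring ones", {
  # AAA always co-occurs with CCC inside one sentence type; GGG lives in
  # separate sentences far away
  set.seed(5)
  s1 <- paste(rep("AAACCC", 40), collapse = "")
  s2 <- paste(rep("GGGTTT", 40), collapse = "")
  cp <- build_corpus(c(c1 = s1, c2 = s2), c("c1", "c2"),
                     fragment_length = 240, max_k = 3)
  tab <- train_kmer_embeddings(cp, k = 3, dim = 16, window = 3, epochs = 20, seed = 3)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  aaa <- embedding_lookup(tab, "AAA")
  ccc <- embedding_lookup(tab, "CCC")
  ggg <- embedding_lookup(tab, "GGG")
  expect_gt(cosine(aaa, ccc), cosine(aaa, ggg))
})

test_that("lookup canonicalizes RNA and rejects malformed tokens", {
  tab <- random_table(3, 5, seed = 2)
  expect_equal(embedding_lookup(tab, "AUA"), embedding_lookup(tab, "ATA"))
  expect_equal(embedding_lookup(tab, "aua"), embedding_lookup(tab, "ATA"))
  expect_null(embedding_lookup(random_table(3, 5, vocab = c("AAA", "CCC")), "ANA"))
  expect_error(embedding_lookup(tab, "AT"), "length")
})

test_that("word2vec text format round-trips and rejects malformed files", {
  tab <- random_table(3, 7, seed = 9, vocab = c("AAA", "ACC", "GTT"))
  f <- withr::local_tempfile(fileext = ".w2v")
  write_embedding_table(tab, f)
  lines <- readLines(f)
  expect_length(lines, 4)  # header + 3 tokens
  expect_equal(lines[1], "3 7")
  back <- read_embedding_table(f)
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-6)

  writeLines(c("2 3", "AAA 1 2 3", "CCC 1 2"), f)
  expect_error(read_embedding_table(f), "fields")
  writeLines(c("notaheader", "AAA 1 2 3"), f)
  expect_error(read_embedding_table(f), "header")
  writeLines(c("3 3", "AAA 1 2 3", "CCC 1 2 3"), f)
  expect_error(read_embedding_table(f), "rows")
})

test_that("multi-k sets keep ascending k order and a shared dimension", {
  mk <- multik_embeddings(list(random_table(5, 6), random_table(3, 6)))
  expect_equal(mk$ks, c(3, 5))
  expect_equal(names(mk$tables), c("3", "5"))
  expect_error(multik_embeddings(list(random_table(3, 6), random_table(4, 7))),
               "dimension")
  expect_error(multik_embeddings(list(random_table(3, 6), random_table(3, 6))),
               "duplicate")

  d <- withr::local_tempdir()
  write_multik_embeddings(mk, d)
  back <- read_multik_embeddings(d)
  expect_equal(back$ks, mk$ks)
  expect_equal(back$tables[["3"]]$vectors, mk$tables[["3"]]$vectors, tolerance = 1e-6)
})
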