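test_that("base codec is the lexicographic bijection a=0, c=1, g=2, t=3", {
  expect_identical(encode_base(c("a", "c", "g", "t")), c(0L, 1L, 2L, 3L))
  expect_identical(encode_base(c("A", "G")), c(0L, 2L))
  expect_identical(decode_base(encode_base(c("t", "g", "c", "a"))),
                   c("t", "g", "c", "a"))
  expect_error(encode_base("n"), "position 1")
  expect_error(encode_base(c("a", "x")), "position 2")
  expect_error(decode_base(4L), "0..3")
})

test_that("prefix_index is the strictly increasing 1-based bijection", {
  expect_identical(prefix_index("gt"), 12L)
  expect_identical(prefix_index("aa"), 1L)
  expect_identical(prefix_index("tt"), 16L)
  for (width in 2:3) {
    all_strings <- sort(apply(
      expand.grid(rep(list(DNA), width), stringsAsFactors = FALSE),
      1L, paste, collapse = ""))
    idx <- vapply(all_strings, prefix_index, integer(1), USE.NAMES = FALSE)
    expect_identical(idx, seq_len(4L^width))  # bijective and monotone
  }
  expect_error(prefix_index("gn"), "invalid DNA")
})

test_that("chunking splits into k/l pieces whose concatenation round-trips", {
  expect_identical(chunk_kmer("gcgccaggaatc", 4), c("gcgc", "cagg", "aatc"))
  expect_identical(chunk_kmer("aaaa", 4), "aaaa")
  expect_identical(chunk_kmer("acgtacgt", 4), c("acgt", "acgt"))
  set.seed(11)
  for (km in random_kmers(20, 24)) {
    for (l in c(3, 4, 6, 8, 12)) {
      ch <- chunk_kmer(km, l)
      expect_length(ch, 24 / l)
      expect_identical(paste(ch, collapse = ""), km)
    }
  }
  expect_error(chunk_kmer("acgtacgtac", 4), "not a multiple")
  expect_error(bft_new(k = 10, l = 4), "multiple")
})

test_that("prefix rotation is a left rotation with period l", {
  expect_identical(rotate_prefix("gtat"), "tatg")
  expect_identical(rotate_prefix("aaaa"), "aaaa")
  s <- "gcgc"
  for (i in 1:4) s <- rotate_prefix(s)
  expect_identical(s, "gcgc")
  set.seed(12)
  for (l in c(4, 8, 9)) {
    orig <- random_kmers(1, l)
    s <- orig
    for (i in seq_len(l)) s <- rotate_prefix(s)
    expect_identical(s, orig)
  }
  expect_error(rotate_prefix("ac"), "length")
  expect_error(rotate_prefix("acgn"), "invalid DNA")
})
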