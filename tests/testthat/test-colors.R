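test_that("color_add sets single bits idempotently", {
  cs <- color_add(NULL, 3)
  expect_identical(which(cs), 3L)
  expect_identical(color_add(cs, 3), cs)
  cs10 <- Reduce(color_add, 1:10, init = logical(0))
  expect_identical(sum(cs10), 10L)
  expect_error(color_add(NULL, 0), ">= 1")
})

test_that("color compression is lossless and never grows the footprint", {
  set.seed(51)
  k <- 12
  kmers <- unique(random_kmers(600, k))
  t <- bft_new(k, 4, capacity = 8)
  # a realistic mix: a large shared backbone plus genome-specific k-mers
  bft_insert(t, kmers, 1)
  for (col in 2:20) bft_insert(t, kmers[1:450], col)
  bft_insert(t, kmers[451:500], 21)
  before <- colors_string(bft_colors(t, kmers))
  stats <- compress_colors(t)
  expect_lte(stats$bits_after, stats$bits_before)
  expect_gt(stats$n_external, 0)
  expect_identical(colors_string(bft_colors(t, kmers)), before)
})

test_that("a widely shared wide set is externalized; unique sets are not", {
  set.seed(52)
  kmers <- unique(random_kmers(300, 12))
  shared <- bft_new(12, 4, capacity = 8)
  for (col in 1:64) bft_insert(shared, kmers, col)  # one 64-color set
  s <- compress_colors(shared)
  expect_equal(s$n_external, 1)
  expect_equal(s$n_replaced, length(kmers))
  # 64-bit sets replaced by byte indices: large saving
  expect_lt(s$bits_after, s$bits_before / 4)

  uniq <- bft_new(12, 4, capacity = 8)
  km2 <- kmers[1:100]
  bft_insert(uniq, km2, sample.int(8, 100, replace = TRUE))
  for (i in seq_along(km2)) bft_insert(uniq, km2[i], 8 + i)  # unique per k-mer
  s2 <- compress_colors(uniq)
  expect_equal(s2$n_external, 0)
  expect_identical(s2$bits_after, s2$bits_before)
})

test_that("compression is deterministic and can be re-run after more insertions", {
  set.seed(53)
  kmers <- unique(random_kmers(400, 12))
  build <- function() {
    t <- bft_new(12, 4, capacity = 8)
    for (col in 1:16) bft_insert(t, kmers[1:(25 * col)], col)
    t
  }
  t1 <- build(); t2 <- build()
  s1 <- compress_colors(t1); s2 <- compress_colors(t2)
  expect_identical(s1, s2)
  expect_identical(bft_colors(t1, kmers), bft_colors(t2, kmers))
  # grow a k-mer whose set was externalized, then recompress
  before <- bft_colors(t1, kmers[1])[[1]]
  bft_insert(t1, kmers[1], 17)
  expect_identical(bft_colors(t1, kmers[1])[[1]], c(before, 17L))
  s3 <- compress_colors(t1)
  expect_lte(s3$bits_after, s3$bits_before)
  expect_identical(bft_colors(t1, kmers[1])[[1]], c(before, 17L))
})
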