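test_that("an empty trie contains nothing and rejects malformed k-mers", {
  t <- bft_new(12, 4, capacity = 5)
  expect_false(bft_contains(t, "acgtacgtacgt"))
  expect_identical(bft_colors(t, "acgtacgtacgt")[[1]], integer(0))
  expect_error(bft_contains(t, "acgt"), "length")
  expect_error(bft_insert(t, "acgtacgtacgn", 1), "invalid DNA")
  expect_error(bft_insert(t, "acgtacgtacgt", 0), ">= 1")
})

test_that("the uncompressed root bursts exactly when its capacity is exceeded", {
  t <- bft_new(12, 4, capacity = 5, graph_mode = FALSE)
  bft_insert(t, fig_kmers[1:5], 1)
  root <- bft_root_structure(t)
  expect_length(root, 1L)
  expect_identical(root[[1]]$type, "uncompressed")
  expect_identical(root[[1]]$n, 5L)

  bft_insert(t, fig_kmers[6], 1)
  root <- bft_root_structure(t)
  expect_length(root, 1L)
  expect_identical(root[[1]]$type, "compressed")
  expect_identical(root[[1]]$q, 4L)  # four distinct first chunks
  expect_true(all(bft_contains(t, fig_kmers)))
})

test_that("re-inserting a k-mer only merges its color set", {
  t <- bft_new(12, 4, capacity = 5)
  bft_insert(t, "gcgccaggaatc", 1)
  bft_insert(t, "gcgccaggaatc", 2)
  expect_identical(bft_colors(t, "gcgccaggaatc")[[1]], c(1L, 2L))
  expect_equal(bft_info(t)$n_kmers, 1)
})

test_that("membership and colors agree with a map oracle under different insertion orders", {
  set.seed(41)
  k <- 16
  kmers <- unique(random_kmers(3000, k))
  colors <- sample.int(6, length(kmers), replace = TRUE)
  oracle <- oracle_index(kmers, colors)
  absent <- setdiff(unique(random_kmers(3000, k)), kmers)
  for (graph_mode in c(TRUE, FALSE)) {
    for (ord in list(seq_along(kmers), sample(seq_along(kmers)))) {
      t <- bft_new(k, 4, capacity = 8, graph_mode = graph_mode, seed = 2)
      bft_insert(t, kmers[ord], colors[ord])
      expect_true(all(bft_contains(t, kmers)))
      expect_false(any(bft_contains(t, absent)))
      got <- bft_colors(t, kmers[1:300])
      want <- lapply(kmers[1:300], function(x) oracle_colors(oracle, x))
      expect_identical(got, want)
    }
  }
})

test_that("bursting conserves the k-mer set and color mapping", {
  set.seed(42)
  k <- 12
  kmers <- unique(random_kmers(400, k))
  colors <- sample.int(4, length(kmers), replace = TRUE)
  t <- bft_new(k, 4, capacity = 5, seed = 7)  # tiny capacity: many bursts
  bft_insert(t, kmers, colors)
  dump <- bft_kmers(t)
  expect_setequal(dump$kmer, kmers)
  oracle <- oracle_index(kmers, colors)
  for (i in seq_along(dump$kmer))
    expect_identical(dump$colors[[i]], oracle_colors(oracle, dump$kmer[i]))
  # no uncompressed container holds more than c suffixes at rest
  expect_lte(bft_info(t)$max_uc_load, 5)
})

test_that("six suffixes sharing one chunk burst into a single-prefix container", {
  t <- bft_new(12, 4, capacity = 5, graph_mode = FALSE)
  tails <- c("aaccgtta", "cgttagct", "acgtacgt", "tttgcaca", "tgcaacga", "caggaatc")
  bft_insert(t, paste0("aaaa", tails), 1)
  root <- bft_root_structure(t)
  expect_identical(root[[1]]$type, "compressed")
  expect_identical(root[[1]]$q, 1L)
  expect_true(all(bft_contains(t, paste0("aaaa", tails))))
})

test_that("a trie at maximal depth everywhere (k == l) still answers exactly", {
  set.seed(43)
  kmers <- unique(random_kmers(200, 6))
  t <- bft_new(6, 6, capacity = 10, graph_mode = FALSE)
  bft_insert(t, kmers, 1)
  expect_true(all(bft_contains(t, kmers)))
  absent <- setdiff(unique(random_kmers(200, 6)), kmers)
  expect_false(any(bft_contains(t, absent)))
})

test_that("incremental insertion equals bulk insertion", {
  set.seed(44)
  k <- 12
  genome_a <- unique(random_kmers(500, k))
  genome_b <- unique(c(genome_a[1:50], random_kmers(450, k)))  # partial overlap
  incr <- bft_new(k, 4, capacity = 8, seed = 5)
  bft_insert(incr, genome_a, 1)
  bft_insert(incr, genome_b, 2)
  bulk <- bft_new(k, 4, capacity = 8, seed = 5)
  both <- union(genome_a, genome_b)
  bft_insert(bulk, both, 1)
  probes <- c(both, setdiff(unique(random_kmers(500, k)), both))
  expect_identical(bft_contains(incr, probes), bft_contains(bulk, probes))
  # colors reflect which genome(s) contributed
  expect_identical(
    bft_colors(incr, intersect(genome_a, genome_b)[1])[[1]], c(1L, 2L))
})
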