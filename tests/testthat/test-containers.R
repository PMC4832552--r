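test_that("hamming_weight matches a brute-force popcount", {
  expect_identical(hamming_weight(16, rep(FALSE, 16)), 0L)
  fig_pref <- seq_len(16) %in% c(4, 5, 10, 12)  # reference container + gt
  expect_identical(hamming_weight(12, fig_pref), 4L)
  set.seed(31)
  for (rep in 1:20) {
    bits <- sample(c(TRUE, FALSE), 64, replace = TRUE)
    alpha <- sample.int(64, 1)
    expect_identical(hamming_weight(alpha, bits),
                     as.integer(naive_popcount_prefix(bits, alpha)))
  }
  expect_error(hamming_weight(0, rep(TRUE, 4)), "1..4")
  expect_error(hamming_weight(5, rep(TRUE, 4)), "1..4")
})

test_that("rank_cluster finds the i-th set bit or returns |clust| + 1", {
  expect_identical(rank_cluster(3, c(TRUE, FALSE, TRUE, TRUE)), 4L)
  expect_identical(rank_cluster(4, c(TRUE, TRUE, TRUE, FALSE)), 5L)
  set.seed(32)
  for (rep in 1:20) {
    clust <- sample(c(TRUE, FALSE), 24, replace = TRUE)
    for (i in seq_len(sum(clust) + 2L))
      expect_identical(rank_cluster(i, clust), naive_rank(i, clust))
  }
  expect_error(rank_cluster(0, c(TRUE)), ">= 1")
})

test_that("uc_binary_search agrees with a linear scan on sorted suffix sets", {
  expect_identical(uc_binary_search(character(0), "acgt"),
                   list(found = FALSE, pos = 1L))
  suf <- sort(fig_kmers)
  for (s in fig_kmers) expect_true(uc_binary_search(suf, s)$found)
  set.seed(33)
  for (rep in 1:10) {
    pool <- unique(random_kmers(40, 6))
    stored <- sort(sample(pool, 20))
    for (s in sample(pool, 15)) {
      res <- uc_binary_search(stored, s)
      expect_identical(res$found, s %in% stored)
      # insertion point from a linear scan
      expect_identical(res$pos, sum(stored < s) + 1L)
    }
  }
  expect_error(uc_binary_search(c("acgt"), "ac"), "length")
})

test_that("compressed-container state is canonical regardless of insertion order", {
  set.seed(34)
  for (rep in 1:5) {
    sps <- unique(random_kmers(30, 6))
    expected <- direct_container(sps, prefix_len = 2L)
    for (shuffle in 1:3) {
      cc <- compressed_container(6, prefix_len = 2, seed = rep)
      for (sp in sample(sps)) cc_insert(cc, sp)
      got <- cc_inspect(cc)
      expect_identical(got$pref_set, expected$pref_set)
      expect_identical(got$suf, unname(expected$suf))
      expect_identical(got$clust, expected$clust)
      # bit bookkeeping: one cluster start per present prefix
      expect_identical(sum(got$clust), length(got$pref_set))
      expect_identical(got$clust[1], 1L)
    }
  }
})

test_that("cc_contains is exact against a set oracle", {
  set.seed(35)
  for (rep in 1:5) {
    pool <- unique(random_kmers(60, 6))
    stored <- sample(pool, length(pool) %/% 2)
    cc <- compressed_container(6, prefix_len = 2, m = 32L, seed = rep)
    for (sp in stored) cc_insert(cc, sp)
    for (sp in pool)
      expect_identical(cc_contains(cc, sp)$found, sp %in% stored)
  }
})

test_that("container footprint follows m + 2^lambda + q*(mu+1)", {
  cc <- compressed_container(6, prefix_len = 2, m = 64L)
  set.seed(36)
  sps <- unique(random_kmers(20, 6))
  for (i in seq_along(sps)) {
    cc_insert(cc, sps[i])
    s <- cc_inspect(cc)
    lambda <- 2 * s$prefix_len
    mu <- 2 * s$suffix_len
    expect_equal(s$footprint_bits, 64 + 2^lambda + s$q * (mu + 1))
  }
})

test_that("duplicate insertion into a compressed container is rejected", {
  cc <- compressed_container(4, prefix_len = 2)
  cc_insert(cc, "gcgc")
  expect_error(cc_insert(cc, "gcgc"), "duplicate")
})

test_that("resizing the split is a no-op when infeasible and shrinks dense containers", {
  cc1 <- compressed_container(6, prefix_len = 1)
  cc_insert(cc1, "acgtac")
  expect_false(cc_resize_split(cc1))     # q = 1: 2^lambda growth dominates
  expect_identical(cc_inspect(cc1)$prefix_len, 1L)

  set.seed(37)
  sps <- unique(random_kmers(90, 5))[1:64]
  cc2 <- compressed_container(5, prefix_len = 1, m = 32L)
  for (sp in sps) cc_insert(cc2, sp)
  before <- cc_inspect(cc2)
  arrays_bits_before <- before$footprint_bits - 32
  expect_true(cc_resize_split(cc2))
  after <- cc_inspect(cc2)
  arrays_bits_after <- after$footprint_bits - 32
  expect_lt(arrays_bits_after, arrays_bits_before)
  expect_gt(after$prefix_len, before$prefix_len)
  expect_gte(after$suffix_len, 2L)       # minimum suffix length of two
  # same stored set, same answers
  expect_setequal(cc_strings(cc2), sps)
  for (sp in sps) expect_true(cc_contains(cc2, sp)$found)
  expect_false(cc_contains(cc2, setdiff(unique(random_kmers(50, 5)), sps)[1])$found)
})
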