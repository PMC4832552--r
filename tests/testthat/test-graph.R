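test_that("an isolated k-mer has no neighbors; constructed edges are found", {
  t <- bft_new(12, 4, capacity = 5)
  x <- "acgtcgtagcta"
  bft_insert(t, x, 1)
  expect_length(successors(t, x)$kmers, 0)
  expect_length(predecessors(t, x)$kmers, 0)

  y <- paste0(substring(x, 2), "c")       # forced successor
  z <- paste0("t", substring(x, 1, 11))   # forced predecessor
  bft_insert(t, c(y, z), 2)
  expect_identical(successors(t, x)$kmers, y)
  expect_identical(predecessors(t, x)$kmers, z)
  expect_identical(successors(t, x)$colors[[1]], 2L)
  nb <- neighborhood(t, x)
  expect_identical(nb$successors$kmers, y)
  expect_identical(nb$predecessors$kmers, z)
})

test_that("traversal requires graph mode", {
  t <- bft_new(12, 4, capacity = 5, graph_mode = FALSE)
  bft_insert(t, "acgtcgtagcta", 1)
  expect_error(successors(t, "acgtcgtagcta"), "graph_mode")
  expect_error(predecessors(t, "acgtcgtagcta"), "graph_mode")
})

test_that("neighborhoods equal the 4-lookup oracle within the visit bounds", {
  set.seed(61)
  k <- 16; l <- 4
  height_max <- k / l - 1
  kmers <- unique(random_kmers(4000, k))
  # add overlapping chains so non-trivial neighborhoods exist
  chains <- unlist(lapply(random_kmers(50, k + 20), function(s)
    substring(s, 1:21, k:(k + 20))))
  kmers <- unique(c(kmers, chains))
  t <- bft_new(k, l, capacity = 8, seed = 4)
  bft_insert(t, kmers, 1)
  probes <- sample(kmers, 500)
  for (x in probes) {
    s <- successors(t, x)
    p <- predecessors(t, x)
    expect_identical(sort(s$kmers), oracle_successors(t, x))
    expect_identical(sort(p$kmers), oracle_predecessors(t, x))
    expect_lte(s$visited, 1 + height_max)
    expect_lte(p$visited, 1 + 4 * height_max)
  }
})

test_that("edges are symmetric: y in succ(x) iff x in pred(y)", {
  set.seed(62)
  base <- random_kmers(10, 30)
  kmers <- unique(unlist(lapply(base, function(s) substring(s, 1:19, 12:30))))
  t <- bft_new(12, 4, capacity = 5, seed = 3)
  bft_insert(t, kmers, 1)
  for (x in kmers) {
    for (y in successors(t, x)$kmers)
      expect_true(x %in% predecessors(t, y)$kmers)
    for (z in predecessors(t, x)$kmers)
      expect_true(x %in% successors(t, z)$kmers)
  }
})

test_that("is_branching matches the 8-lookup oracle and rejects absent k-mers", {
  set.seed(63)
  # linear chain: no branching anywhere
  s <- random_kmers(1, 40)
  chain <- substring(s, 1:29, 12:40)
  t <- bft_new(12, 4, capacity = 5, seed = 9)
  bft_insert(t, chain, 1)
  expect_false(any(vapply(chain, function(x) is_branching(t, x), logical(1))))

  # force an out-branch
  x <- chain[10]
  extra <- setdiff(paste0(substring(x, 2), DNA), chain)[1]
  bft_insert(t, extra, 1)
  expect_true(is_branching(t, x))
  expect_true(is_branching(t, x, mode = "out"))
  expect_false(is_branching(t, x, mode = "in"))
  expect_error(is_branching(t, "tttttttttttt"), "not stored")

  # randomized agreement with the brute-force degree oracle
  kmers <- unique(c(chain, random_kmers(500, 12)))
  t2 <- bft_new(12, 4, capacity = 5, seed = 10)
  bft_insert(t2, kmers, 1)
  for (x in sample(kmers, 100)) {
    out_deg <- length(oracle_successors(t2, x))
    in_deg <- length(oracle_predecessors(t2, x))
    expect_identical(is_branching(t2, x), out_deg > 1 || in_deg > 1)
  }
})
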