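test_that("the simulator is deterministic in its seed", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  a <- simulate_pangenome(d1, ref_length = 3000, n_genomes = 2,
                          reads_per_genome = 200, k = 16, seed = 7)
  b <- simulate_pangenome(d2, ref_length = 3000, n_genomes = 2,
                          reads_per_genome = 200, k = 16, seed = 7)
  expect_identical(unname(tools::md5sum(a$read_files)),
                   unname(tools::md5sum(b$read_files)))
  expect_identical(a$truth, b$truth)
  c3 <- simulate_pangenome(d3, ref_length = 3000, n_genomes = 2,
                           reads_per_genome = 200, k = 16, seed = 8)
  expect_false(identical(unname(tools::md5sum(a$read_files)),
                         unname(tools::md5sum(c3$read_files))))
})

test_that("zero mutation and error rates give identical genomes and all-color k-mers", {
  sim <- simulate_pangenome(tempfile(), ref_length = 2000, n_genomes = 3,
                            sub_rate = 0, error_rate = 0,
                            reads_per_genome = 100, k = 16, seed = 3)
  expect_length(unique(sim$genomes), 1L)
  expect_true(all(sim$truth$colors == "1,2,3"))
  # reads cover only reference k-mers
  for (f in sim$read_files)
    expect_true(all(extract_kmers(f, 16)$kmer %in% sim$truth$kmer))
})

test_that("higher substitution rates shrink the shared k-mer fraction", {
  shared_fraction <- function(rate) {
    sim <- simulate_pangenome(tempfile(), ref_length = 20000, n_genomes = 2,
                              sub_rate = rate, error_rate = 0,
                              reads_per_genome = 100, k = 16, seed = 5)
    mean(sim$truth$colors == "1,2")
  }
  expect_gt(shared_fraction(0.01), shared_fraction(0.1))
})

test_that("error-free reads at min_occ = 1 reproduce the per-genome truth sets", {
  sim <- simulate_pangenome(tempfile(), ref_length = 5000, n_genomes = 2,
                            sub_rate = 0.01, error_rate = 0,
                            reads_per_genome = 500, k = 16, seed = 9)
  for (i in 1:2)
    expect_setequal(extract_kmers(sim$read_files[i], 16)$kmer,
                    sim$genome_kmers[[i]])
})

test_that("the map oracle collapses duplicates and matches a built index", {
  empty <- oracle_index(character(0), integer(0))
  expect_identical(oracle_colors(empty, "acgt"), integer(0))
  o <- oracle_index(c("acgt", "acgt", "gggg"), c(2L, 2L, 1L))
  expect_identical(oracle_colors(o, "acgt"), 2L)

  sim <- simulate_pangenome(tempfile(), ref_length = 2000, n_genomes = 3,
                            sub_rate = 0.01, error_rate = 0,
                            reads_per_genome = 200, k = 16, seed = 13)
  t <- build_index(sim$read_files, k = 16, l = 4, capacity = 32,
                   min_occ = 1, verbose = FALSE)
  streams <- lapply(sim$read_files, function(f) extract_kmers(f, 16)$kmer)
  oracle <- oracle_index(unlist(streams), rep(1:3, lengths(streams)))
  all_km <- unique(unlist(streams))
  expect_identical(bft_colors(t, all_km),
                   lapply(all_km, function(x) oracle_colors(oracle, x)))
})
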