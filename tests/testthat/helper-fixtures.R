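# Six 12-mers whose burst (k = 12, l = 4, c = 5) reproduces the reference
# container used by the insertion arithmetic checks: four distinct first
# chunks (atcg, cagg, gcga, gcgc), three clusters under the |a|=2 split, all
# chunk prefixes lexicographically below "gt". The sixth k-mer triggers the
# burst.
fig_kmers <- c("atcgaaccgtta", "atcgcgttagct", "caggacgtacgt",
               "caggtttgcaca", "gcgatgcaacga", "gcgccaggaatc")

fig_trie <- function() {
  t <- bft_new(k = 12, l = 4, capacity = 5, graph_mode = FALSE, seed = 1)
  bft_insert(t, fig_kmers, color = 1)
  t
}

# Desk-scale simulated pan-genome: built once per test run and reused.
.desk_cache <- new.env(parent = emptyenv())

desk_fixture <- function() {
  if (is.null(.desk_cache$fix)) {
    sim <- simulate_pangenome(dir = file.path(tempdir(), "desk-pangenome"),
                              seed = 1L)
    idx <- build_index(sim$read_files, k = 32, l = 8, capacity = 248,
                       min_occ = 3, graph_mode = TRUE, seed = 1,
                       verbose = FALSE)
    .desk_cache$fix <- list(sim = sim, index = idx,
                            stored = bft_kmers(idx)$kmer)
  }
  .desk_cache$fix
}
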