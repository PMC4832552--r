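# Brute-force oracles kept deliberately independent of the implementation.

DNA <- c("a", "c", "g", "t")

random_kmers <- function(n, k) {
  vapply(seq_len(n),
         function(i) paste(sample(DNA, k, replace = TRUE), collapse = ""),
         character(1))
}

# popcount of the first alpha bits, by plain summation
naive_popcount_prefix <- function(bits, alpha) sum(bits[seq_len(alpha)])

# position of the i-th set bit, by linear scan
naive_rank <- function(i, clust) {
  pos <- which(as.logical(clust))
  if (length(pos) >= i) pos[i] else length(clust) + 1L
}

# canonical (pref, suf, clust) of a set of suffix prefixes, built directly:
# sort, group by prefix a, suffixes b in order within each group
direct_container <- function(sps, prefix_len) {
  sps <- sort(unique(sps))
  a <- substring(sps, 1L, prefix_len)
  b <- substring(sps, prefix_len + 1L)
  list(pref_set = sort(vapply(unique(a), prefix_index, integer(1),
                              USE.NAMES = FALSE)),
       suf = b,
       clust = as.integer(!duplicated(a)))
}

# neighborhood by four independent look-ups
oracle_successors <- function(t, x) {
  k <- nchar(x)
  cand <- paste0(substring(x, 2L), DNA)
  sort(cand[bft_contains(t, cand)])
}
oracle_predecessors <- function(t, x) {
  k <- nchar(x)
  cand <- paste0(DNA, substring(x, 1L, k - 1L))
  sort(cand[bft_contains(t, cand)])
}

colors_string <- function(color_list) {
  vapply(color_list, paste, character(1), collapse = ",")
}
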