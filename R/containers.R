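#' Container helper functions
#'
#' The three primitives used by container algorithms. `hamming_weight()`
#' counts the 1s in `pref[1:alpha]`; when `pref[alpha]` is set this is the
#' index of the cluster holding prefix `alpha`. `rank_cluster()` returns the
#' position of the i-th 1 in the cluster-start bit array `clust`, or
#' `length(clust) + 1` when there are fewer than `i` ones (the append
#' position). `uc_binary_search()` is the sorted search of an uncompressed
#' container: it returns whether suffix `s` is present and its (match or
#' insertion) position.
#'
#' @param alpha 1-based prefix index in `1:length(pref)`.
#' @param pref logical bit vector (the prefix-presence array).
#' @param i cluster index, `>= 1`.
#' @param clust logical bit vector of cluster starts.
#' @param sorted_suffixes character vector of suffixes in sorted order.
#' @param s suffix to search; must match the stored suffix length.
#' @return `hamming_weight()`, `rank_cluster()`: an integer;
#'   `uc_binary_search()`: `list(found = , pos = )`.
#' @examples
#' hamming_weight(12, seq_len(16) %in% c(4, 5, 10, 12))  # 4
#' rank_cluster(3, c(TRUE, FALSE, TRUE, TRUE))           # 4
#' uc_binary_search(c("ac", "gt"), "gt")
#' @export
hamming_weight <- function(alpha, pref) {
  hamming_weight_cpp(as.integer(alpha), as.logical(pref))
}

#' @rdname hamming_weight
#' @export
rank_cluster <- function(i, clust) {
  rank_cluster_cpp(as.integer(i), as.logical(clust))
}

#' @rdname hamming_weight
#' @export
uc_binary_search <- function(sorted_suffixes, s) {
  uc_binary_search_cpp(as.character(sorted_suffixes), as.character(s)[1])
}

#' Standalone compressed container
#'
#' A compressed container stores up to a burst's worth of length-`l` suffix
#' prefixes as a quartet: a Bloom filter `quer`, a `pref` bit array of
#' `4^prefix_len` bits recording which prefixes `a` occur, a `suf` array of
#' the suffix parts `b` (sorted within each cluster), and a `clust` bit array
#' marking cluster starts. Each stored string `s` is split as `s = ab` with
#' `nchar(b) >= 2`. Inside a trie, containers are created by bursts; this
#' constructor builds one directly for inspection, testing and the insertion
#' arithmetic of [cc_insert()].
#'
#' @param l length of the stored suffix prefixes.
#' @param prefix_len `|a|`, in `1:(l-2)`.
#' @param m,f,seed,restricted Bloom filter parameters (see [bloom_filter()]).
#' @return an object of class `bft_cc` (external pointer, mutated in place).
#' @seealso [cc_insert()], [cc_contains()], [cc_inspect()], [cc_resize_split()]
#' @export
compressed_container <- function(l, prefix_len = l %/% 2, m = 64L, f = 1L,
                                 seed = 1, restricted = FALSE) {
  cc_new_cpp(as.integer(l), as.integer(prefix_len), as.integer(m),
             as.integer(f), as.numeric(seed), isTRUE(restricted))
}

#' Compressed container operations
#'
#' `cc_contains()` is the exact membership test: it checks `pref[alpha]`,
#' computes the cluster index by Hamming weight and the cluster start by
#' rank, then scans the cluster comparing suffix parts. Never a false
#' positive. `cc_insert()` inserts a new suffix prefix and returns the
#' cluster index and the 1-based `suf` position it was placed at (the two
#' quantities of the `gtat` arithmetic). `cc_inspect()` exposes the internal
#' quartet; `cc_strings()` reconstructs the stored suffix prefixes;
#' `cc_resize_split()` recomputes the arrays under a larger `|a|` whenever
#' that strictly shrinks `2^lambda + q*mu`, and is a no-op otherwise.
#'
#' @param cc a `bft_cc` (from [compressed_container()] or
#'   [bft_root_container()]).
#' @param s_pref suffix prefix of length `l`.
#' @return `cc_contains()`: `list(found, cluster, pos)`; `cc_insert()`:
#'   `list(cluster, pos)`; `cc_inspect()`: a list with `q`, `pref_set` (set
#'   positions of `pref`), `suf`, `clust`, `footprint_bits` and the split
#'   parameters; `cc_strings()`: character vector; `cc_resize_split()`:
#'   `TRUE` if a resize happened.
#' @examples
#' cc <- compressed_container(4, prefix_len = 2)
#' cc_insert(cc, "atcg")
#' cc_contains(cc, "atcg")$found
#' @export
cc_contains <- function(cc, s_pref) cc_contains_cpp(cc, as.character(s_pref)[1])

#' @rdname cc_contains
#' @export
cc_insert <- function(cc, s_pref) cc_insert_cpp(cc, as.character(s_pref)[1])

#' @rdname cc_contains
#' @export
cc_inspect <- function(cc) cc_inspect_cpp(cc)

#' @rdname cc_contains
#' @export
cc_strings <- function(cc) cc_strings_cpp(cc)

#' @rdname cc_contains
#' @export
cc_resize_split <- function(cc) cc_resize_cpp(cc)

#' @export
print.bft_cc <- function(x, ...) {
  s <- cc_inspect_cpp(x)
  cat(sprintf(
    "Compressed container: q = %d, |a| = %d, |b| = %d%s, %.0f bits\n",
    s$q, s$prefix_len, s$suffix_len,
    if (s$terminal) " (terminal)" else "", s$footprint_bits))
  invisible(x)
}
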