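#' Create a Bloom Filter Trie
#'
#' The trie stores k-mers level by level in length-`l` chunks, so `k` must be
#' a multiple of `l` and the maximum height is `k/l - 1`. Each vertex is a
#' list of compressed containers plus at most one uncompressed container of
#' capacity `capacity`; an insertion that would exceed the capacity bursts
#' the uncompressed container into a compressed one with new child vertices.
#' Membership answers are exact for any workload: Bloom-filter hits are
#' always confirmed against the succinct arrays.
#'
#' With `graph_mode = TRUE` (the default) suffix prefixes are stored rotated
#' and Bloom hashing is restricted to the middle characters, enabling the
#' single-pass successor/predecessor traversal of [successors()] and
#' [predecessors()]. Set `graph_mode = FALSE` to store chunks verbatim
#' (membership-only indexes and the container arithmetic shown in
#' [cc_insert()]).
#'
#' The returned handle has reference semantics, like a connection or an
#' environment: [bft_insert()] and [compress_colors()] modify the index in
#' place and return the handle invisibly.
#'
#' @param k k-mer length.
#' @param l chunk length (`>= 3`, dividing `k`).
#' @param capacity uncompressed-container capacity `c`.
#' @param graph_mode enable prefix rotation and restricted hashing.
#' @param bf_bits Bloom filter size `m` (bits) of each compressed container.
#' @param bf_hashes number of hash functions `f`; `NULL` derives it from
#'   `bf_bits` and `capacity` (capped at 4).
#' @param seed hashing seed.
#' @param resize_factor trigger for [cc_resize_split()]: a container is
#'   re-split when `q * (mu + 1)` exceeds `resize_factor * (m + 2^lambda)`.
#' @return an object of class `bft`.
#' @examples
#' t <- bft_new(k = 12, l = 4, capacity = 5, graph_mode = FALSE)
#' bft_insert(t, c("gcgccaggaatc", "caggacgtacgt"), color = 1)
#' bft_contains(t, "gcgccaggaatc")
#' @export
bft_new <- function(k, l, capacity = 248L, graph_mode = TRUE, bf_bits = 256L,
                    bf_hashes = NULL, seed = 1, resize_factor = 8) {
  ptr <- bft_new_cpp(as.integer(k), as.integer(l), as.integer(capacity),
                     isTRUE(graph_mode), as.integer(bf_bits),
                     if (is.null(bf_hashes)) -1L else as.integer(bf_hashes),
                     as.numeric(seed), as.numeric(resize_factor))
  structure(list(ptr = ptr), class = "bft")
}

check_bft <- function(t) {
  if (!inherits(t, "bft")) stop("not a 'bft' index")
  t$ptr
}

#' Insert k-mers with colors
#'
#' Looks each k-mer up first: if present, only its color set is updated; if
#' absent, the look-up's stopping container receives it -- a sorted insert
#' for uncompressed containers, false-positive recycling for compressed ones
#' (the suffix prefix goes into the first compressed container whose Bloom
#' filter already claims it, leaving the filter untouched). Overflowing an
#' uncompressed container triggers a burst. The index is modified in place.
#'
#' @param t a `bft` index.
#' @param kmers character vector of length-`k` DNA strings.
#' @param color integer color index (`>= 1`), length 1 or `length(kmers)`.
#' @return `t`, invisibly.
#' @export
bft_insert <- function(t, kmers, color) {
  bft_insert_cpp(check_bft(t), as.character(kmers), as.integer(color))
  invisible(t)
}

#' Exact k-mer membership and colors
#'
#' `bft_contains()` walks the trie chunk by chunk (Bloom filter probe, then
#' exact container confirmation) and returns exact presence -- no false
#' positives, no false negatives. `bft_colors()` additionally dereferences
#' the color set of each present k-mer.
#'
#' @param t a `bft` index.
#' @param kmers character vector of length-`k` DNA strings.
#' @return `bft_contains()`: logical vector; `bft_colors()`: list of integer
#'   color-index vectors (empty for absent k-mers).
#' @export
bft_contains <- function(t, kmers) {
  bft_contains_cpp(check_bft(t), as.character(kmers))
}

#' @rdname bft_contains
#' @export
bft_colors <- function(t, kmers) {
  bft_colors_cpp(check_bft(t), as.character(kmers))
}

#' Index statistics
#'
#' Parameters, stored k-mer and color counts, vertex/container tallies, and
#' the footprint accounting: each compressed container is charged
#' `m + 2^lambda + q * (mu + 1)` bits, uncompressed suffixes 2 bits per
#' character, and color storage its byte-rounded sets (or external-table
#' index costs after [compress_colors()]).
#'
#' @param t a `bft` index.
#' @return a named list.
#' @export
bft_info <- function(t) {
  info <- bft_info_cpp(check_bft(t))
  info$color_names <- bft_color_names_cpp(t$ptr)
  info
}

#' Enumerate the stored k-mers
#'
#' Walks the trie and reconstructs every stored k-mer with its dereferenced
#' color set. Mostly useful for validation; order is the trie walk order.
#'
#' @param t a `bft` index.
#' @return `list(kmer = character, colors = list of integer vectors)`.
#' @export
bft_kmers <- function(t) bft_dump_cpp(check_bft(t))

#' Inspect the root vertex
#'
#' `bft_root_structure()` summarises the root's container list (type, number
#' of stored suffix prefixes `q`, split parameters, footprint).
#' `bft_root_container()` extracts a copy of the i-th compressed container as
#' a standalone `bft_cc` for use with [cc_contains()] / [cc_insert()].
#' `bft_stop_container()` reports which root container a look-up for the
#' given suffix prefix stops on (the first whose Bloom filter fires; 0 means
#' none fired, i.e. the uncompressed container decides).
#'
#' @param t a `bft` index.
#' @param i 1-based compressed-container position.
#' @param s_pref suffix prefix of length `l`.
#' @export
bft_root_structure <- function(t) bft_root_structure_cpp(check_bft(t))

#' @rdname bft_root_structure
#' @export
bft_root_container <- function(t, i = 1L) {
  bft_root_container_cpp(check_bft(t), as.integer(i))
}

#' @rdname bft_root_structure
#' @export
bft_stop_container <- function(t, s_pref) {
  bft_stop_container_cpp(check_bft(t), as.character(s_pref)[1])
}

#' Save / load an index
#'
#' Writes the complete index -- header (k, l, capacity, mode, Bloom
#' parameters, seed), vertices with their containers, color slots, the
#' external color table and the color names -- to a binary file, and reads it
#' back. The round trip is exact: the loaded index answers every query
#' identically.
#'
#' @param t a `bft` index.
#' @param path file path.
#' @return `bft_save()`: `path`, invisibly; `bft_load()`: a `bft`.
#' @export
bft_save <- function(t, path) {
  bft_save_cpp(check_bft(t), path.expand(path))
  invisible(path)
}

#' @rdname bft_save
#' @export
bft_load <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  structure(list(ptr = bft_load_cpp(path.expand(path))), class = "bft")
}

#' @export
print.bft <- function(x, ...) {
  info <- bft_info(x)
  cat(sprintf("Bloom Filter Trie (k = %d, l = %d, c = %d%s)\n",
              info$k, info$l, info$capacity,
              if (info$graph_mode) ", graph mode" else ""))
  cat(sprintf("  %s k-mers, %d color(s), %s vertices\n",
              format(info$n_kmers, big.mark = ","), info$n_colors,
              format(info$n_vertices, big.mark = ",")))
  cat(sprintf("  containers: %s compressed, %s uncompressed; ~%.2f MB + %.2f MB colors\n",
              format(info$n_compressed, big.mark = ","),
              format(info$n_uncompressed, big.mark = ","),
              info$container_bits / 8 / 2^20, info$color_bits / 8 / 2^20))
  invisible(x)
}

#' @export
summary.bft <- function(object, ...) {
  info <- bft_info(object)
  print(object)
  root <- bft_root_structure(object)
  cat("  root containers:\n")
  for (ct in root) {
    if (ct$type == "compressed")
      cat(sprintf("    compressed: q = %d, |a| = %d, |b| = %d%s\n",
                  ct$q, ct$prefix_len, ct$suffix_len,
                  if (isTRUE(ct$terminal)) " (terminal)" else ""))
    else
      cat(sprintf("    uncompressed: %d suffix(es)\n", ct$n))
  }
  if (length(info$color_names))
    cat("  colors:", paste(seq_along(info$color_names), info$color_names,
                           sep = "=", collapse = ", "), "\n")
  invisible(info)
}
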