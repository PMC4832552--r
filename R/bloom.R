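#' Seeded Bloom filter over DNA strings
#'
#' A bit array `B[1..m]` probed by `f` hash positions derived from two
#' independent seeded 64-bit hashes of the 2-bit-packed input via double
#' hashing (`h_i = h_A + i * h_B mod m`). Inserted elements are always
#' reported present (no false negatives); absent elements may collide (false
#' positives). With `restricted = TRUE` the hashes read only positions
#' `2..l-1` of the input, so all strings sharing a middle substring probe
#' identical positions -- the property graph traversal relies on.
#'
#' @param m filter length in bits.
#' @param f number of hash positions; `NULL` picks
#'   `min(4, max(1, round(log(2) * m / c)))` for capacity `c`.
#' @param seed integer hashing seed; same seed, same inputs, same bit array.
#' @param restricted hash only the middle characters (positions `2..l-1`).
#' @param c capacity used to derive `f` when `f` is `NULL`.
#' @return an object of class `bloom_filter` (external pointer, mutated in
#'   place by [bf_insert()]).
#' @examples
#' bf <- bloom_filter(64, f = 2, seed = 7)
#' bf_insert(bf, "gcgc")
#' bf_may_contain(bf, "gcgc")
#' @export
bloom_filter <- function(m, f = NULL, seed = 1, restricted = FALSE, c = 248L) {
  if (is.null(f)) f <- max(1L, min(4L, as.integer(round(log(2) * m / c))))
  bloom_new_cpp(as.integer(m), as.integer(f), as.numeric(seed),
                isTRUE(restricted))
}

#' @rdname bloom_filter
#' @param bf a `bloom_filter`.
#' @param e DNA string to insert or query.
#' @export
bf_insert <- function(bf, e) {
  for (x in as.character(e)) bloom_insert_cpp(bf, x)
  invisible(bf)
}

#' @rdname bloom_filter
#' @export
bf_may_contain <- function(bf, e) {
  vapply(as.character(e), function(x) bloom_may_contain_cpp(bf, x),
         logical(1), USE.NAMES = FALSE)
}

#' @rdname bloom_filter
#' @return `bf_positions()`: the 1-based bit positions the element hashes to;
#'   `bf_set_bits()`: positions of all set bits.
#' @export
bf_positions <- function(bf, e) bloom_positions_cpp(bf, as.character(e)[1])

#' @rdname bloom_filter
#' @export
bf_set_bits <- function(bf) bloom_set_bits_cpp(bf)

#' @export
print.bloom_filter <- function(x, ...) {
  p <- bloom_params_cpp(x)
  cat(sprintf("Bloom filter: m = %d bits, f = %d, seed = %.0f%s, %d bit(s) set\n",
              p$m, p$f, p$seed,
              if (p$restricted) ", restricted hashing" else "",
              length(bloom_set_bits_cpp(x))))
  invisible(x)
}
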