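#' Color sets
#'
#' A color set is the genome-membership record of one k-mer: a bit array in
#' which bit `i` says the k-mer occurs in genome (color) `i`. `color_add()`
#' sets a bit, growing the array as needed; it is idempotent and leaves all
#' other bits untouched. In R a color set is represented as a logical
#' vector.
#'
#' @param cs logical vector (a color set); `NULL` or `logical(0)` for the
#'   empty set.
#' @param i_color 1-based color index.
#' @return the updated logical vector.
#' @examples
#' cs <- color_add(NULL, 3)
#' which(color_add(cs, 3))  # still {3}
#' @export
color_add <- function(cs, i_color) {
  i_color <- as.integer(i_color)
  if (i_color < 1L) stop("color index must be >= 1")
  if (is.null(cs)) cs <- logical(0)
  cs <- as.logical(cs)
  if (length(cs) < i_color) cs <- c(cs, rep(FALSE, i_color - length(cs)))
  cs[i_color] <- TRUE
  cs
}

#' Compress the color sets of an index
#'
#' Many k-mers of a pan-genome share identical color sets. This pass takes a
#' census of the distinct sets with their k-mer counts, orders them by
#' decreasing total size (count times byte-rounded set size; ties broken by
#' bit-lexicographic order for reproducibility), and greedily moves a set
#' into an external array when the integer index replacing it is cheaper
#' than the set -- and the one-time table copy still leaves a net saving, so
#' total color storage never grows. K-mers whose set was externalized then
#' store only the index. Lossless: dereferenced colors are identical before
#' and after, and the pass may be re-run after further insertions.
#'
#' @param t a `bft` index (modified in place).
#' @return invisibly, a list with `n_distinct`, `n_external`, `n_replaced`,
#'   `bits_before`, `bits_after`.
#' @export
compress_colors <- function(t) {
  invisible(bft_compress_colors_cpp(check_bft(t)))
}
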