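#' 2-bit DNA encoding
#'
#' The index packs DNA into two bits per character with the lexicographic
#' mapping a=0, c=1, g=2, t=3 (case-insensitive). `encode_base()` and
#' `decode_base()` convert between characters and codes; both are bijections
#' on the 4-letter alphabet and reject anything else.
#'
#' @param ch character vector of single DNA characters.
#' @param code integer vector of 2-bit codes (0--3).
#' @return `encode_base()`: integer codes; `decode_base()`: lowercase
#'   characters.
#' @examples
#' encode_base(c("a", "g", "T"))
#' decode_base(0:3)
#' @export
encode_base <- function(ch) encode_base_cpp(as.character(ch))

#' @rdname encode_base
#' @export
decode_base <- function(code) decode_base_cpp(as.integer(code))

#' 1-based prefix index of a DNA string
#'
#' Interprets the concatenated 2-bit codes of `a` (first character most
#' significant) as an integer and returns it 1-based, so `"aa...a"` maps to 1
#' and `"tt...t"` to `4^nchar(a)`. This is the position at which the presence
#' of prefix `a` is recorded in a compressed container's `pref` bit array;
#' for example `prefix_index("gt")` is 12. Strictly increasing in the
#' lexicographic order of `a`.
#'
#' @param a non-empty DNA string (at most 14 characters).
#' @return integer position in `1:4^nchar(a)`.
#' @examples
#' prefix_index("gt")  # 12
#' prefix_index("aa")  # 1
#' @export
prefix_index <- function(a) prefix_index_cpp(as.character(a)[1])

#' Split a k-mer into length-l chunks
#'
#' The trie consumes k-mers one length-`l` chunk per level, so `k` must be a
#' multiple of `l`. The concatenation of the chunks is the original k-mer.
#'
#' @param x DNA string of length k.
#' @param l chunk length; must divide `nchar(x)`.
#' @return character vector of `k/l` chunks.
#' @examples
#' chunk_kmer("gcgccaggaatc", 4)
#' @export
chunk_kmer <- function(x, l) {
  x <- as.character(x)[1]
  l <- as.integer(l)
  k <- nchar(x)
  if (l < 1L || k %% l != 0L)
    stop("k-mer length ", k, " is not a multiple of chunk length ", l)
  starts <- seq.int(1L, k, by = l)
  substring(x, starts, starts + l - 1L)
}

#' Left-rotate a suffix prefix by one character
#'
#' Graph-traversal mode stores each length-`l` suffix prefix `s` in rotated
#' form `s[2..l] s[1]`. Combined with Bloom-filter hashing restricted to the
#' middle characters, this places all four successor (and predecessor)
#' variants of a k-mer in the same container and cluster. Applying the
#' rotation `l` times is the identity.
#'
#' @param s_pref DNA string of length at least 3.
#' @return the rotated string.
#' @examples
#' rotate_prefix("gtat")  # "tatg"
#' @export
rotate_prefix <- function(s_pref) {
  s <- as.character(s_pref)[1]
  if (nchar(s) < 3L) stop("suffix prefix must have length >= 3")
  if (grepl("[^acgtACGT]", s)) stop("invalid DNA character in suffix prefix")
  paste0(substring(s, 2L), substring(s, 1L, 1L))
}
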