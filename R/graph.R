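#' Colored de Bruijn graph traversal
#'
#' Edges of the graph are never stored: k-mer `y` is a successor of `x` iff
#' `x[2..k] == y[1..k-1]` (and symmetrically for predecessors), so each
#' k-mer has at most four of each, recovered by look-up. `successors()` and
#' `predecessors()` exploit the index structure instead of four independent
#' look-ups: all successors share `x[2..k]` and hence one root-to-vertex
#' path; with rotation and restricted hashing their four final chunks land
#' in the same container and cluster. Predecessors differ in their first
#' character, so after one shared probe at the root at most four paths are
#' walked independently. The number of trie vertices touched is therefore at
#' most `1 + height_max` for successors and `1 + 4 * height_max` for
#' predecessors, returned as `visited` for instrumentation.
#'
#' Requires an index built with `graph_mode = TRUE`.
#'
#' @param t a `bft` index in graph mode.
#' @param x a stored or candidate k-mer.
#' @return a list with `kmers` (character), `colors` (list of integer
#'   vectors, parallel to `kmers`) and `visited` (vertex count).
#' @seealso [neighborhood()], [is_branching()]
#' @export
successors <- function(t, x) {
  bft_successors_cpp(check_bft(t), as.character(x)[1])
}

#' @rdname successors
#' @export
predecessors <- function(t, x) {
  bft_predecessors_cpp(check_bft(t), as.character(x)[1])
}

#' @rdname successors
#' @return `neighborhood()`: a list with components `kmer`, `successors`,
#'   `predecessors` and `visited_vertices` (total over both directions).
#' @export
neighborhood <- function(t, x) {
  s <- successors(t, x)
  p <- predecessors(t, x)
  list(kmer = as.character(x)[1], successors = s, predecessors = p,
       visited_vertices = s$visited + p$visited)
}

#' Branching-vertex predicate
#'
#' A graph vertex is branching when it has more than one successor
#' (`mode = "out"`), more than one predecessor (`mode = "in"`), or either
#' (`mode = "either"`, the default). The k-mer must be present in the index.
#'
#' @param t a `bft` index in graph mode.
#' @param x a stored k-mer.
#' @param mode which degrees count.
#' @return logical.
#' @export
is_branching <- function(t, x, mode = c("either", "out", "in")) {
  mode <- match.arg(mode)
  x <- as.character(x)[1]
  if (!bft_contains(t, x)) stop("k-mer is not stored in the index: ", x)
  out_deg <- if (mode != "in") length(successors(t, x)$kmers) else 0L
  in_deg <- if (mode != "out") length(predecessors(t, x)$kmers) else 0L
  switch(mode,
         either = out_deg > 1L || in_deg > 1L,
         out = out_deg > 1L,
         `in` = in_deg > 1L)
}
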