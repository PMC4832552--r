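#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from the extension (`.fq`/`.fastq` vs anything else;
#' `.gz` variants accepted). Quality strings are ignored.
#'
#' @param path a single file path.
#' @return character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  base <- sub("\\.gz$", "", path, ignore.case = TRUE)
  fmt <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("malformed ", fmt, " in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  as.character(seqs, use.names = FALSE)
}

#' Extract and count k-mers
#'
#' Counts every length-`k` window over the ACGT-only stretches of the input
#' (windows containing any other character are skipped; reads shorter than
#' `k` contribute nothing) and keeps the k-mers seen at least `min_occ`
#' times -- the usual guard against k-mers born of sequencing errors.
#' Emission is lexicographic, so the result is independent of read order.
#'
#' @param x a FASTA/FASTQ file path, or a character vector of sequences.
#' @param k k-mer length.
#' @param min_occ minimum occurrence count (`>= 1`).
#' @return `data.frame(kmer, count)` in lexicographic k-mer order.
#' @examples
#' extract_kmers("acgtacgt", k = 4)
#' @export
extract_kmers <- function(x, k, min_occ = 1L) {
  if (length(x) == 1L && file.exists(x)) x <- read_sequences(x)
  res <- kmer_count_cpp(as.character(x), as.integer(k), as.integer(min_occ))
  data.frame(kmer = res$kmer, count = res$count, stringsAsFactors = FALSE)
}

#' Build an index from per-genome sequence files
#'
#' Each input file is one genome and contributes one color, in order: file
#' `i` colors its k-mers with `i`. Per file, k-mers are counted with
#' [extract_kmers()] and those passing `min_occ` are inserted. After all
#' genomes, [compress_colors()] is run. When `output` is given the index is
#' serialized there and a `<output>.colors.tsv` records the color-to-file
#' mapping.
#'
#' @param files character vector of FASTA/FASTQ paths (gzip accepted).
#' @param k,l,capacity,graph_mode,bf_bits,bf_hashes,seed,resize_factor index
#'   parameters, see [bft_new()].
#' @param min_occ per-genome minimum k-mer count, see [extract_kmers()].
#' @param output optional index file path.
#' @param verbose print per-color progress.
#' @return a `bft` index with color names set to the file base names.
#' @export
build_index <- function(files, k, l, capacity = 248L, min_occ = 1L,
                        graph_mode = TRUE, bf_bits = 256L, bf_hashes = NULL,
                        seed = 1, resize_factor = 8, output = NULL,
                        verbose = TRUE) {
  if (length(files) < 1L) stop("at least one input file is required")
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("input file(s) not found: ",
                            paste(missing, collapse = ", "))
  t <- bft_new(k = k, l = l, capacity = capacity, graph_mode = graph_mode,
               bf_bits = bf_bits, bf_hashes = bf_hashes, seed = seed,
               resize_factor = resize_factor)
  for (i in seq_along(files)) {
    km <- extract_kmers(files[i], k = k, min_occ = min_occ)
    bft_insert(t, km$kmer, i)
    if (verbose)
      message(sprintf("color %d (%s): %d distinct k-mer(s) passing min_occ = %d",
                      i, basename(files[i]), nrow(km), min_occ))
  }
  bft_set_color_names_cpp(t$ptr, basename(files))
  stats <- compress_colors(t)
  if (verbose) {
    info <- bft_info(t)
    message(sprintf("index: %.0f unique k-mer(s), %d color(s); color storage %.0f -> %.0f bits",
                    info$n_kmers, info$n_colors,
                    stats$bits_before, stats$bits_after))
  }
  if (!is.null(output)) {
    bft_save(t, output)
    write.table(
      data.frame(color = seq_along(files), file = basename(files)),
      file = paste0(output, ".colors.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  t
}

#' Batch k-mer query
#'
#' Queries one k-mer per line (or element) against the index, preserving
#' input order. Lines that are not length-`k` ACGT strings are flagged
#' invalid and skipped rather than aborting the batch.
#'
#' @param t a `bft` index.
#' @param queries a text file path (one k-mer per line) or character vector.
#' @return `data.frame(kmer, valid, present, colors)` with `colors` a
#'   comma-separated string of 1-based color indices (empty when absent); a
#'   `summary` attribute counts total/valid/present rows.
#' @export
batch_query <- function(t, queries) {
  if (length(queries) == 1L && file.exists(queries))
    queries <- readLines(queries, warn = FALSE)
  queries <- as.character(queries)
  k <- bft_info(t)$k
  valid <- nchar(queries) == k & grepl("^[acgtACGT]*$", queries)
  present <- logical(length(queries))
  colors <- character(length(queries))
  if (any(valid)) {
    cols <- bft_colors(t, queries[valid])
    present[valid] <- lengths(cols) > 0L
    colors[valid] <- vapply(cols, paste, character(1), collapse = ",")
  }
  out <- data.frame(kmer = queries, valid = valid, present = present,
                    colors = colors, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(total = length(queries),
                            valid = sum(valid),
                            present = sum(present))
  out
}
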