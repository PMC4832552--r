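#' Simulate a pan-genome with per-genome reads and a truth table
#'
#' Emulates the simulated-isolate setting used to validate the index, at
#' desk scale: one random reference sequence, `n_genomes` copies mutated by
#' independent per-base substitutions at `sub_rate` (no indels, so genome
#' coordinates stay aligned and the truth table is exact), and per genome a
#' set of length-`read_length` reads carrying substitution sequencing errors
#' at `error_rate`. Read start positions are a deterministic tiling of the
#' genome (step `read_length - k + 1`, guaranteeing every genome k-mer is
#' observed at least once) topped up with uniform random starts to
#' `reads_per_genome`.
#'
#' The truth table is computed from the genome strings, not the reads:
#' k-mer `x` has color `i` iff `x` occurs in genome `i`. Reads are written
#' as 4-line FASTQ (constant quality), one file per genome, plus a
#' `truth.tsv` with columns `kmer` and comma-separated `colors`. Same seed,
#' byte-identical outputs.
#'
#' @param dir output directory (created if needed).
#' @param ref_length reference length in bases.
#' @param n_genomes number of genomes (colors).
#' @param sub_rate per-base substitution rate between reference and genome.
#' @param read_length read length in bases.
#' @param reads_per_genome total reads per genome (tiling included).
#' @param error_rate per-base sequencing substitution error rate.
#' @param k k-mer length used for the truth table and the tiling step.
#' @param seed RNG seed.
#' @return a list with `dir`, `read_files`, `truth_file`, `truth`
#'   (`data.frame(kmer, colors)`), `genome_kmers` (per-genome character
#'   vectors), `genomes` (strings) and the parameters.
#' @export
simulate_pangenome <- function(dir = tempfile("pangenome"),
                               ref_length = 100000L, n_genomes = 5L,
                               sub_rate = 0.005, read_length = 100L,
                               reads_per_genome = 20000L, error_rate = 0.005,
                               k = 32L, seed = 1L) {
  stopifnot(ref_length >= read_length, read_length >= k,
            sub_rate >= 0, sub_rate <= 1, error_rate >= 0, error_rate <= 1,
            n_genomes >= 1, reads_per_genome >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  bases <- c("a", "c", "g", "t")
  ref <- sample(bases, ref_length, replace = TRUE)

  mutate <- function(genome, rate) {
    if (rate <= 0) return(genome)
    n_mut <- stats::rbinom(1L, length(genome), rate)
    if (n_mut == 0L) return(genome)
    pos <- sample.int(length(genome), n_mut)
    # substitute with a uniformly chosen different base
    shift <- sample.int(3L, n_mut, replace = TRUE)
    genome[pos] <- bases[((match(genome[pos], bases) - 1L + shift) %% 4L) + 1L]
    genome
  }

  sample_reads <- function(genome_str) {
    max_start <- nchar(genome_str) - read_length + 1L
    tiling <- seq.int(1L, max_start, by = read_length - k + 1L)
    if (tiling[length(tiling)] != max_start) tiling <- c(tiling, max_start)
    n_random <- max(0L, reads_per_genome - length(tiling))
    starts <- c(tiling, sample.int(max_start, n_random, replace = TRUE))
    reads <- substring(genome_str, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      total <- length(reads) * read_length
      n_err <- stats::rbinom(1L, total, error_rate)
      if (n_err > 0L) {
        flat <- sample.int(total, n_err)
        ri <- (flat - 1L) %/% read_length + 1L
        off <- (flat - 1L) %% read_length + 1L
        shift <- sample.int(3L, n_err, replace = TRUE)
        for (j in seq_len(n_err)) {
          old <- substr(reads[ri[j]], off[j], off[j])
          substr(reads[ri[j]], off[j], off[j]) <-
            bases[((match(old, bases) - 1L + shift[j]) %% 4L) + 1L]
        }
      }
    }
    reads
  }

  genomes <- character(n_genomes)
  read_files <- character(n_genomes)
  genome_kmers <- vector("list", n_genomes)
  qual <- strrep("I", read_length)
  for (i in seq_len(n_genomes)) {
    genomes[i] <- paste(mutate(ref, sub_rate), collapse = "")
    reads <- sample_reads(genomes[i])
    read_files[i] <- file.path(dir, sprintf("genome%02d.fq", i))
    fq <- rbind(sprintf("@g%d_r%d", i, seq_along(reads)), reads, "+", qual)
    writeLines(as.vector(fq), read_files[i])
    genome_kmers[[i]] <- kmer_count_cpp(genomes[i], as.integer(k), 1L)$kmer
  }

  all_kmers <- sort(unique(unlist(genome_kmers)))
  membership <- vapply(genome_kmers, function(g) all_kmers %in% g,
                       logical(length(all_kmers)))
  membership <- matrix(membership, nrow = length(all_kmers))
  colors <- apply(membership, 1L, function(r) paste(which(r), collapse = ","))
  truth <- data.frame(kmer = all_kmers, colors = colors,
                      stringsAsFactors = FALSE)
  truth_file <- file.path(dir, "truth.tsv")
  write.table(truth, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)

  list(dir = dir, read_files = read_files, truth_file = truth_file,
       truth = truth, genome_kmers = genome_kmers, genomes = genomes,
       params = list(ref_length = ref_length, n_genomes = n_genomes,
                     sub_rate = sub_rate, read_length = read_length,
                     reads_per_genome = reads_per_genome,
                     error_rate = error_rate, k = k, seed = seed))
}

#' Exact map oracle for k-mer/color streams
#'
#' Plain associative map from k-mer to its accumulated color set, used as
#' ground truth in equivalence checks against the trie. Duplicate
#' (k-mer, color) pairs collapse.
#'
#' @param kmers character vector.
#' @param colors integer vector, length 1 or `length(kmers)`.
#' @return an environment mapping k-mer to sorted integer color vector; query
#'   with [oracle_colors()].
#' @export
oracle_index <- function(kmers, colors) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  kmers <- as.character(kmers)
  colors <- as.integer(colors)
  if (length(colors) == 1L) colors <- rep(colors, length(kmers))
  for (i in seq_along(kmers)) {
    cur <- env[[kmers[i]]]
    env[[kmers[i]]] <- sort(unique(c(cur, colors[i])))
  }
  env
}

#' @rdname oracle_index
#' @param oracle an environment from `oracle_index()`.
#' @param kmer a single k-mer.
#' @return `oracle_colors()`: sorted integer vector (length 0 when absent).
#' @export
oracle_colors <- function(oracle, kmer) {
  res <- oracle[[as.character(kmer)[1]]]
  if (is.null(res)) integer(0) else res
}
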