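# bftrie

An exact, incremental, alignment-free index for **pan-genomes** stored as a
**colored de Bruijn graph**, implemented as a Bloom filter trie.

## The problem

Large sequencing projects produce tens to thousands of genomes per species —
a highly redundant collection of very similar sequences. A practical way to
store and query such a pan-genome is to decompose every genome into its
*k*-mers (substrings of fixed length *k* over `{a,c,g,t}`) and annotate each
*k*-mer with the set of genomes ("colors") it occurs in. The resulting
colored de Bruijn graph needs no alignment and no reference, and its edges
need never be stored: *k*-mer `y` follows `x` exactly when
`x[2..k] == y[1..k-1]`.

`bftrie` indexes such a graph for people who need exact membership and color
queries over many similar genomes, incremental insertion (a new genome never
forces a rebuild), and implicit-edge traversal — at desk scale, from R or a
shell.

## The data structure

*k* must be a multiple of a chunk length *l*; the trie consumes a *k*-mer one
length-*l* chunk per level. Each vertex is a list of containers:

- an **uncompressed container** — at most *c* `(suffix, colors)` tuples,
  kept sorted;
- **compressed containers**, created when an uncompressed container
  overflows ("bursts"). A burst splits each suffix into its first chunk
  `s_pref` and a remainder that moves into a child vertex. The `q` distinct
  chunks are stored as a quartet:
  - `quer` — a small Bloom filter over the chunks (a prefilter, never
    trusted on its own),
  - `pref` — a bit array of `2^λ` bits marking which prefixes `a` occur,
    where each chunk is split `s_pref = ab` and `α`, the 2-bit integer value
    of `a`, indexes the array (λ = 2|a| bits),
  - `suf` — the `q` suffix parts `b`, sorted within clusters of equal `a`,
  - `clust` — `q` bits marking cluster starts.

  Membership is resolved by `HammingWeight(α, pref)` (the cluster index),
  `Rank(i, clust)` (the cluster start), and a scan of the cluster, so a
  Bloom-filter false positive is always caught: **the index is exact**. A
  chunk absent from the arrays but claimed by `quer` is *recycled* — a later
  insertion stores it there without touching the filter. A container costs
  `m + 2^λ + q(μ+1)` bits (μ = 2|b|) and is re-split with a larger |a|
  whenever that strictly shrinks `2^λ + qμ`.

In graph mode (the default), chunks are stored rotated (`s[2..l]s[1]`) and
`quer` hashes only positions `2..l-1`, which places all four successor or
predecessor variants of a *k*-mer in one container and one cluster: a
successor query touches at most `1 + k/l − 1` trie vertices, a predecessor
query at most `1 + 4(k/l − 1)`.

## A worked example

The six 12-mers below, inserted into a trie with `k = 12`, `l = 4`, `c = 5`,
fill the root's uncompressed container with five suffixes; the sixth bursts
it into a compressed container holding `q = 4` distinct chunks:

```r
library(bftrie)
six <- c("atcgaaccgtta", "atcgcgttagct", "caggacgtacgt",
         "caggtttgcaca", "gcgatgcaacga", "gcgccaggaatc")
t <- bft_new(k = 12, l = 4, capacity = 5, graph_mode = FALSE)
bft_insert(t, six, color = 1)
str(bft_root_structure(t)[[1]])
#> List of 6
#>  $ type          : chr "compressed"
#>  $ q             : int 4
#>  $ prefix_len    : int 2
#>  $ suffix_len    : int 2
#>  $ terminal      : logi FALSE
#>  $ footprint_bits: num 292
```

Under the `|a| = 2, |b| = 2` split the container's arrays are
`suf = [cg, gg, ga, gc]`, `clust = [1,1,1,0]` (three clusters). Inserting
the suffix prefix `gtat` records prefix `gt` at `pref[12]` (its 2-bit value
`1011` is 11, so position 12), lands in cluster 4 at position 5, and places
`at` at `suf[5]` with `clust[5] = 1`:

```r
cc <- bft_root_container(t)
cc_insert(cc, "gtat")
#> $cluster
#> [1] 4
#> $pos
#> [1] 5
prefix_index("gt")
#> [1] 12
```

End-to-end, from reads:

```r
sim <- simulate_pangenome(tempfile(), ref_length = 100000, n_genomes = 5,
                          sub_rate = 0.005, error_rate = 0.005, k = 32)
idx <- build_index(sim$read_files, k = 32, l = 8, capacity = 248, min_occ = 3)
bft_info(idx)$n_kmers      # ~173,000 unique 32-mers for the default seed
bft_colors(idx, sim$truth$kmer[1])
successors(idx, sim$truth$kmer[1])
```

A thin command-line wrapper ships in `exec/bft`
(`bft build | query | branching | info | simulate`).

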