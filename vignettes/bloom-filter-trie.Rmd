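---
title: "Indexing colored k-mer sets with a Bloom filter trie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing colored k-mer sets with a Bloom filter trie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bftrie)
```

## The model

A pan-genome — many highly similar genomes of one species — is represented
here as a colored de Bruijn graph: the set of all length-*k* substrings
(*k*-mers) of the input genomes, each carrying a color set that records
which genomes it occurs in. Edges are implicit: `y` succeeds `x` exactly
when `x[2..k] == y[1..k-1]`, so each *k*-mer has at most four successors
and four predecessors and no edge is ever stored.

The index is a burst trie. With *k* a multiple of the chunk length *l*, a
*k*-mer descends one length-*l* chunk per level; the maximum height is
`k/l - 1`. A vertex is a list of containers: zero or more compressed, plus
at most one uncompressed. An uncompressed container is a sorted,
capacity-*c* set of `(suffix, colors)` tuples. Exceeding *c* bursts it:
each suffix is split into its first chunk and a remainder, remainders move
to fresh child vertices, and the `q` distinct chunks are stored compressed
as four structures — a Bloom filter `quer`, a prefix-presence bit array
`pref` of `2^λ` bits, the sorted suffix-part array `suf`, and the
cluster-start bit array `clust`. Each chunk `s` is split `s = ab`; the
2-bit integer value of `a` (a = 00, c = 01, g = 10, t = 11, first character
most significant) indexes `pref` 1-based, and a *cluster* is the run of
`suf` entries sharing one `a`, located by the Hamming weight of
`pref[1..α]` and the rank of that cluster index in `clust`.

Two properties make the structure exact despite its Bloom filters. First, a
filter hit is only ever a hint: membership is always confirmed against
`pref`/`suf`/`clust` or by binary search in an uncompressed container.
Second, insertion *recycles* false positives: a new chunk goes into the
first compressed container of the vertex whose filter already claims it,
so the filter needs no update and a look-up that stops on the first firing
container stops exactly where insertion would have placed the chunk. A
look-up that finds the firing container without the chunk can therefore
safely report absence.

## Graph traversal

All successors of `x` share the prefix `x[2..k]`, hence one root-to-vertex
path; predecessors differ in their first character and share everything
else. Two refinements confine the final four candidates of either
direction to one container and one cluster: chunks are stored rotated
(`s[2..l]s[1]`) and the `quer` hashes read only positions `2..l-1` of the
unrotated chunk. The four variants `c1·mid·c2` of a fixed middle then
probe identical filter positions, so a traversal probes once and scans one
cluster. Suffix parts `b` are required to keep at least two characters
(`|a| ≤ l-2`) precisely so that the variable first/last characters stay in
`suf`. The instrumented vertex-visit counts are bounded by `1 + k/l - 1`
(successors) and `1 + 4(k/l - 1)` (predecessors), and the test suite
asserts the bounds on every probe.

Because the insertion worked example predates the rotation, the package
exposes `graph_mode = FALSE`, which stores chunks verbatim and hashes all
*l* characters; traversal then refuses to run. Default is
`graph_mode = TRUE`.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | — | k-mer length (characters). Must be a multiple of `l`. |
| `l` | — | chunk length (characters), `>= 3`. Larger `l` means a shallower trie with bigger containers; published runs on real bacterial data used `l = 9` with `k` 54–63. |
| `capacity` (`c`) | 248 | uncompressed-container capacity (suffix count). Burst trigger; 248 is the published compromise between compression and speed. |
| `bf_bits` (`m`) | 256 | `quer` size in bits. The filter is meant to be tiny — the burst size bound `m + 2^λ ≤ q(λ-1)` only admits small `m` — so one byte-per-element order of magnitude; exposed for experimentation. |
| `bf_hashes` (`f`) | derived | `max(1, round(ln 2 · m/c))`, capped at 4 — the textbook optimum for an `m`-bit filter holding up to `c` elements. |
| `seed` | 1 | hashing seed; same seed, same inputs, bit-identical filters. |
| `resize_factor` | 8 | a container is re-split when `q(μ+1) > resize_factor · (m + 2^λ)`, i.e. when the incremental cost dominates the fixed arrays enough that a larger `|a|` pays off. |
| `min_occ` | 1 | per-genome minimum k-mer count during extraction; counts below it are treated as sequencing errors. 3 is a sensible default for ~20× coverage. |

## Numerical and design choices

- **Burst split choice.** At burst time the split `|a|` is the smallest
  value with `|b| ≥ 2` satisfying `m + 2^λ ≤ q(λ-1)` for the `q` chunks at
  hand (the container then costs no more than the plain 2-bit encoding of
  its strings). When no `|a|` qualifies — small `l` or small `q`, as in the
  `l = 4` toy example — the fallback is `|a| = l/2` (capped so `|b| ≥ 2`).
- **Resizing.** `cc_resize_split()` increases `|a|` only while
  `2^λ' + qμ' < 2^λ + qμ` holds strictly and `|b| ≥ 2` survives; otherwise
  it is a no-op. `quer` is left untouched: its hashes read only the middle
  characters, which the `a`/`b` split does not alter.
- **Insertion target.** When several filters fire but none contains the
  chunk, insertion uses the *first* firing container — the same container
  a look-up stops on, which is what makes stop-on-first-firing sound.
- **Duplicates.** Re-inserting a stored k-mer only merges color sets;
  duplicate chunk insertion into a compressed container is a contract
  violation and raises an error.
- **Non-ACGT input.** Reads are split at ambiguity codes during
  extraction; no k-mer containing one is ever stored (the 2-bit packing
  admits four symbols). K-mers are indexed as given — no
  reverse-complement canonicalization.
- **Color compression.** A census of distinct color sets (trailing zero
  bits trimmed, so late-added genomes do not fragment older sets) is
  sorted by decreasing count × size, ties broken by bit-lexicographic
  order for run-to-run determinism. A set moves to the external array when
  the byte-rounded index replacing it is cheaper than the byte-rounded set
  *and* the move is a net saving including the one-time table copy — the
  second condition is this package's guard; without it a set occurring
  once could grow the total. Compression is lossless, idempotent in
  effect, and re-runnable after further insertions (externally stored sets
  are copied back inline on write).
- **Degenerate shapes.** `k = l` is supported: the root is at maximal
  depth and bursts directly into terminal compressed containers whose
  entries carry color references instead of children. A burst whose
  suffixes all share one chunk produces `q = 1` and recurses into the
  single child if it overflows in turn.
- **Serialization** is a versioned, native-endian binary dump of the
  complete state (header, vertices, color slots, external table, color
  names); the round trip is required — and tested — to answer every query
  identically. The format is this package's own.

## The synthetic pan-genome generator

`simulate_pangenome()` emulates a simulated-isolate study at desk scale:
one random reference (default 100 kb), `n_genomes = 5` copies mutated by
independent per-base substitutions (`sub_rate = 0.005`; substitutions
only, so coordinates stay aligned and the truth table — computed from the
genome strings, never from reads — is exact), and per genome 20,000 reads
of 100 bp with substitution sequencing errors at 0.5 %. The default
`k = 32` with `l = 8` keeps the published parameter regime (reads of 100
bp, error rate 0.5 %, k in the tens) while giving the trie four levels;
a prime k would admit no chunk length at all.

Read starts are a deterministic tiling at step `read_length - k + 1`
topped up with uniform random starts. Pure uniform sampling leaves the
genome ends uncovered with non-trivial probability, which would break the
generator's contract that error-free reads at `min_occ = 1` reproduce the
per-genome truth sets exactly; the tiling makes that identity hold while
random reads still dominate the multiset.

What the generator does *not* emulate: indels and structural variation,
realistic error and quality profiles, coverage biases, contamination.
Passing tests therefore demonstrate correctness of the data structure and
its color bookkeeping on realistic *scales* and mutation structure, not
robustness to every artifact of real sequencing data.

## Validation design and problem sizes

All expected values come from independent oracles: plain associative maps
for membership and colors, brute-force popcount/linear-scan for the bit
primitives, direct sorted construction for container state, and four (or
eight) independent look-ups for neighborhoods and branching. The suite
runs, among others: exactness on the full simulated preset (about 173,000
stored 32-mers; 10,000 present plus 10,000 absent probes), 1,000
instrumented traversal probes, order-independence with 3,000 k-mers,
burst-conservation with capacity 5, and the exhaustive 16-variant
restricted-hashing check. These sizes were chosen as the smallest that
exercise multi-burst, multi-container, multi-level behavior convincingly.

## Known limitations

- No k-mer deletion (insert-only, like the structure it implements).
- No reverse-complement canonicalization; strand handling is the caller's.
- Arrays are reallocated on insertion (`O(q)` per compressed insert);
  fine at desk scale, not tuned for billions of k-mers.
- `Rank` is the space-efficient linear scan, not an `O(1)` succinct
  structure.
- Non-branching paths are not compacted into unitigs.
- The on-disk format is native-endian and not interoperable with other
  tools.
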