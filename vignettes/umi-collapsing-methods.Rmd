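---
title: "Methods: error-tolerant UMI collapsing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error-tolerant UMI collapsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umidedup)
```

## The problem

Unique molecular identifiers (UMIs) are short random tags ligated to DNA
molecules before PCR amplification.  Reads that share a UMI (and, for
aligned data, an alignment coordinate) are amplification copies of one
original molecule and should be counted once.  Sequencing and PCR introduce
substitution errors into the UMIs themselves, so exact-match collapsing
overcounts molecules: an error-tolerant collapse must merge UMIs within a
small Hamming distance `k` (typically 1), while being careful not to merge
genuinely distinct molecules.  Insertions and deletions in UMIs are far
rarer than substitutions and are ignored; consequently all reads in a run
must carry UMIs of one fixed length `M`.

## Distance model and encoding

Every UMI is a string over the five-letter alphabet {A, C, G, T, N}.  `N`
(an undetermined base call) is treated as a fifth letter: it mismatches
each of the four nucleotides and matches another `N`.

Distances are computed word-parallel.  Each nucleotide maps to a 3-bit
code — `e_A = 110`, `e_T = 011`, `e_C = 101`, `e_G = 000` — chosen so that
the four codes are *pairwise equidistant*: any two distinct codes differ in
exactly two bits (the codes are vertices of a regular tetrahedron in
Hamming space).  Concatenating codes packs `floor(64/3) = 21` positions
into one 64-bit word, and for N-free sequences

```
d(u, v) = popcount(encode(u) XOR encode(v)) / 2
```

per word — one XOR and one popcount regardless of `M` (up to 21).  `N`
positions hold the canonical pattern `000` in the coded bits and are
tracked in a separate one-bit-per-position mask; the full distance is the
masked coded-bit popcount halved, plus the popcount of the XOR of the two
N-masks.  The choice of `000` as the canonical N pattern makes both-N
positions contribute nothing automatically.

```{r}
umi_encode("AAT")$bits
umi_encode("AAA")$bits
umi_xor_popcount("AAT", "AAA")   # 2 bits differ ...
umi_hamming("AAT", "AAA")        # ... one substitution
```

For `M <= 21` the engine additionally mirrors the packed words into flat
arrays so a distance evaluation touches contiguous memory; this changes
nothing observable except speed.

## The near-neighbor contract

All grouping logic is phrased over two operations on a dynamically
shrinking set of UMIs, which implicitly represent the UMI graph
`G = (V, E)` with edges between UMIs at distance at most `k`:

* `remove_near(u, k, F)` — return and delete every alive UMI `v` with
  `d(u, v) <= k` and frequency `f(v) <= F`.  The queried UMI itself is
  always included when alive, regardless of its own frequency — this
  matters for the directional algorithm, where the ceiling routinely lies
  below `f(u)`.  A UMI can therefore be returned by at most one query over
  an index's lifetime.
* `contains(u)` — is `u` present and not yet removed?

`k` is fixed when an index is built; querying with any other `k` is an
error rather than a silent rebuild.  `F = Inf` means no ceiling.

Eight interchangeable backends implement the contract.  Their answers are
required to be identical — the accelerated structures only prune where the
answer cannot be:

| backend     | idea | query cost driver |
|-------------|------|-------------------|
| `naive`     | scan all alive UMIs | `O(N)` distance checks |
| `combo`     | generate the Hamming ball of `u`, probe a hash table | `O(|Σ|^k M^k)` probes |
| `subseq`    | hash all `choose(M,k)` placeholder-masked keys | bin sizes; no distance check needed |
| `ngram`     | inverted index over `k+1` contiguous grams | bin sizes + verification |
| `trie`      | depth-first walk with an edits-remaining budget | shared prefixes |
| `bktree`    | metric tree, triangle-inequality window `[Δ-k, Δ+k]` | tree height |
| `fenwickbk` | Fenwick prefix decomposition over frequency ranks, a BK-tree per node | `log N` trees |
| `ngrambk`   | a BK-tree per n-gram bin | short trees, few bins |

Correctness arguments worth recording:

* **n-grams** split the UMI into `k + 1` contiguous, non-overlapping grams
  of length `floor(M/(k+1))` (the last gram absorbs the remainder).  Two
  sequences within `k` substitutions must agree exactly on at least one
  gram (pigeonhole), so unioning the query's `k + 1` bins and verifying
  distances is complete.  Keys carry the gram's slot as well as its
  sequence, so equal substrings at different offsets occupy different bins.
* **subsequences** mask every choice of `k` positions with a placeholder.
  Two UMIs share a key iff they differ only at masked positions, i.e. iff
  `d <= k` — membership needs no verification at all.
* **BK-trees** index each child by its distance to the parent.  With
  `Δ = d(query, node)`, the triangle inequality confines results to child
  slots in `[Δ - k, Δ + k]`.  Nodes are inserted in increasing frequency
  (ties broken by sequence) so low-frequency UMIs — the ones directional
  queries can still return — sit near the root, making the
  minimum-frequency subtree bound more effective.
* **Fenwick BK-trees** rank-compress the distinct frequency values; node
  `t` of the binary-indexed array holds a BK-tree over the UMIs whose rank
  falls in `(t - lowbit(t), t]`.  A ceiling `F` decomposes into `O(log N)`
  nodes tiling `[1, rank(F)]`, so each candidate appears in exactly one
  visited tree.

Two bookkeeping rules keep the shared-membership structures honest: the
global alive set is authoritative, and per-tree "subtree fully removed" /
"minimum alive frequency" flags are conservative pruning hints refreshed on
the return path of later traversals (a stale flag can only make a query
slower, never wrong).  Hash bins compact themselves once more than half
their members are dead.  For the exclusive-membership trie, flags are
maintained exactly by walking the leaf-to-root path at each removal.

## The three grouping algorithms

All three visit UMIs in a canonical order — decreasing frequency, ties
broken by sequence — and consume one fresh index:

* **cluster** (connected components): each still-alive seed expands
  transitively through `remove_near(·, k, Inf)`.  Chains of intermediate
  UMIs can *bridge* sequences more than `k` apart, so this algorithm
  merges most aggressively and can undercount molecules.
* **adjacency**: each seed claims exactly its alive neighbors, without
  recursion.
* **directional** (the default): recursive like cluster, but a neighbor
  `v` of `u` is admitted only if `f(v) <= epsilon * (f(u) + 1)`.  With the
  default `epsilon = 0.5` this is the familiar `2 f(v) - 1 <= f(u)` rule:
  an error copy of a true molecule should be substantially rarer than its
  source.  The recursion re-evaluates the threshold at every hop.

The admission rule uses `epsilon * (f(u) + 1)`; the equivalent rearranged
inequality `2 f(v) - 1 <= f(u)` pins the sign of the constant, and the
rule lives in a single helper should anyone want the variant.  Recursions
are implemented with explicit stacks so million-UMI components cannot
overflow the call stack.  Each group's representative is its
highest-frequency member, ties broken by lexicographically smallest
sequence; every tie-break in the package is deterministic, so two runs on
the same input are byte-identical, and the grouping is invariant to the
backend — a property the test suite asserts wholesale against the naive
reference on ~100 simulated datasets.

```{r}
tab <- umi_count(c(rep("AAAA", 10), rep("AAAT", 5), rep("AATT", 2)))
n_groups(umi_group(tab, k = 1, method = "cluster"))      # bridged into 1
n_groups(umi_group(tab, k = 1, method = "adjacency"))    # 2
n_groups(umi_group(tab, k = 1, method = "directional"))  # chain admitted: 1
```

## The dataset simulator

`simulate_umi_dataset(C, M, k, ...)` generates the synthetic datasets used
for validation: `C` uniform random centers over the 5-letter alphabet,
each with 20 neighbors within `k` substitutions.  For `k = 1` a neighbor
is exactly one substitution away — a uniform position changed to a uniform
*different* letter, giving `4M` possible neighbors per center.  For
`k >= 2` (where the generation rule is genuinely open) the number of
edited positions is drawn uniformly from `1..k`.  Center frequencies are
uniform on `[19, 100]` and neighbor frequencies uniform on `[1, 10]` —
ranges chosen so the separation `2 f(v) - 1 <= f(u)` holds for *every*
center/neighbor pair, tight at `2·10 - 1 = 19`; at the extreme the
directional rule still admits every neighbor of its own center
(`10 <= 0.5 · 20`).  Draws follow a fixed documented order, so a seed
fully determines the dataset.

Two independent checks anchor the generator.  Analytically, a center at
`M = 10, k = 1` has 40 possible one-edit neighbors, of which 20 draws with
replacement hit `40·(1 − (39/40)^20) ≈ 15.86` distinct ones, so a
`(C, 10, 1)` dataset has `≈ 16.86·C` unique UMIs before cross-center
collisions.  At `M = 9` the 5^9 sequence space is small enough that
collisions matter and must (and do) emerge from the simulation itself.

What the simulator does *not* model: errors in the non-UMI read body, PCR
amplification trees (frequencies are drawn, not grown), quality-score
structure, or indels.  Passing tests on simulated data therefore
demonstrate the correctness and relative efficiency of the collapsing
machinery, not biological fidelity of any particular error process.

## File drivers

**FASTQ** — fixed-length reads are deduplicated by their full sequence
(the read *is* the UMI).  One global table, one grouping, one output
record per group: among reads whose sequence equals the group
representative, the copy with the highest mean Phred score (ties: first in
file) is emitted verbatim.

**SAM/BAM** — the UMI is the suffix of the read name after the last
`"_"`.  Reads are keyed by (reference, strand, coordinate), where the
coordinate is the 5' start for forward reads and the 3' end (start +
reference-consumed CIGAR length − 1) for reverse reads; by default
soft-clipped bases are restored into the coordinate so clipping
differences do not split a molecule (a flag disables this, as the
convention varies between pipelines).  Each key is deduplicated
independently; the consensus read per group is chosen by mapping quality,
then mean Phred, then file order.  Unmapped reads and
secondary/supplementary alignments never participate in grouping and are
dropped by default (flags pass them through).  Every output record is an
unmodified input record — the driver never synthesizes sequences.
Paired-end and per-cell/per-gene collapsing are out of scope.

## Numerical and scale choices

* Frequencies are integers; ceilings `F = epsilon·(f + 1)` are compared in
  double precision, and `Inf` is the no-ceiling sentinel, so no overflow
  is possible.
* The test suite validates backend equivalence on ~100 seeded datasets
  with `C ∈ [30, 1000]`, `M ∈ {8, 10, 12}`, `k ∈ {1, 2}`, and the
  simulator's printed-size checks use 5–20 seeds per configuration with
  the largest case at `C = 10^5, M = 9` (~2.1 million generated UMIs).
  These sizes keep a full run in a few minutes on one CPU while leaving
  the sampling error of each checked mean near 0.1%.
* The instrumented efficiency check counts Hamming-distance evaluations:
  on a `(10^4, 10, 1)` dataset a full directional run performs ~4×10^9
  evaluations through the naive backend and ~3×10^6 through the n-grams
  BK-trees hybrid — a >1000× reduction, which is the portable stand-in
  for wall-clock comparisons.

## Known limitations

Substitution-only distances (UMIs with indels shift the whole tag and are
not recoverable); one UMI length per run; single-end alignment handling
only; grouping quality on real data depends on the directional
assumption that error copies are rarer than their sources, which deep
saturation sequencing can violate.
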