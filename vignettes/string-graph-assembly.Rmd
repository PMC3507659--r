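---
title: "String graph assembly by suffix-prefix match enumeration"
author: "sgasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{String graph assembly by suffix-prefix match enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgasm)
```

## The problem and the model

`sgasm` assembles a collection of error-free DNA reads by the
overlap-layout paradigm built on *exact suffix-prefix matches*. A
suffix-prefix match (SPM) is a triple ⟨r, r′, ℓ⟩ in which the length-ℓ
suffix of read r equals the length-ℓ prefix of read r′, with ℓ at least a
user-chosen minimum overlap ℓ~min~. Because reads originate from both
strands of a DNA molecule, all computations run over the strand set R̄ of
the m reads plus their m reverse complements; strand index i ≤ m is read
r~i~, index m+i its reverse complement. Each strand is virtually padded by
a sentinel $~i~ with A < C < G < T < $~1~ < … < $~2m~: sentinels are never
stored, the comparison routines realize them (a proper prefix of another
strand sorts *after* the longer strand; identical strands are ordered by
strand index).

The assembly itself is the classical string graph: two vertices per read
(r.B for its beginning, r.E for its end), and for every irreducible,
non-redundant SPM two complementary directed edges whose labels are the
unmatched extension of the destination read. Maximal unbranched walks in
this graph spell contigs.

## The pipeline

### 1. Prefilter: a suffix- and prefix-free read set

Reads that are prefixes or suffixes of other reads (or of reverse
complements) carry no extra information and would break the later
identification of whole reads by their sentinel-terminated suffixes. All
2m strands are sorted lexicographically (`lex_sort_with_lcp()`), with the
length of the longest common prefix (lcp) of consecutive strands computed
as a byproduct. A scan of consecutive pairs then marks:

* a strand whose lcp with its neighbour equals its own length — it is a
  proper prefix of the neighbour. A mark on a forward strand means the
  read is a prefix of another read; a mark on a reverse-complement strand
  m+i means read i is a *suffix* of another read (r is a suffix of r′
  exactly if the reverse complement of r is a prefix of that of r′).
* of two identical strands, the read that comes later in the input
  (the order relation ≺). Marks are mapped to forward reads *before* the
  comparison, so a pair formed by the two strands of one read (a
  reverse-complement palindrome such as `ACGT`) places no mark — a
  palindromic read must not delete itself — and cross-strand duplicate
  pairs (r~i~ equal to the reverse complement of r~j~) remove exactly the
  ≺-larger read. This mapping was a genuinely open design point: marking
  literally by strand index would delete *both* members of a cross-strand
  duplicate pair, because each of the two identical runs in the sorted
  order marks the other read.

`prefilter()` removes all marked reads and reports counts by category
(duplicates take priority over prefix- over suffix-containment when one
read is marked for several reasons; the *set* of removed reads is what the
tests verify against a brute-force containment oracle).

### 2. Overlap: SPM-relevant suffixes, bucketed

Any SPM ⟨r, r′, ℓ⟩ pairs a *proper* suffix of r (it cannot start at
position 1, or r′ would make the set non-prefix-free) with the whole read
r′. The *SPM-relevant suffixes* are all whole reads plus every proper
suffix of length ≥ ℓ~min~ whose initial k-mer equals some read's initial
k-mer. The parameter k ≤ min(ℓ~min~, 32) lets a k-mer live in one 64-bit
word as the base-4 integer code φ~k~ (A→0, C→1, G→2, T→3, high digit
first), which preserves lexicographic order. The code of a window is
maintained in constant time while sweeping along a read
(`sliding_codes()`), and the codes of the k′-prefix and of the k″-suffix
of the initial k-mer are a right shift and a mask (`kmer_prefix_code()`,
`kmer_suffix_code()`).

Indexing follows a counting-sort plan (`counting_phase()`,
`compute_partial_sums()`, `insertion_phase()`):

* the sorted distinct initial k-mers form the key table K with initial
  multiplicities C;
* the same scan fills two exact membership filters: P (codes of all
  k′-prefixes) and Q (codes of all k″-suffixes of initial k-mers). A
  candidate suffix failing either filter matches no key and is discarded
  cheaply. Small filters are bit vectors; larger ones use an
  open-addressing hash set, which keeps membership exact and memory
  proportional to the distinct codes (for the default
  k′ = ⌈log₂ n⌉ − 8 a literal 4^k′-bit vector would dwarf the read set at
  desk scale).
* candidates passing P and Q are buffered; each full buffer is sorted and
  merged against K in a single binary search plus linear scan,
  incrementing the counters (counts are independent of the buffer
  capacity b; the default is b = max(1024, 2m/4), γ = 4 applied to the 2m
  upper bound on |K| since |K| is unknown before the scan).
* partial sums π of the final counts follow the inclusive recurrence
  π[0] = C[0], π[i] = π[i−1] + C[i], π[d] = π[d−1]; bucket i occupies
  S[π[i−1] .. π[i]−1] (with π[−1] := 0), and the insertion phase fills
  each bucket top-down by a decrementing cursor, validating candidates
  against K during the buffered merge.

Because no two buckets can share an ℓ~min~-overlap (their suffixes differ
within the first k ≤ ℓ~min~ characters), buckets are independent:
`plan_partitions()` tiles the key range into q contiguous parts of roughly
equal total size (greedy accumulation; alternatively the minimal q whose
largest part fits a memory limit under a simplified 16-bytes-per-entry
model), and only one part's suffix table is resident at a time, at the
price of one extra read-set scan per part. The SPM output and the contigs
are byte-identical for every q — this is asserted by tests, not assumed.

### 3. Per-bucket lcp-interval trees

Each bucket is sorted by full suffix under the sentinel order, yielding an
lcp table L with all values ≥ k. The nested *lcp-intervals* of (H, L) —
maximal intervals whose members share a prefix of a given depth — form a
tree traversed bottom-up by a stack algorithm (`traverse_bucket()`): push
on rising lcp, pop and complete on falling lcp, extended so that every
singleton is delivered exactly once as a leaf edge of the deepest interval
containing it, before that interval completes. A bucket with a single
entry gets a pseudo-root of depth k carrying its leaf (an lcp-interval
proper requires at least two members; tests compare emitted intervals
against a naive O(β²) enumeration from the interval definition on all
buckets with 2 ≤ β ≤ 12). Per bucket of size β there are β leaf edges, at
most β−1 branch edges and at most β−1 intervals, so at most 3β−1 callback
invocations.

### 4. SPM enumeration, containment, transitivity

During the traversal (inside `spm_overlap()`):

* a leaf with read offset 0 is a *whole-read leaf*: its read is a
  potential SPM destination and is appended to the list W, together with a
  fresh left-context dictionary;
* a leaf whose suffix ends exactly at the depth of its interval (the edge
  label is just the sentinel) is a *terminal edge*: its read's suffix
  equals the interval's prefix string, making it a potential SPM source;
  such strands are collected in T;
* when an interval of depth ℓ ≥ ℓ~min~ completes, every pair from
  T × W[firstinW..] is an SPM of length ℓ (the `firstinW` slot restricts W
  to the whole-read leaves of the interval's own subtree; it is set by the
  interval's first edge and inherited from the first child). T is cleared
  after each product — terminal edges sort after all branch edges of an
  interval, so one global list suffices. W is cleared whenever an interval
  of depth < ℓ~min~ completes: nothing deeper can reach its reads anymore.

A terminal *whole-read* leaf (offset 0) means some other SPM-relevant
suffix has the entire read as a proper prefix — with a prefix-free input
that is precisely an internal occurrence in another read. The overlap
stage therefore runs two passes: pass 1 flags internally contained reads
(`detect_internally_contained()`), pass 2 removes all entries of flagged
reads from the sorted buckets (the lcp table is min-folded across removed
entries) and enumerates SPMs among the remainder. Removing contained
reads *before* transitivity suppression is a deliberate choice where the
order was open; it matches the usual string-graph formulation, and the
definitional oracle in the tests quantifies over the same reduced set.

Every SPM over R̄ appears together with its mirror (both strands flipped,
roles swapped); `is_nonredundant()` keeps exactly one of each pair (both
forward; or forward→reverse with the source read earlier in input order;
or reverse→forward with the destination read earlier). Self-overlaps of a
read with itself or its own reverse complement are excluded everywhere —
they are never emitted, never stored, and equally excluded from the
brute-force oracles, so both sides classify transitivity over the same SPM
set.

An SPM ⟨r, t, ℓ″⟩ is *transitive* when two chained SPMs ⟨r, s, ℓ⟩ and
⟨s, t, ℓ′⟩ explain it: ℓ + ℓ′ = |s| + ℓ″. Equivalently — and this is what
makes a streaming check possible — it is transitive exactly when the left
context of some irreducible SPM into the same destination t (the part of
the source read not covered by the overlap) is a suffix of its own left
context. The bottom-up traversal delivers the SPMs of each whole-read
path in non-increasing ℓ, so the first SPM per destination is always
irreducible; each later SPM is checked against the stored left contexts
(`lcsearch()`: true if some stored string is a suffix of the query,
otherwise the query is stored). The dictionary is a plain string set with
a direct suffix scan — paths collect few SPMs at desk scale, so a
compressed trie would change constants, not contracts. Classification
runs *before* the redundancy filter: a redundant SPM still witnesses
transitivity (its mirror is equivalent), only emission is filtered. SPMs
of equal length into one destination cannot suppress each other (a suffix
relation between their left contexts would contradict suffix-freeness),
so their processing order is immaterial; a property test confirms
order-independence indirectly through oracle equality.

### 5. String graph and contigs

For each irreducible non-redundant SPM ⟨x, y, ℓ⟩ over strands, writing
out(s) for vertex r.E when strand s is read r forward and r.B when s is
its reverse complement, `build_string_graph()` inserts
out(x) → out(y) with label length |read(y)| − ℓ and the complement edge
out(flip(y)) → out(flip(x)) with label length |read(x)| − ℓ. This single
rule reproduces the three orientation cases (forward/forward,
forward/reverse, reverse/forward). Edges live in a flat array of size 2ρ
grouped by source vertex (outdegree counting, partial sums, fill);
`complement_edge()` is an involution pairing the two edges of each SPM,
and the two walks they induce spell reverse-complementary sequences.

`extract_contigs()` walks maximal unbranched paths: an edge starts a
contig when its source vertex does not have outdegree 1 and indegree 1,
and the walk extends while the current vertex has both degrees equal
to 1. Each traversed edge is marked visited together with its complement,
so each double-stranded contig is reported once; cycles of unbranched
edges are collected afterwards from the lowest remaining edge index, and
traversal order is deterministic (ascending vertex/edge ids), so output is
reproducible run to run. Spelling starts with the oriented read of the
first edge's source vertex (out of r.E: r forward; out of r.B: its
reverse complement) and appends each edge's label, i.e. the last
label-length characters of the oriented destination read. Reads with no
incident edges that are not internally contained become single-read
contigs. Contigs shorter than `min_contig_length` (default ℓ~min~ + 1, so
isolated-read contigs at typical read lengths survive) are dropped. No
graph cleaning (tip or bubble removal) is performed; the traversal keeps
branching reads, which therefore start new contigs at repeat boundaries.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `l_min` | minimum overlap length (bases) | 45 | reads shorter than `l_min` are dropped at encoding |
| `k` | initial-mer size (bases) | `min(l_min, 32)` | one 64-bit word per code |
| `k_prime` | P-filter mer (bases) | `clamp(⌈log₂ n⌉ − 8, 8, k)` | n = total read bases |
| `k_dbl_prime` | Q-filter mer (bases) | `k_prime − 1`, floor 1 | |
| `parts` | partition count q | 1 | output-invariant; bounds memory |
| `mem_limit` | bytes, alternative to `parts` | — | minimal q fitting the size model |
| `buffer_size` | counting/insertion buffer b | `max(1024, 2m/4)` | result-invariant |
| `min_contig_length` | shortest reported contig (bases) | `l_min + 1` | |

The `k_prime` clamp extends the standard setting max{8, log₂ n − 8} so the
chain k″ ≤ k′ ≤ k holds on arbitrarily small test inputs.

## The synthetic-data generator

`random_genome()` draws uniform i.i.d. bases; `simulate_reads()` samples
`ceiling(coverage·|template|/mean read length)` reads at uniform start
positions, from either strand with equal probability, error-free by
default (an optional per-base substitution rate exists to demonstrate how
exact-overlap assembly degrades with noise, and stays off by default);
`tile_reads()` places reads deterministically at a fixed step plus one
flush-right read, guaranteeing consecutive overlaps ≥ read length − step.
All generators are seeded (Mersenne-Twister through `set.seed()`, integer
arithmetic only in the outputs) and restore the caller's RNG state.

What the generator emulates: even, error-free sampling of a single
haploid, repeat-free template from both strands — the regime in which
exact-SPM assembly is lossless. What it does not emulate: sequencing
errors, indels, quality values, non-uniform coverage, repeats at or above
read length, ploidy or contamination. Passing tests therefore demonstrate
algorithmic correctness of the index, the SPM sets, the graph and the
layout, not robustness on real sequencing data: on real data this
assembler would require error correction upstream (deliberately out of
scope here).

For the reconstruction checks the tiled generator (step 50 at read
length 100, random strand flips) is used rather than random 20× sampling:
random sampling leaves a small but non-negligible chance of a coverage
gap larger than read length − ℓ~min~ on a multi-kilobase template, which
would test the simulator's luck rather than the assembler. Random
sampling is exercised by the oracle-equality and scaling suites instead.

Problem sizes in the test suite were chosen to keep the full suite in the
minutes range on one core while still exercising every code path at
non-toy scale: ~100 oracle-checked read sets of 20–200 reads, one 1 Mb
template at 20× (≈200k reads) for partition invariance, twenty 5–20 kb
reconstruction templates, and a 1–8 Mb scaling ladder.

## Numerical and degenerate-input choices

* k-mer codes are unsigned 64-bit integers in compiled code; the R-level
  helpers return doubles and are restricted to k ≤ 26 (exact integers in
  double range). The pipeline supports k up to 32.
* The empty read set, reads all shorter than ℓ~min~, single-read buckets,
  and an overlap stage with zero SPMs all return well-formed empty
  results; the CLI maps "no reads survive" to exit code 2.
* Ties everywhere are broken deterministically (sentinel rule by strand
  index; SPM files sorted by source id, destination id, decreasing
  length; contig traversal by ascending ids).
* A counting/insertion mismatch (bucket overflow) raises an internal
  consistency error instead of corrupting the table.

## Known limitations

* Exact overlaps only: a single sequencing error destroys every SPM
  spanning it; there is no error tolerance or correction.
* No graph cleaning, scaffolding, or paired-end support; repeats longer
  than ℓ~min~ shared by two contexts create branches and stop contigs.
* The brute-force oracles are quadratic and guarded to small m; they are
  test instruments, not tools.
* Memory models for partition planning are simplified (bytes per entry),
  not bit-exact layouts.

## A worked example

```{r}
reads <- c("TGGACGT", "GGACGTAA", "ACGTAACC")
asm <- assemble_reads(reads, l_min = 4, forward_only = TRUE)
asm$spms
asm$contigs$sequence
```

The overlap of length 4 between the first and last read is recognized as
transitive (it is explained by the two length-6 overlaps through the
middle read: 6 + 6 = 8 + 4) and does not become a graph edge; the three
reads spell the single contig `TGGACGTAACC`.
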