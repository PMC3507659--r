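# sgasm — string graph assembly of DNA reads

`sgasm` is an R package implementing an overlap-layout assembler for
error-free DNA reads, built on exact **suffix-prefix matches** (SPMs). It
is aimed at people studying assembly algorithms: every stage is exposed as
a testable function, brute-force oracles are shipped alongside the
indexed implementation, and the whole pipeline is deterministic.

## The method

A suffix-prefix match ⟨r, r′, ℓ⟩ pairs the length-ℓ suffix of read r with
the equal length-ℓ prefix of read r′, for ℓ ≥ ℓ_min. Over the strand set
R̄ (the m reads plus their reverse complements, each virtually terminated
by a sentinel $_i with A < C < G < T < $_1 < … < $_2m) the pipeline runs
in three steps:

1. **prefilter** — lexicographic sort of all 2m strands with
   longest-common-prefix (lcp) values as a byproduct; reads that are
   prefixes or suffixes of other reads (or of reverse complements), and
   all but the first copy of duplicated reads, are removed, yielding a
   suffix- and prefix-free set.
2. **overlap** — all *SPM-relevant suffixes* (whole reads plus proper
   suffixes of length ≥ ℓ_min whose initial k-mer matches some read's
   initial k-mer) are bucketed by their initial k-mer integer code
   φ_k(s) = Σ 4^(k−i)·φ(s_i), φ = [A→0, C→1, G→2, T→3], using a
   counting-sort scheme (count table C, partial sums π, decrementing-cursor
   insertion) with k′-prefix / k″-suffix code filters P and Q and optional
   partitioning of the key range to bound memory. Each sorted bucket's
   lcp-interval tree is traversed bottom-up; whole-read leaves (offset 0)
   and terminal edges (suffix ending exactly at the interval depth) are
   combined per interval of depth ℓ ≥ ℓ_min into SPMs ⟨source, whole read,
   ℓ⟩. Internally contained reads are detected (a terminal whole-read
   leaf) and removed; an SPM is discarded as **transitive** when the
   stored left context of an irreducible SPM on the same whole-read path
   is a suffix of its own left context (the streaming equivalent of
   ℓ + ℓ′ = |s| + ℓ″ for a chain through s); mirror SPMs over the two
   strands are reduced to one non-redundant representative.
3. **assembly** — the string graph has vertices r.B and r.E per read and,
   per irreducible non-redundant SPM, two complementary edges labelled by
   the unmatched read extensions. Maximal unbranched walks spell contigs;
   each contig and its reverse complement are reported once.

The core loops (sorting, counting/insertion, traversal, classification)
are compiled C++ (Rcpp); everything is reachable from R. See the vignette
`vignettes/string-graph-assembly.Rmd` for the full account of the model,
parameter defaults and design decisions.

## A worked example

Three reads with overlaps 6 (r→s), 6 (s→t) and 4 (r→t); the length-4
overlap is transitive (6 + 6 = 8 + 4, the chain through s explains it)
and does not enter the graph:

```r
library(sgasm)
reads <- c("TGGACGT", "GGACGTAA", "ACGTAACC")
asm <- assemble_reads(reads, l_min = 4, forward_only = TRUE)
asm$spms
#>   src dst src_strand dst_strand length      status
#> 1   2   3          +          +      6 irreducible
#> 2   1   3          +          +      4  transitive
#> 3   1   2          +          +      6 irreducible
asm
#> sgasm assembly
#>   reads kept:        3 (of 3 input)
#>   contained reads:   0
#>   SPMs:              3 non-redundant, 2 irreducible
#>   string graph:      6 vertices, 4 edges
#>   contigs:           1 (total 11 bp, N50 11 bp)
asm$contigs$sequence
#> [1] "TGGACGTAACC"
```

The string graph has two vertices per read (6 for 3 reads) and two edges
per irreducible SPM (4 for 2 SPMs); the single maximal unbranched walk
spells the 11 bp sequence the three reads tile.

A realistic run starts from a simulated genome:

```r
tpl   <- random_genome(100000, seed = 1)
reads <- simulate_reads(tpl, coverage = 20, read_length = 100, seed = 2)
asm   <- assemble_reads(reads, l_min = 45)
summary(asm)
write_contigs_fasta(asm$contigs, "contigs.fa")
```

There is also a command-line front-end (`exec/sgasm`, installed with the
package) with subcommands `simreads`, `prefilter`, `overlap`, `assembly`,
`pipeline` and `verify`; `sgasm verify reads.fa` re-checks the pipeline
against the brute-force oracles on a small read set.

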