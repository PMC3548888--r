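---
title: "Minimum unique length mappability: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum unique length mappability: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulmap)
```

## The model

Short-read experiments can only interpret a read if it aligns to exactly
one place in the reference. mulmap makes this property queryable ahead
of time: for every position $p$ of a reference sequence it computes the
**minimum unique length** (MUL), the smallest read length $L$ within a
queried range $[k_{\min}, k_{\max}]$ such that the window of length $L$
starting at $p$ occurs exactly once in the whole reference. A stored
value of 0 means no length in the range makes the position unique. Given
a MUL track, "is a read of length $r$ starting at $p$ uniquely
mappable?" reduces to the constant-time test $0 < \mathrm{MUL}[p] \le r$.

Matching is exact (no mismatches, no quality scores) and, by default,
double-stranded: an occurrence is either the window itself or its
reverse complement appearing on the forward representation of any
reference sequence. A palindromic window therefore counts twice at the
same locus — once per strand — and is never unique there. Windows that
overlap any non-ACGT base (e.g. `N`) never match anything, including
themselves.

### Uniqueness is monotone in read length

If a window of length $L$ at $p$ occurs exactly once, every extension of
it also occurs at most once, and at least once (it matches itself), as
long as the extension stays within the run of ACGT bases containing $p$.
This monotonicity justifies the bracketing search used by
`compute_mul_array()`: probe the longest fitting length (if that is not
unique the position gets 0), probe $k_{\min}$, then ascend in steps
(default 25) until a unique length bounds the answer, and scan that
bracket linearly. The result is identical to exhaustive scanning of all
lengths — the test suite verifies this against a brute-force
window-tabulation oracle — but needs far fewer occurrence queries.

Monotonicity has one boundary subtlety: a window extended into an `N`
has zero occurrences, not one. The engine therefore caps the search at
the end of the valid ACGT run around each position.

### Bisulfite-converted genomes

Bisulfite sequencing reads derive from one of two converted references:
the forward strand with C→T applied, or the reverse strand, which on the
forward representation appears as G→A. `compute_bisulfite_mul()`
declares a position unique at length $L$ when the converted window
occurs exactly once (forward orientation) in its own converted genome
**and** does not occur at all in the other strand's converted genome
(by default checking both orientations there,
`crosscheck_orientation = "both"`). Because conversion collapses
alphabet symbols, bisulfite MUL values are never smaller than the
unconverted forward-only MUL at the same position — a property the test
suite asserts positionwise. A corollary worth knowing: a sequence with
no C (or no G) converts identically on both strands, so under the
crosscheck *no* position of it is bisulfite-unique.

### Transcriptome uniqueness

For spliced transcripts, reads are matched against a combined index of
the genome plus every spliced transcript sequence, and each occurrence
is collapsed to its genomic outer span (start of the first matched base,
end of the last, in genomic coordinates — a junction-spanning match
yields a span covering the intervening intron). Two levels are defined
on the collapsed spans:

* **gene-level unique**: all spans share one start or share one end
  (reads from alternative isoforms of one gene still point to one
  locus);
* **transcript-level unique**: the spans have exactly one distinct start
  *and* one distinct end (the coordinate rule, default). An alternate
  rule, `transcript_rule = "single_source"`, additionally requires that
  at most one annotated transcript produced a hit. Both rules are
  implemented because they differ on byte-identical annotated
  duplicates; the coordinate rule treats two identically-annotated
  isoforms as one location, the single-source rule does not.

Transcript-level uniqueness implies gene-level uniqueness, so the
transcript-unique position set is nested inside the gene-unique set at
every read length. Unlike the genome case, collapse-based uniqueness is
*not* provably monotone in read length across junctions, so
`compute_transcript_mul()` scans lengths linearly instead of
bracketing. This is a deliberate correctness-over-speed choice.

### Paired-end fragments

`fragment_config()` models fragment (insert) lengths as
$\mathcal{N}(\mu = 250, \sigma = 25)$, rounded to integers, with
`draws_per_position = 5` fragments drawn anchored at every transcript
position and eligible insert sizes bounded by $\mu \pm 3\sigma$
(defaults 175 and 325, covering ≥ 99.7% of the distribution). A
fragment is uniquely mappable (`pair_is_unique()`) when, pairing
same-strand occurrences of its two mates at a separation within the
insert bounds, all candidate spans collapse to a single start or a
single end. Fragments no longer than the read length have fully
overlapping mates and are treated as non-mappable.
`estimate_effective_lengths()` summarizes this as
$\text{effective length} = \text{length} \times
\frac{\#\text{unique fragments}}{\#\text{fragments}}$.

Fragment draws use a per-position seeded stream
(`derive_seed(seed, label, position)`), so results are independent of
chunking and of the order positions are visited, and truncating a
transcript preserves the draws at the shared positions.

### Expression quantification

`quantify_expression()` computes, per gene model (exon union of its
transcripts, optionally with bases shared between different genes
removed, `rmnameoverlap = TRUE`):

* raw RPKM $= \dfrac{\text{reads} \times 10^9}
  {\text{raw length} \times \text{total mapped reads}}$, and
* normalized RPKM, identical except that raw length is replaced by the
  **effective length** — the number of exon-union positions with
  $0 < \mathrm{MUL} \le r$ at read length $r$.

Reads are assigned by the genomic position of their 5′-most aligned
base (CIGAR-aware for reverse-strand SAM records). With this estimator
the norm/raw ratio is algebraically
$\text{raw length}/\text{effective length} = 1/u$ where $u$ is the
gene's unique proportion, and if the input alignments are restricted to
uniquely mapping reads drawn uniformly over the gene body, the
normalized RPKM is an unbiased estimator of the planted expression. The
acceptance suite checks exactly these two statements. Genes with
effective length 0 are reported as unquantifiable (`NA`) rather than
silently dropped.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `kmin` | 20 | shortest read length worth indexing; shorter reads are rarely unique and inflate the track's dynamic range |
| `kmax` | 255 | largest value a one-byte track can store; two-byte tracks allow up to 65535 |
| `step` | 25 | bracketing ascent stride; any positive value gives identical results (tested), this one balances probe counts |
| `strand_mode` | `"both"` | sequencing does not observe strand of origin |
| fragment `mean`, `sd` | 250, 25 | typical paired-end library; insert bounds derived as mean ± 3 sd |
| `draws_per_position` | 5 | Monte-Carlo effort per transcript position |
| `value_width` | 1 byte | MUL ≤ 255 fits one byte per position; the sidecar records width, length and range for validation |
| `denominator` | `"fitting"` | proportions count only positions where a full read fits, avoiding edge bias |

## The synthetic data generator

`generate_genome()` draws i.i.d. ACGT sequence and can plant exact
repeat copies (reported in a `repeat_map`); `generate_transcriptome()`
lays out exon/intron structures with isoforms as exon subsets;
`simulate_read_placements()` places reads uniformly over the positions
where they fit, with per-transcript seed streams;
`placements_to_alignments()`/`write_sam()` turn placements into spliced
alignments and SAM/BED files. All generators are deterministic given a
seed.

**Scope of what the tests show.** The test and acceptance suites
demonstrate *internal correctness on synthetic data*: agreement with
brute-force definitions, exact algebraic identities, format roundtrips,
nesting of uniqueness levels, the direction of bisulfite degradation,
and statistical recovery of planted expression at depth $10^4$
reads/gene. They do not compute — and therefore this package does not
claim to reproduce — any genome-scale empirical result: no whole-genome
mappability fractions, no real-organism transcript uniqueness
percentages, and no differential-expression counts on real RNA-seq
data. Problem sizes in the suites (genomes up to a few kilobases) are
the package's own choice, set so that exhaustive oracles remain
feasible.

## Numerical and design choices

* All coordinates are 0-based, half-open, on every API surface;
  refFlat and BED12 are both natively 0-based-start formats and are
  parsed without shifting.
* MUL tracks are stored little-endian at 1 or 2 bytes/position with a
  YAML sidecar holding name, length, range and width; reading validates
  the payload size against the sidecar.
* Occurrence counting is exact string matching in C++ with an optional
  early-exit cap (uniqueness tests only need to distinguish 0/1/≥2).
* Effective lengths and RPKM are computed in double precision; the only
  exact-equality claims made are ones that are algebraically identities
  of the same floating-point expressions.

## Limitations

* Exact matching only: no mismatches, indels, or quality-aware
  alignment. Sequencing error (~1% per base on common platforms) makes
  real uniqueness slightly worse than exact-match uniqueness.
* Single-reference analysis: no awareness of population variation.
* The transcript-level linear scan is slower than genome bracketing;
  for large annotations compute gene-level tracks first and reserve
  transcript-level queries for loci of interest.
* Paired-end uniqueness is estimated by sampling, not enumerated
  exhaustively; precision scales with `draws_per_position`.
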