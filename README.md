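# mulmap

Per-position **minimum unique length** (MUL) mappability tracks for
genomes, bisulfite-converted genomes, and spliced transcriptomes — plus
the things you build on top of them: region uniqueness queries,
paired-end effective lengths, and mappability-corrected RPKM expression
estimates.

## The problem

A short sequencing read is only informative if it aligns to exactly one
place in the reference. Which positions of a genome can host such a
read depends on the read length: a position inside a long repeat may
need a 60 nt read to become unique, or may never become unique at all.
Recomputing alignability for every new read length is wasteful.

mulmap instead computes, once per reference, the **minimum unique
length** at every position: the shortest read starting there that
occurs exactly once in the whole reference (counting both strands;
value 0 means no length in the queried range `[kmin, kmax]` works).
Uniqueness at any read length `r` is then the constant-time test
`0 < MUL[p] <= r`. Tracks are stored compactly at 1–2 bytes per
position with a human-readable sidecar.

Beyond plain genomes, the same machinery covers:

* **bisulfite-converted genomes** (per-strand C→T / G→A references,
  with an other-strand crosscheck),
* **spliced transcriptomes** (gene-level and transcript-level
  uniqueness after collapsing transcript hits to genomic coordinates),
* **paired-end fragments** (Gaussian insert simulation and fragment
  uniqueness, yielding effective transcript lengths),
* **expression quantification** (RPKM with the gene model's raw length
  replaced by its uniquely mappable effective length).

## Worked example

Build a 1.2 kb genome with a planted 100 bp duplication, profile it,
and quantify a gene overlapping the repeat:

```r
library(mulmap)

gen <- generate_genome(c(chr1 = 1200L),
                       repeats = list(list(chrom = "chr1", length = 100L,
                                           copies = 2L)),
                       seed = 4L)
gen$repeat_map
#>   family chrom start  end
#> 1      1  chr1   181  281
#> 2      1  chr1   944 1044

idx <- occurrence_index(gen$sequences)
arr <- compute_mul_array(idx, "chr1", kmin = 20L, kmax = 64L)
arr
#> MULArray 'chr1' (genome): 1200 positions, 1107 mappable within [20, 64]

dir <- tempfile(); dir.create(dir)
fs <- write_mul_files(list(arr), dir)          # binary track + YAML sidecar

# positions inside the duplicated segment are never unique:
query_region(fs, "chr1", 191, 195, read_length = 30L)
#>   position mul unique
#> 1      191   0  FALSE
#> 2      192   0  FALSE
#> 3      193   0  FALSE
#> 4      194   0  FALSE

prop <- proportion_unique(fs, data.frame(seq_name = "chr1",
                                         start = 0L, end = 1200L), 30L)
prop$pooled
#> [1] 0.8787361

# a 150 bp single-exon gene straddling the repeat's left edge
txs <- generate_transcriptome(list(list(gene_id = "G1", chrom = "chr1",
  start = 131L, strand = "+", exon_lengths = 150L,
  isoforms = list(T1 = 1L))))
pl  <- simulate_read_placements(txs, c(T1 = 400L), 30L, seed = 2L)
aln <- placements_to_alignments(pl, txs, gen$sequences, 30L,
                                genome_index = idx, unique_only = TRUE)
reads <- data.frame(chrom = aln$chrom, pos5 = aln$gstart, strand = "+")
quantify_expression(reads, gene_models(txs), fs, 30L)
#>   gene_id read_count raw_length effective_length raw_rpkm norm_rpkm    ratio
#> 1      G1        185        150               79  6666667  12658228 1.898734
```

Only 79 of the gene's 150 bases are uniquely mappable at 30 nt, so the
multimapping reads lost to the repeat are compensated by quantifying
against the effective length: the normalized RPKM is 1.9× the raw one,
exactly `raw_length / effective_length`.

Other entry points: `compute_bisulfite_mul()`,
`compute_transcript_mul()`, `estimate_effective_lengths()`
(paired-end), `parse_annotation()` (refFlat/BED12), and
`read_alignments()` (SAM/BED). A command-line front end is installed at
`exec/mulmap` inside the package library
(`file.path(find.package("mulmap"), "exec", "mulmap")`) with
subcommands `build-genome`, `build-bisulfite`, `query`, `proportion`,
`rpkm`, and `simulate`.

See the vignette (`vignettes/minimum-unique-length.Rmd`) for the full
model, parameter rationale, and limitations.

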