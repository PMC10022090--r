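# npolyalign

Repeat-aware realignment of mapped long reads with context-dependent gap
penalties, for anyone working on pileup-based small-variant calling from
nanopore data.

Nanopore basecallers mis-call the length of homopolymers and short tandem
repeats, so mapped reads are littered with small insertions and deletions
whose placement varies read to read. A conventional affine gap penalty
(`G_open + (len − 1)·G_extend`, context-free) prices a one-unit change
inside a long repeat the same as a gap in unique sequence, which scatters
these events across inconsistent alignments — and most true small INDELs
sit exactly in those repeats. `npolyalign` realigns each read globally
against its original reference window under penalties defined as measured
negative log event frequencies, with dedicated transitions for changing
the copy number of an *n-polymer* (≥ 3 exact copies of a 1–6 bp unit):

- substitutions: `P[i,j] = −log((C_P[i,j]+ε) / (ΣC_P[i,·]+ε))`
- affine gaps: least-squares fit of per-length INDEL frequencies,
  defaults `G_open = 5`, `G_extend = 1`
- copy-number changes: `N[n,i,j] = −log((C_N[n,i,j]+ε) / (ΣC_N[n,i,·]+ε))`,
  regularized so penalties rise with INDEL size and fall with polymer
  length

The aligner is a five-matrix dynamic program — delete, insert, match,
shorten, lengthen — where shortening/lengthening moves consume whole
repeat units and are admitted only where the reference annotation marks a
polymer (entry at its first unit, which canonicalizes INDEL placement).
Realignment is evaluated only inside a band that follows the read's
original alignment path ("follow-banding", default half-width 30), so
memory and time are linear in read length. The package also provides
penalty estimation from SAM/BAM confusion statistics, Gini-purity
read-concordance histograms (`GP = Σ pᵢ²` per pileup column, insertions
scored separately), phased truth-VCF standardization that re-expresses
variants in the realigner's preferred representation while preserving the
haplotype sequences exactly, and a seeded synthetic-data generator.

## Worked example

A read that drops one `A` from a 7-base homopolymer:

```r
library(npolyalign)
model <- default_model()
ref   <- "GGCTGAAAAAAACTGGACGT"
read  <- "GGCTGAAAAAACTGGACGT"
ann   <- annotate_reference(ref)
align(read, ref, ann, model)
#> alignment: score 2.7890, CIGAR 5M1D14M (window 1..20)
align(read, ref, NULL, model, use_npoly = FALSE)
#> alignment: score 5.1910, CIGAR 5M1D14M (window 1..20)
```

Both runs place the deletion at the polymer start, but the repeat-aware
score charges the copy-number penalty `N[1, 7, 6] = 2.598` instead of
`G_open = 5`: the model knows a one-unit slip in a 7-mer homopolymer is a
likely event. On harder inputs (a deletion in one polymer next to an
insertion in another) the affine aligner trades the pair for
substitutions while the repeat-aware aligner keeps two clean copy-number
INDELs.

End to end, on a simulated 865 bp reference carrying 36 designed polymers,
phased one-unit copy-number variants, and naively aligned reads at 40×:

```r
res <- realign_bam("naive.sam", c(ctg1 = ref_seq), model, "realigned.sam")
res$counters
#> realigned passed_through  band_failures skipped_contig
#>        99              0              0              0
gini_histograms("naive.sam")
#> Gini purity: 806 scored columns (mean GP 0.9744), 805 scored insertion gaps
gini_histograms("realigned.sam")
#> Gini purity: 806 scored columns (mean GP 0.9756), 805 scored insertion gaps
```

Realignment raises mean column concordance and empties the
low-concordance tail (columns with GP < 0.5 drop from 4 to 0 in this
run): the same reads, re-expressed consistently.

A thin command-line wrapper over these functions is installed as
`exec/npolyalign` (subcommands `train-model`, `realign`, `gini`,
`standardize-vcf`, `simulate`, `align`).

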