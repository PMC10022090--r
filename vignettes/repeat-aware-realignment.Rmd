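---
title: "Repeat-aware realignment with context-dependent gap penalties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware realignment with context-dependent gap penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npolyalign)
```

## The problem

Nanopore basecallers call the length of repeated sequence poorly: the pore
senses 5–6 bases at a time, so a homopolymer or short tandem repeat produces
a nearly constant signal from which the repeat length is hard to recover.
The practical consequence for variant calling is that mapped long reads
carry many small insertions and deletions inside repeats, and a standard
affine-gap aligner — whose gap costs `G_open` and `G_extend` are independent
of context — places them inconsistently from read to read, or trades them
for substitutions when a nearby repeat absorbs the length change. Pileup
columns over such regions disagree across reads even where the underlying
molecules agree, and pileup-based variant callers lose recall exactly where
most true INDELs live.

`npolyalign` realigns mapped reads globally against the reference window
their original alignment consumes, using penalties that reflect how likely
each event actually is. The unit of context is the *n-polymer*: at least
three exact copies of the same repeat unit of length 1 to `n_max = 6`
bases. `AAAAA`, `ACACACAC` and `TTGTTGTTG` qualify; `ATAT` (two copies) and
irregular repeats such as `AATTAATT` do not. A *copy-number INDEL* adds or
removes whole units of an n-polymer.

## Penalties as measured negative log frequencies

Every alignment penalty is the negative natural log of a measured event
frequency, so the minimum-penalty alignment is the maximum-likelihood
explanation of the read under an independence assumption. Three components
are estimated from alignment confusion statistics (`count_confusions()`,
`train_model()`), each smoothed with a constant `eps = 0.01` that guards
events never observed:

* **Substitutions.** `P[i, j] = -log((C_P[i, j] + eps) / (sum(C_P[i, ]) + eps))`
  from the 4×4 matrix of aligned reference/read base counts. Matches are
  scored with `P[x, x]`, not zero — the diagonal carries the (small) cost
  of the no-error event.
* **Affine gaps.** Insertion and deletion run-length counts give per-length
  penalties `-log((C[len] + eps) / (sum(C) + eps))`; a least-squares fit of
  `penalty(len) ~ G_open + (len - 1) * G_extend` (clipped at zero) yields
  the gap parameters. The defaults are `G_open = 5`, `G_extend = 1`, so a
  3-base gap in unique sequence costs 7.
* **Copy-number changes.** The tensor `N[n, i, j]` is the penalty for
  observing `j` copies of an n-unit where the reference has `i`, from a
  `6 × 100 × 100` count array row-normalized over observed lengths. An
  expected copy number is clamped to 99 for lookups; runs longer than that
  keep their true `l` in the annotation.

A useful consequence of the log scale: misestimating an event's
probability by a factor of two moves its penalty by only `log 2 ≈ 0.69`,
so the model is robust to the circularity of measuring error rates from
imperfectly aligned input.

### Regularity of the copy-number tensor

Sparsely observed rows make raw `N` values noisy, so two monotonicity
families are enforced after estimation:

1. within a row, penalty strictly rises with INDEL size `k`
   (`N[n,i,i±k] < N[n,i,i±(k+1)]`) — smaller copy-number changes are more
   likely;
2. at matching `k`, a longer polymer's penalty is strictly lower
   (`N[n,i+1,(i+1)±k] < N[n,i,i±k]`) — longer polymers contain INDELs more
   often.

The source prints both properties with the opposite inequality direction
from its prose; this package implements the prose semantics (the
directions above) and `npolymer_penalties(printed_direction = TRUE)`
flips them for comparison.

Enforcement is an ordered single pass, ascending in copy number: each row
is first made strictly `k`-monotone by raising the farther cell minimally,
then the next row is clamped strictly below it. Two properties of real
count data shaped this design. First, rows with *no* observations are
uninformative — the smoothed formula collapses them to zero penalty — so
they inherit the running bound rather than acting as clamp sources.
Second, rows below the first observed copy number can never occur (a
polymer needs at least three copies), so they are raised above the
observed region afterwards; this keeps the global property without
distorting any row the aligner can index. The pass provably reaches a
fixed point in one sweep: clamping preserves within-row monotonicity
(the pointwise minimum of two strictly increasing rows is strictly
increasing), and re-fixing a clamped row cannot push it back above its
predecessor.

`default_model()` avoids empty rows entirely by filling the tensor from a
parametric error profile (`copy_error_profile()`): the error rate rises
quadratically with polymer length, halves per unit-length increase, and
spreads geometrically over INDEL sizes with a slight excess of
insertions. At its defaults a length-10 homopolymer has a 45 percent
INDEL rate. A model trained on a small alignment set would assign
near-zero penalties to unobserved rows (the eps-only limit of the
formula), which is unusable for realignment; the parametric default is
the recommended model when no large training BAM is available.

## Reference annotation

`annotate_reference()` stores, for every unit length `n` and every
reference position that starts a repeat unit, the total copy number `l`
and the 0-based unit index `idx` (zero elsewhere). Phase-shifted
overlapping polymers of the same `n` are each annotated — `ATATATAT`
carries both AT×4 and TA×3 — and annotations for different `n` overlap
freely. `N` bases compare unequal to everything, including themselves,
and break repeats. The per-contig annotation is computed once and shared
by all reads; window slices (`annotation_window()`) keep full-polymer
copy numbers deliberately, because `l` means the expected copy number of
the whole polymer even when a window cuts it.

## The five-matrix dynamic program

`align()` runs a global dynamic program with matrices D (deleting),
I (inserting), M (matching), S (shortening) and L (lengthening), computed
in lockstep in that order. D and I are the usual affine recurrences;
M takes the minimum of the diagonal move and the other four matrices at
the same cell (hand-back carries no extra cost, because traceback happens
entirely within M). S consumes one reference unit per move and L one
read-side unit, writing their results forward — `S[i, j+n]` and
`L[i+n, j]` — under the gating conditions:

* entering S or L requires the polymer start (`l > 0` and `idx == 0`),
  which canonicalizes every copy-number INDEL to the left edge of its
  polymer;
* continuing S requires a unit start whose `idx` equals the units already
  removed (`idx == run/n`), which pins the run to the polymer it entered —
  the unit-start condition alone would let a run leak across adjacent
  polymers;
* L additionally requires the next `n` read bases to equal the reference
  unit, checked at every step.

A run of `k` units is charged the single lookup `N[n, l, l∓k]` — the
lookup *replaces* the previous one rather than adding to it, so each S/L
cell stores the value at the run's entry point alongside its own value
and run length.

Two storage decisions matter for exactness. Runs keep the unit length
they entered with: a shortening run that entered as a 3-polymer run may
not continue as a 6-polymer run, since that would re-price the same
deleted bases as a different event. And S/L keep one slot per unit
length, because runs of different `n` through the same cell are distinct
continuation states; for S this makes the program exact (at a fixed
column, `idx` pins the run length of any continuable candidate, so the
per-slot minimum is sufficient). For L a residual approximation remains:
two same-`n` runs entered at different rows can reach the same cell, and
only the cheaper is kept. With geometrically decaying error profiles the
per-unit penalty increments are nearly constant, which is exactly the
regime where this collapse is loss-free; the test suite's exhaustive
path enumeration has not exhibited a counterexample at the sizes it can
cover.

Other numerical choices: ties in M are broken in the order diagonal, S,
L, D, I, which prefers the repeat-aware representation and makes CIGARs
byte-deterministic; alignment is anchored at both ends (`M[0,0] = 0`,
borders reachable only through gap chains) because realignment trusts
the mapped span; non-ACGT read bases are charged the maximum entry of
`P` and are never eligible for S/L; an empty window with a nonempty read
yields a pure-insertion CIGAR. With S and L disabled the program reduces
exactly to Needleman-Wunsch with affine gaps, which the test suite
verifies against an independent three-matrix implementation.

`score_cigar()` re-prices an existing CIGAR as the cheapest decomposition
of each gap run into affine segments and gated whole-unit runs; replaying
an emitted alignment reproduces its score, and replaying the input CIGAR
gives the realignment's improvement.

## Follow-banding

Realignment does not need the full `|r| × m` matrix: the new optimum lies
near the original alignment path. `banded_align()` expands the original
CIGAR into an insertion/deletion path (every M becomes I-then-D), walks
one anti-diagonal of width `2b + 1` at a time centered on that path, and
stores the band as a `(2b+1) × (|r| + m)` workspace — memory is linear in
read length regardless of window size. Cumulative offset arrays map band
cells back to matrix coordinates (`row = INSs[i] + b - j`,
`col = DELs[i] - b + j`). Cells outside the band are unreachable;
forward S/L writes that would land outside are dropped. Because the
supplemented original path itself lies in the band, the terminal cell is
always reachable for a consistent input CIGAR, and the banded score can
never beat the unbanded optimum; with the default half-width `b = 30`
the two agree on all simulated reads in the test suite. The band
half-width is the `±50 bp` small-variant window of the method realized
as a path-following band rather than re-mapping.

## The realignment pipeline

`realign_bam()` trusts POS, replaces each mapped primary alignment's
CIGAR with the banded realignment of its read against the window the old
CIGAR consumed, recomputes NM/MD, and passes everything else through
byte-identically — sequence, qualities, flags, names, tags, soft and
hard clips (clipped prefixes/suffixes are excluded from the aligned
window). Secondary, supplementary and unmapped records are untouched.
Work is partitioned by contig; the output is independent of the worker
count. A band failure falls back to unbanded alignment up to a window
length cap, else the original record passes through and is counted.

## Concordance: Gini purity

`gini_histograms()` quantifies read agreement per reference position as
`GP = sum(p_i^2)` over the class proportions A, C, G, T and deletion:
1 when unanimous, 0.5 for a two-way even split, 0.2 for the worst
five-way split. Insertions are scored separately per inter-base gap with
one class per insertion string (the empty insertion included), because
their variable class count shifts the distribution. Columns shallower
than `min_depth = 5` reads are skipped rather than scored — the statistic
is meaninglessly noisy there and the method is silent on a threshold.
Reads can be grouped by their HP tag before scoring, which removes the
mixing contributed by true heterozygous variants.

## Truth-VCF standardization

`standardize_vcf()` rewrites a phased truth VCF into the representation
the realigner tends toward, without changing the haplotypes it implies:
apply the phased variants to obtain both haplotype sequences and their
construction CIGARs (`apply_phased_vcf()`); treat each haplotype as a
read at position zero and realign it with the banded aligner, the
construction CIGAR seeding the band; parse every substitution, insertion
and deletion run of the result into records; merge the two haplotypes'
records into genotyped phased records (a multi-allelic `1|2` record when
position and REF coincide exactly, separate phased records otherwise —
the merging rule is unspecified upstream and this is the package's
choice). Processing is chunked at variant-free stretches of at least
200 bp, split mid-run, so whole-contig alignment is never needed; chunks
are independent, so the output is identical where the band assumption
holds. The invariant — reconstructed haplotypes are byte-identical
before and after — is property-tested on random toy VCFs. Records use
1-based coordinates with the usual anchor-base convention for INDELs;
an edit at the first reference base anchors on the following base.

## What the synthetic data emulates

The generator (`sim_config()`, `make_reference()`, `simulate_reads()`,
`make_phased_truth()`) builds references with designed polymers embedded
between repeat-free spacers, and reads carrying three error processes:
substitutions (default 0.5 per kb) and short affine INDELs (1 per kb
each way) in unique sequence, and copy-number INDELs inside designed
polymers drawn from the same parametric profile as `default_model()`.
Junctions are constrained so concatenation cannot extend a designed
polymer or any of its phase shifts — the adjoining character may not
continue the unit's period on either side — which keeps the designed
copy numbers exact and, more importantly, keeps measured confusion
frequencies identifiable: a phase-shifted mirror polymer whose span is
offset by one base systematically skips real events through the
whole-unit parity rule and biases estimation.

Two CIGAR modes serve different experiments. `"truth"` emits the
generating CIGAR (unit-aligned INDELs at polymer starts) and is the
right input for estimation-recovery experiments. `"naive"` emits a plain
affine-gap alignment under a mildly substitution-favouring scheme, which
merges opposing INDELs of nearby polymers into substitution runs the way
minimizing aligners do — this is what gives realignment something
measurable to fix. The generator can also overlay phased one-unit
copy-number variants (`het_cn_frac`), assigning reads alternately to two
haplotypes with HP tags; genuinely mixed pileup columns only arise
around true heterozygous variants, and the low-concordance columns the
end-to-end experiment tracks are naive-alignment scatter around exactly
such sites.

What it does not emulate: signal-level artefacts, quality-correlated
errors, chimeras, coverage biases, mapping errors (reads are placed at
their true positions). Passing tests therefore demonstrate the
alignment, estimation and evaluation machinery under a controlled error
process, not basecaller realism.

## Problem sizes in the shipped experiments

The test suite verifies oracle equivalence on 1000 random affine pairs
(≤ 12 bp) and 200 repeat-rich pairs (≤ 10 bp) against exhaustive
enumeration; band exactness and the end-to-end concordance experiment
run on simulated references of roughly 2–4 kb at 15–40× depth; the
estimation-recovery experiment uses rows of 20–40 polymers at 520×
depth with a one-unit error profile, sized so every assessed tensor
cell carries well over a thousand observations (homopolymer lengths 7
and 11 are chosen so their phase shadows fall outside the assessed
rows); the standardization round trip covers 100 random phased VCFs.
These sizes were chosen as the smallest at which each property is
measured with comfortable statistical margin.

## Known limitations

* The L matrix's same-unit-length collapse (above) is inherited from the
  single-slot-per-cell storage of the published algorithm; it is exact
  for constant per-unit penalty increments and approximate otherwise.
* Polymers that begin before the realignment window start cannot be
  entered (their `idx == 0` column lies outside the window); such reads
  fall back to affine gaps over the truncated polymer.
* The strict exact-repeat definition excludes near-repeats
  (`AAATAAAATAAAT…`), where reduced penalties might also help; relaxing
  it would enlarge the gated search space.
* Base qualities are ignored throughout, as the penalty model is
  frequency-based.
* Estimation from an already-biased BAM inherits that bias, bounded by
  the log-2 argument above; a second estimation pass over realigned
  output is possible but not implemented.
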