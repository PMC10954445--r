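---
title: "Methods: nonreference-sequence discovery, genotyping and population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonreference-sequence discovery, genotyping and population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A linear reference genome omits DNA that segregates in real populations.
Sequence present in an individual but absent from the reference — a
*nonreference sequence* (NRS) — is equivalent to an insertion-type
structural variant, typically 50 bp and longer, and is discovered by
assembling each individual's genome and asking which parts of the
assembly fail to align to the reference.  `nrskit` implements the full
desk-scale arc of such a study: a seeded simulator of reference +
population assemblies with planted events; extraction of unaligned
segments with depth, satellite and contamination filters; flank-based
anchoring of each segment to a reference insertion point; merging of
per-sample calls into a nonredundant population catalogue with stable
`GNRS_*` identifiers; presence/absence genotyping with Hardy–Weinberg
and trio-Mendelian validation; and the inference layers on top: allele
frequency classes, growth curves, PCA, the population branch statistic
(PBS) with downsampling consensus and a platform batch-effect filter,
cis-eQTL and GWAS models, and LD against phenotype-associated SNPs.

## The simulated world

The generator's defaults describe one fixed world, used by the
acceptance suite and documented here; they are not tuning knobs.

* Reference: 2 chromosomes × 1 Mb at GC 0.41, one satellite array
  (20–40 kb of exact monomer copies, from a bundled *synthetic* monomer
  library) marking the arm boundary of each chromosome, and 25 annotated
  genes per chromosome with TSS and two exons.
* Panel: three populations (EAS/AFR/AMR) × 20 samples, plus 2 trios
  whose offspring are extra samples; platforms alternate ONT/HiFi within
  each population so the batch-effect filter has contrasts.
* Events: 300 planted insertions of 50 bp–3 kb: 45% tandem repeat
  (k copies of a 2–100 bp motif), 30% mobile-element-like (copies of two
  shared library elements, 300 bp and 6 kb, at 1–5% divergence), 25%
  unique novel sequence — a mix spanning the repeat-heavy composition of
  real nonreference callsets.  Per-population allele frequencies draw
  from Beta(0.4, 1.2) (U-shaped: singletons through common events);
  3 selection events get AF 0.9 in EAS vs 0.05 elsewhere.
* Assemblies: both haplotypes are emitted per sample, fragmented by a
  Poisson breakpoint process (3 per Mb, contigs a few hundred kb); 5% of
  contigs are contaminants from a GC-shifted Markov composition model;
  1% of event-carrying contigs get 3.5× depth as filter bait; depth is
  20× with 5% noise.
* All randomness flows from one seed through named substreams
  (`derive_seed(seed, stage)`), so any stage can be re-run independently
  and a fixed config is byte-reproducible.

What the generator does **not** emulate: sequencing error and read-level
artefacts, assembly collapse in segmental duplications, alignment
ambiguity in long homologous repeats, population LD structure beyond
per-event independence, and cross-population admixture.  A green
recovery test therefore establishes that the pipeline's logic is
correct on clean assemblies — not that it would match a real-world
callset's precision.

## Alignment machinery and numerical choices

All coordinates are 0-based half-open internally; VCF output alone is
1-based.  Identity is matches ÷ alignment columns (gap columns
included); coverage is aligned query bases ÷ query length; these two
definitions are used everywhere.

`align_pair()` is a k-mer seeded aligner (k = 15): seeds are sampled,
matched against a target index, clustered by diagonal, and either
extended by full dynamic programming on a seeded window (queries
≤ 12 kb) or chained colinearly with per-gap dynamic programming (long
contigs).  Two choices matter:

* **Seed multiplicity cap.** k-mers occurring more than 32 times in the
  target are dropped from the index, as read aligners do.  Satellite
  arrays therefore surface as unaligned segments — and are then removed
  by the ≥ 80% satellite-masking filter, which is exactly the flow the
  pipeline wants.
* **Stiff scoring.**  Defaults are match +2, mismatch −4, gap open −4,
  extend −1.  With soft penalties (mismatch −1, gap −0.5) a local flank
  alignment drifts tens of bases across an insertion junction, because
  chance matches plus cheap gaps keep the score afloat; the stiff
  scheme pins the alignment end at the junction.  The scheme
  +2/−1/−0.5 is used only where it is part of the method itself:
  representative selection.

`seq_similarity()` does direct dynamic programming with no seeding and
is used wherever two *specific* short sequences must be compared
(cluster matching, record verification): seeded search is structurally
blind to tandem-repeat sequences whose k-mers the multiplicity cap
removed.

**Anchoring.**  1 kb flanks are cut from the contig on each side of a
segment, with a 50 bp overshoot into the segment, and aligned locally
to the reference.  A segment is placed when both flanks align > 500 bp
on the same chromosome and strand and the signed reference gap between
their inner endpoints is < 20 bp.  A *negative* gap (the flank images
cross) arises when the insertion shares sequence with the reference at
the junction — tandem-repeat slippage or microhomology — and is
tolerated up to the 50 bp overshoot, with the floored midpoint as the
insertion point.  Without this allowance, legitimate tandem-repeat
insertions with ~25 bp of junction homology are systematically lost
(observed on the synthetic panel); the placement error stays within
half the homology length.

**Tandem-repeat detection** compares the sequence against itself at
every candidate period (1–100), merges agreement runs allowing
interruptions up to 20% of a unit, requires ≥ 5 copies at ≥ 80% unit
agreement, and reports the lexicographically least rotation of the
primitive unit.  Candidates are accepted greedily longest-array-first,
suppressing re-detections at period multiples.  A subsampled prefilter
skips periods whose global agreement fraction is near the 0.25 random
baseline; arrays covering less than about a quarter of the sequence can
be missed by design — the filters that consume these annotations
trigger at 80% coverage.

**Representative selection.**  The merging stage scores each cluster
member as the sum of its optimal pairwise global alignment scores
against all other members under match +2, mismatch −1, gap −0.5 per
position (the gap extension equals the opening penalty, as only an
opening penalty is specified for this stage), and picks the argmax with
deterministic tie-breaks (longer, then lexicographically smaller, then
input order).  A projected multiple-alignment score was considered and
rejected: projected pairwise scores depend on the centre choice and
cannot be guaranteed to agree with brute-force pairwise scoring, which
the package's own invariant (and test oracle) requires.  Long
near-identical members — offset-shifted copies of one insertion with
different flank slack — are scored by locating the shared core with an
anchor k-mer and scoring the implied gapped alignment directly; the
full dynamic program is always used at or below 64 bp (where exactness
against the brute-force oracle is asserted) and for any pair the
anchor route cannot explain at ≥ 80% overlap identity.

**Cluster splitting.**  Placed calls cluster by single linkage at
250 bp, then clusters are split farthest-point-first (the two extreme
positions seed two groups, ties join the lower seed) until every
pairwise distance is ≤ 250 bp.  On all small inputs the number of
clusters equals the brute-force optimum (tested exhaustively up to six
calls).

**Hotspots.**  Insertion-point density (Gaussian kernel, bw 200 kb, 512
grid points per chromosome) is compared against `trials` uniform draws
over the non-satellite genome; maximal regions above the pointwise 95th
percentile containing at least two insertion points are reported with
the add-one empirical p-value `(1 + #trials with global peak ≥ observed
peak) / (trials + 1)`.  The two-point minimum exists because a single
point's own kernel mass always exceeds a sparse null pointwise, yet
indicates no clustering.

**Hardy–Weinberg.**  The exact conditional test enumerates the
distribution of the heterozygote count given the allele counts
(multinomial kernel `2^h / (n_AA! n_Aa! n_aa!)`), summing probabilities
of configurations no more probable than observed; it matches a full
independent enumeration for all genotype configurations up to n = 20.

**PBS.**  FST uses Hudson's estimator (the common choice for PBS and
the only fully specifiable one), clamped to [0, 1 − 1e−9] before
`T = −log(1 − FST)`; negative estimates clamp to 0.  The scan
downsamples the focal population to 40 without replacement, 10 times;
loci in the top 0.1% in ≥ 7 replicates whose platform batch-effect
q-value is ≥ 0.05 are candidates; candidates chaining within 1 Mb merge
into one signal represented by the max-mean-PBS locus.

**Associations.**  cis-eQTL and quantitative GWAS use a residualised
closed-form linear model (verified against `lm()` per locus), logistic
GWAS uses `glm`; BH correction via the standard step-up (tested against
a hand enumeration).  λ_GC = median(χ²)/0.4549.  BMI is excluded from
its own covariates.  Missing genotypes in LD computations are coded
homozygous reference by default (`"as_ref"`), matching the catalogue-LD
convention; pairwise deletion is available.

## Degenerate inputs and edge policies

Empty alignments return zero-row frames, never NULL; an all-missing
locus yields an undefined-AF record, flagged; constant dosage vectors
give `NA` LD with a `"constant"` attribute; monomorphic loci give HWE
p = 1; a catalogue without placed records aborts the pipeline with a
clear error.  `filter_unplaced()` is idempotent, and the three
extraction filters commute (each writes only its own flag).

## Scaling of the verification suites

Calibration suites run at reduced but honest sizes so the whole test
suite fits a desk budget: the eQTL null uses 12–15 panels of
50 × 50–150 rather than 50 panels of 500 × 200; hotspot calibration uses
12–40 replicates at 150–200 trials; the GWAS family-wise check uses
2000 loci × 40 replicates (the λ_GC check runs at the full 5000 loci).
Monte-Carlo tolerances are widened only by the corresponding standard
errors, never beyond the stated nominal levels.

## Known limitations

* The genotyper counts contig breakpoint evidence (at most two
  haplotypes of evidence per sample); with the default minimum support
  of 2, loci where one haplotype's contig is fragmented near the
  junction come out missing (`./.`) rather than half-called.  A true
  graph genotyper can be swapped in behind the same per-sample contract.
* Stage intermediates are written as plain text with a MANIFEST, but
  automatic resume-from-intermediate is not implemented.
* Minus-strand flank anchoring falls back to full dynamic programming;
  the fast chain path assumes the contig orientation matches the
  reference, which the simulator guarantees but real assemblies do not.
* The hotspot null draws uniformly from the non-satellite genome at
  1 kb granularity; real accessibility masks are richer.
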