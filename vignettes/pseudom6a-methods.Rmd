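---
title: "Models and methods behind pseudom6a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pseudom6a}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pseudom6a` joins five omics layers — MeRIP-seq m⁶A methylation,
expression, survival, genetic alteration and miRNA seed structure — into a
single candidate-prioritization pipeline for pseudogene-derived RNAs. This
vignette documents the models, the assumptions behind them, the tunable
parameters, and the choices made where the design was genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## Coordinates and the gene catalog

All internal coordinates are 0-based half-open; GTF I/O converts at the
boundary (GTF is 1-based inclusive) and BED output is native. A catalog
holds one transcript model per gene. Pseudogene biotypes are mapped onto
the four standard classes — processed, unprocessed, unitary, polymorphic —
and anything else is kept as an ordinary gene. Parent pairing is an input
table (annotation resources differ on how they define the cognate parent,
so the mapping is the user's choice); the synthetic generator always emits
one. Region labels are strand-aware: 5'UTR/3'UTR, TSS/TTS follow the
transcription direction, and the TSS/TTS windows default to ±1000 nt
(configurable `flank`), a conventional promoter-scale window.

## Peak calling model

Exons are tiled at (`window_size` = 50 nt, `step` = 25 nt), both
configurable; windows never span exon junctions, and a trailing remainder
is kept only when it covers strictly more than half a window (a 100-nt
exon at 50/25 yields windows at offsets 0, 25, 50).

For a condition, IP and input counts are pooled across replicates. Each
window is tested with a one-sided 2×2 hypergeometric exact test of

    [ ip_w , ip_gene − ip_w ; input_w , input_gene − input_w ]

The background is the **rest of the same gene**, not the whole library:
the input sample measures the gene's background transcriptome level, and
conditioning on per-gene totals removes gene-level abundance fluctuations
(biological replicate noise, library composition) that a 2×2 null cannot
model. Pooling replicates instead of fitting a per-replicate GLM keeps the
test exact and oracle-testable; a dispersion-modelling extension is out of
scope. BH correction is applied over all windows; windows of one gene
within one `step` of each other merge into a peak. A peak's p-value is its
best window's; its enrichment score is `log2((IP CPM + 1)/(input CPM + 1))`
with the pseudocount guarding against log-of-zero.

Because sliding windows overlap, summing member-window counts would count
reads twice; pooled span counts therefore use a greedy non-overlapping
subset of member windows.

Differential methylation tests each union peak's
`[IP_t, input_t; IP_n, input_n]` table after scaling all four libraries to
their common mean size (rounded). Direction is the sign of the log odds
ratio (`hyper` = more methylated in tumour). Significance follows the raw
p < .05 convention used in this literature; BH q-values are always
reported alongside so users can apply an FDR rule instead.

The per-gene relative m⁶A level is `log2((IP CPM + α)/(input CPM + α))`
(α = 1) over the gene's significant peak spans, or the whole gene when it
has none; genes are ranked and cut into tertiles whose sizes differ by at
most one — the "tristile" stratification used for all level-vs-expression
analyses.

## Motif discovery

Discriminative, DREME-style: controls are per-sequence mononucleotide
shuffles (preserving each sequence's length and base composition — the
stated shuffling model, rather than a dinucleotide shuffle). Every exact
word of widths 4–8 occurring in the targets is scored by a one-sided exact
test on presence/absence counts (ZOOPS-style: a sequence counts once). The
best word is generalized greedily over IUPAC codes, accepting a degenerate
position only when it improves the p-value; the motif's matches are erased
(masked to N) and the search repeats, up to `max_motifs` = 5, stopping
when the best candidate fails a Bonferroni-corrected α over the number of
words tested in that round. RRACH matching treats a pattern of width ≥ 5
as RRACH-compatible when it contains a full RRACH window
position-by-position, and a width-4 pattern when it aligns inside a RRACH
sub-window — discriminative searches legitimately return 4-mers such as
GGAC when the planted signal is a mixture of RRACH variants.

## Differential expression

An internal negative-binomial moderated-Wald test (deliberately
self-contained so its behaviour is fully specified and testable against
simulation; it is not claimed to reproduce any external package's
numerics). Per gene, on the CPM scale: method-of-moments dispersion in
each group, averaged, then shrunk 75%/25% toward the across-gene trend
mean. The statistic is the log2 ratio of group means (+1 pseudocount) over
a delta-method standard error, referred to a t distribution with
`n_t + n_n − 2 + prior_df` degrees of freedom. `prior_df` (default 40)
credits the trend with the information it contributes — the moderation
logic of shrinkage estimators; with it, the measured type-I rate on null
NB data sits inside the binomial confidence band of the nominal 0.05
(computed by the acceptance checks, not asserted here). Directions are
called at q < .05.

CPM (+1, log2) is the expression unit everywhere downstream; it is simple,
library-size-robust, and the tertile/correlation analyses are rank-based
and insensitive to the choice among CPM-like units.

## Correlation, stratification and correspondence

Pseudogene–parent association uses Spearman correlation (average ranks for
ties) with classes Positive (ρ > 0, p < .05), Negative (ρ < 0, p < .05),
else No; a constant vector leaves ρ undefined and classifies No. Tertile
comparisons use two-sided Wilcoxon rank-sum tests (exact for small
tie-free samples through the standard implementation, normal approximation
otherwise); strata with fewer than 3 members are skipped and flagged.
Correspondence (Sankey-style) tables cross-tabulate two gene-level flags
and use chi-square unless any expected cell is below 5, where Fisher's
exact test takes over.

## Survival screening

Univariate Cox proportional hazards per gene, Efron tie handling (the
synthetic times are continuous, but user data are often discretized, where
Efron is the better approximation). The covariate is z-scored before
fitting so the hazard ratio reads per SD of expression. Risk = HR > 1 and
p < .05; protective = HR < 1 and p < .05. Monotone likelihood (perfect
separation) is flagged and the estimate capped at ±10. Kaplan–Meier
curves split at the covariate median by default (the dichotomization is
not standardized in this literature; median is the conventional neutral
choice) with the two-group log-rank test.

A note on recovery precision: with n = 500 and 20% censoring there are
about 400 events, so the sampling SD of a two-group log-HR estimate is
about `2/√400 ≈ 0.10` for any correct partial-likelihood estimator. An
interval of ±0.15 around the true log 2 therefore captures roughly 84% of
replicates — a property of the information content of the design, not of
the implementation, which the test suite verifies is unbiased and matches
a grid-search maximization of the Efron partial likelihood to 1e-4.

## ceRNA layer

Seed sites use the four canonical types with exact complementarity: the
core 6mer is the reverse complement of miRNA positions 2–7; 7mer-m8 adds
pairing to position 8 (immediately 5' of the core on the transcript);
7mer-A1 adds an adenosine opposite miRNA position 1 (immediately 3' of the
core); 8mer has both. One call per locus, highest type wins. No wobble
pairing, no thermodynamic scoring, no conservation filtering — the point
is a reproducible, offline-checkable rule rather than a database lookup.
ORF finding scans the three forward frames for ATG→stop spans;
`aa_length` counts codons from the ATG inclusive to the stop exclusive.
The bundled `inst/extdata/RPS15AP12_like_synthetic.fa` is a constructed
stand-in transcript with one planted 118-codon ORF (it is synthetic — see
its header — not the real transcript, which cannot be redistributed here).

## The candidate cascade

Ordered filters over the pseudogene universe, each recording survivors:

1. differential m⁶A at raw p < .05;
2. expressed ("stabilized RNA", operationalized as mean CPM ≥ 1 in at
   least half the samples of one condition — the notion is not precisely
   defined in this literature, so it is exposed as a threshold);
3. concurrent differential expression with sign opposite the m⁶A change
   (hypo→up, hyper→down; a non-directional switch exists);
4. prognosis at p < .05, direction-consistent (up+risk or
   down+protective);
5. genetic confound excluded (mutation frequency < 1%, CNV frequency
   < 5%, mirroring the observed ranges in this setting; configurable);
6. ceRNA evidence (≥ 1 shared miRNA and a positively correlated parent) —
   **annotation by default**, a hard filter only with
   `apply_cerna = TRUE`, since this layer corroborates a candidate rather
   than defining the funnel.

Survivors are ranked by
`|z(diff-m⁶A log2FC)| + |z(expression log2FC)| + |z(Cox β)|`, z-scored over
the survivors; ties break by smaller differential-m⁶A p, then id.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes, at
desk scale, with one master seed spawning named substreams per component
(adding a generator never perturbs another's draws):

* ~200 genes on 4 chromosomes, half pseudogenes; subtypes at 72%
  processed / 20% unprocessed / 5% unitary / 3% polymorphic (processed
  pseudogenes are intronless, mirroring their retrotransposed origin);
* MeRIP: 3 IP+input replicate pairs per condition, mean 30 input reads
  per window. Replicate noise is NB (variance μ + φμ², φ = 0.1, the
  typical bulk RNA-seq scale) at the **gene** level, with reads placed
  multinomially along windows; enrichment fold 4 at one planted RRACH
  (GGACU) window per methylated gene; 30% of genes methylated, a quarter
  each tumour-only (hyper) and normal-only (hypo);
* expression: 50 tumour / 30 normal samples, log-normal baselines, NB
  counts, 10% DE genes at |log2FC| = 2, pseudogene–parent coupling via a
  bivariate Gaussian on per-sample log-scale noise (ρ = 0.6; optionally
  attenuated linearly in the pseudogene's m⁶A rank), and gene means scaled
  by `exp(−γ·m⁶A level)` (γ = 0.3);
* survival: tumour samples only; exponential times with hazard
  `∝ exp(β·z)` of the planted risk gene's standardized expression
  (β = log 2), uniform censoring with its bound solved numerically for a
  20% censored fraction;
* genetics: Bernoulli mutations (0.5%) and sparse CNV states in −2..2
  (3%);
* one planted "driver": a processed, paired pseudogene forced to
  hypo-methylated + up-regulated + risk + unaltered, with a shared
  UUGGCA-core miRNA site planted in both its transcript and its parent's.

What the generator does **not** emulate: read-level data (no FASTQ/BAM),
GC or mappability bias, batch effects between expression cohorts,
overlapping genes, alternative isoforms, wobble-pairing miRNA sites, and
physically-overlapping window counts (each window is its own multinomial
category). Passing tests therefore demonstrate correctness of the
statistics under the stated model, not robustness to those artefacts of
real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the sizes chosen for the
package's validation studies: 200 genes for peak-caller recovery and the
end-to-end cascade (20 master seeds), 2000 null genes for DE calibration,
100 replicates for Cox recovery, 40 seeded runs of 50×100-nt sequences for
motif recovery, and 900 genes for the tertile analyses. Ties in rank
statistics use average ranks; tertile cuts differ by at most one gene;
odds ratios add 0.5 only when a table contains a zero; the one-phase decay
fit fixes the plateau at 0 by default (abundances are fractions of t = 0;
a free plateau is exposed as a parameter) and treats rates below 1e-6 as
no measurable decay.

## Known limitations

Peak resolution is window-scale, not single-base; the differential test
shares no dispersion information across peaks; the DE test is a
two-group-only design; Cox screening is univariate with no
proportionality diagnostics; seed matching ignores 3'-compensatory
pairing. These bounds are deliberate: every statistic in the package is
either exactly testable against an enumeration oracle or calibrated
against the generator's planted truth.
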