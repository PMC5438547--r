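---
title: "Quantifying transition and transversion effects on regulatory DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transition and transversion effects on regulatory DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tstvreg)
library(dplyr)
```

## The question

Single-nucleotide substitutions split into transitions (Ts: A↔G, C↔T,
4 of the 12 ordered substitutions) and transversions (Tv: any
purine↔pyrimidine exchange, the other 8). Because transcription factors
recognise binding sites through base identity *and* local DNA shape, and
because swapping a one-ring for a two-ring base distorts the backbone more
than swapping like for like, transversions are plausibly the more
disruptive class in regulatory sequence. `tstvreg` implements four
mutually independent analysis arms that each operationalise that
comparison, plus a synthetic-data module that generates all of their
inputs with known planted effects so that every statistical claim in the
package can be checked by parameter recovery.

All user-facing functions take data frames first and return tibbles, so
arms compose with the pipe; fitted models are returned as light
`tstv_fit` objects with `tidy()`, `glance()` and `autoplot()` methods.

## Arm 1: DNA shape

Shape prediction uses a pentamer lookup: a table mapping each of the 1024
ACGT 5-mers to four parameters — minor groove width (MGW, Å) and
propeller twist (ProT, degrees) read at the central base pair, roll and
helical twist (degrees) read at base-pair steps. `shape_profile()`
slides the window across a sequence; base-pair parameters are defined at
positions 3..L−2, and step parameters at steps 3..L−3 as the mean of the
step values of the two pentamers flanking the step. That mean is a design
choice — the pentamer model itself does not dictate how two overlapping
pentamer windows share a step — chosen because it is symmetric and
order-independent. Undefined edge entries are `NA` and are excluded from
all sums rather than zero-filled.

`run_shape_experiment()` draws random sequences (default 503 bp, an odd
length so "the middle base" is unique; the 503 bp default is
configurable), substitutes the middle base to all four alleles, and
scores all 6 unordered variant pairs per quartet — 2 transitions and
4 transversions, a ratio fixed by the combinatorics of the base alphabet.
The effect statistic is the summed absolute difference Σ|Δ| per parameter.
Because the pentamer model is strictly local, a substitution at position
*c* can only alter base-pair parameters at *c* ± 2 and steps *c* − 3..*c* + 2;
the implementation exploits this by profiling only a 17-bp window around
the mutation, and the test suite verifies window-vs-full equality
elementwise on 1000 quartets.

`compare_shape_effects()` contrasts the classes with a linear model in
which the identity of the starting sequence (the quartet) is a fixed
effect. With 10^5 quartets an explicit dummy expansion is intractable, so
the fixed effect is absorbed by within-quartet demeaning of both response
and class indicator; by the Frisch–Waugh theorem this is algebraically
identical to the dummy regression, and the residual degrees of freedom are
adjusted accordingly (n − #quartets − 1). A unit test checks exact
agreement with `lm()` plus explicit dummies on a 50-quartet instance.
Because the single summary number per class could be a mean or a median,
both are reported; the mean is primary and drives the Tv/Ts ratio.

The shipped generator `gen_shape_table()` draws pentamer values uniformly
within physically plausible ranges (MGW 2.8–6.2 Å, ProT −18–0°, Roll
−8–10°, HelT 30–40°). It exercises every code path but carries no real
structural signal, so with it the Tv/Ts shape ratios hover around 1; the
directional claims (Tv > Ts for MGW and roll, the reverse for ProT and
HelT) are properties of experimentally derived pentamer tables, which the
reader functions accept as a drop-in TSV.

## Arm 2: TF binding motifs

`read_jaspar()`/`write_jaspar()` handle the JASPAR flat PFM format (no
parser for it exists in the installed R stack, so the package carries its
own, round-trip tested). `pfm_to_pssm()` adds a pseudocount (default 0.1)
to every count, normalises columns to frequencies, and takes log2 odds
against a uniform background; scores are in bits so per-position
information content `2 + Σ f log2 f` lies in [0, 2]. Base-2 logs and the
uniform background are defaults (both configurable): bits are the standard
scale on which the IC bound of 2 holds. The consensus base is the
per-column score argmax with ties broken in A < C < G < T order.

`enumerate_mutation_scores()` scores every unordered base pair at every
position — `|Δscore|` is symmetric, so ordered enumeration would only
duplicate magnitudes — and attaches two covariates: the position's IC and
its normalised position `2·min(i, L−1−i)/(L−1)` (0-based *i*), which folds
the motif about its centre so 0 means either edge and 1 means the centre.
Folding reflects the edge/centre symmetry of motif specificity; the
unfolded coordinate is available via `fold_position = FALSE`.

`stratified_ts_tv_test()` partitions records into equal-width bins — 11
over normalised position, 20 over IC, matching the hypothesis counts of
the binned analysis it implements; equal-width is an assumption, and both
bin counts are arguments — and runs a Welch two-sample t-test (Tv vs Ts)
per bin. Welch is used because class sizes are unequal by construction
(2:1) and variances need not match. Per-bin p-values are reported
unadjusted with the Bonferroni threshold α/n_bins alongside; bins with
fewer than two records in either class are flagged untestable rather than
dropped. Calibration is checked by simulation: with deltas drawn from one
distribution regardless of class, the per-bin p-values are uniform.

## Arm 3: Allele-specific binding

The ASB arm consumes a neutral TSV of tested SNPs (chrom, pos, ref, alt,
TF-or-cell-line group, ASB flag); published call sets are converted to
this layout rather than parsed in their bespoke formats.
`collapse_redundant()` reduces variants listed for several groups to one
record per (chrom, pos, ref, alt) key, keeping the ASB flag if any group
set it; collapsing is idempotent and deterministic (sorted output).

`asb_enrichment()` compares the Tv fraction among collapsed ASB variants
(p1, n1) with the fraction among all tested variants (p0) using the
pooled two-proportion Z-test `z = (p1 − p0)/sqrt(p̂(1−p̂)(1/n1 + 1/n0))`,
two-tailed. Two pooling conventions set n0: `"across_groups_mean_n"`
(default) uses the mean tested count per group — the right convention when
the per-group tested sets overlap by an unknown amount, as when pooling
one TF across cell lines — and `"union"` uses the total collapsed count.
The mean-n convention deliberately understates the null sample size, which
makes the test conservative (simulated type-I error ≈ 0.02 at α = 0.05);
the Z-test itself is calibrated, which the acceptance suite verifies under
union pooling (empirical type-I within binomial error of 0.05 over 1000
null replicates). ASB variants are treated as a subset of the tested set
and are not excluded from the null, and a one-sample variant
(`one_sample_z_test()`, null proportion fixed) is provided as the
alternative reading of a binomial-to-normal enrichment test.

## Arm 4: Reporter assays

### Population-scale haplotypes

Haplotypes are comparable only within an amplicon (identical capture
coordinates), so `group_by_amplicon()` nests them per amplicon and
`choose_reference()` designates one member per amplicon as the reference
by a seeded uniform draw (processed in sorted order, so the choice is
independent of row order). `build_contrasts()` compares every other
member to the reference at the amplicon's segregating sites — either from
an explicit allele table (haplotype, 1-based position, base) or from
aligned FASTA sequences via `alleles_from_sequences()` — classifying each
differing site as Ts or Tv and recording
`delta_mag = |log2(effect) − log2(effect_ref)|`. Amplicon groups without
any haplotype at effect p < 0.05 are removed by `filter_groups()`
(the reference's own p-value counts toward the filter). Coordinates
follow the two standard conventions — BED intervals 0-based half-open,
variant positions 1-based — with the conversion centralised in one
predicate.

`fit_model()` runs OLS of `delta_mag` on Ts/Tv presence indicators,
counts, or counts restricted to the middle third of the amplicon's DHS
interval (`[start + ⌊L/3⌋, start + ⌊2L/3⌋)`), always with the amplicon as
a categorical covariate; p-values are two-sided t-tests. The middle-third
analysis re-counts substitutions inside the interval while keeping all
haplotypes (rather than subsetting haplotypes), which preserves the
full-model Ts estimate by construction; both class terms enter one joint
regression by default, with separate per-class fits available
(`joint = FALSE`) since either reading of "presence or absence of a Tv or
Ts" is defensible.

### Saturation mutagenesis

`read_satmut()` consumes per-mutation activity tables (element, 0-based
position, ref, alt, replicate fold changes). Replicates are averaged on
the ratio scale *before* the log: `|log2(mean(replicates))|` — averaging
first is the stated processing order of the data this re-analysis
targets. `satmut_ts_tv_test()` regresses that magnitude on a Tv
indicator; the pooled model adds the element as a categorical covariate
and the mutation's scaled distance from the element centre
(`|position − centre|/length`) as a location covariate — our fixed
reading of "adjusting for element and location", since the exact original
formulas are not published in the text this package works from —
and per-element fits drop the element term. The Tv p-value is one-sided
for β_TV > 0 (the directional hypothesis); covariate p-values stay
two-sided.

## The synthetic-data module

Generators are pure functions of their seed (`withr::with_seed`, leaving
the session RNG untouched) and write the standard formats (FASTA via
Biostrings, BED, minimal VCFv4.2, JASPAR, TSV). Defaults are the study
conditions the analyses are designed for:

* `beta_ts = 0.06`, `beta_tv = 0.12` — per-variant activity effects on the
  |Δlog2| scale, 100 amplicons × 8 haplotypes;
* `noise_sd = 0.03` — residual log2-activity noise, at the scale of the
  standard errors the coefficient estimates carry;
* ASB transversion fractions 0.3933 (ASB) vs 0.3416 (tested);
* `tv_shape_multiplier = 1.5` for the shape/saturation scale contrast;
* amplicons 425 bp with an interior DHS; segregating sites
  Poisson(5) per amplicon with uniformly drawn alternative alleles
  (1:2 Ts:Tv; `ts_bias` reproduces the ≈2:1 Ts:Tv ratio of natural
  variation when population-like data are wanted).

Haplotypes within an amplicon are distinct allele vectors (weighted by
`maf^k (1−maf)^(S−k)`), mirroring the fact that assayed haplotypes are
unique sequences; the first haplotype carries the reference alleles and is
flagged `reference = TRUE`. Parameter-recovery checks contrast against
that generative reference, under which the count model is exactly
well-specified; `choose_reference()` remains the analysis-faithful random
path, and because `delta_mag` is an absolute value, a random reference
mildly attenuates coefficients — a property of the design itself, not of
the implementation. The `"null"` scenario switches every planted effect
off and is used for type-I-error calibration.

What the generators do *not* emulate: linkage disequilibrium and
demography, real pentamer shape physics, motif-position dependence of
real ASB calls, or read-level noise. Passing tests therefore demonstrate
that the estimators recover known effects under the stated noise model —
not that any particular biological dataset will show them.

## Numerical choices and problem sizes

* Degenerate inputs fail with classed errors (`tstv_error_*`):
  single-class designs, rank-deficient regressions (naming the collinear
  term), pooled proportions of 0/1, mismatched site sets, malformed
  tables.
* Ties in consensus calling break toward A < C < G < T; equal-width bins
  close the right edge of the last bin.
* The test suite runs the arms at reduced but statistically meaningful
  sizes: 1000 shape quartets of 503 bp for the window-vs-full oracle, 200
  synthetic motifs for t-test calibration, 1000 null and 100 power
  replicates for the ASB Z-test, 200 recovery and 400 null replicates for
  the haplotype models, 150 null and 200 power replicates for the
  saturation arm. `scripts/acceptance.R` re-runs each arm once at those
  design sizes and writes every headline quantity as JSON.

## Limitations

The package analyses biallelic ACGT SNVs only (no indels or ambiguity
codes), treats motif positions as independent (no dinucleotide models),
consumes ASB calls and haplotype effect sizes as given (no read-level
processing or mapping-bias correction), and makes no attempt to reproduce
numbers that depend on external resources it does not ship — the
experimentally derived pentamer table, published ASB call sets, and
original reporter-assay supplementary tables plug in through the reader
functions when available.
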