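---
title: "Measuring transcriptional cis-effects of broad copy-number gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptional cis-effects of broad copy-number gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Broad copy-number gains (BCNGs) — trisomies and tetrasomies of whole
chromosomes or chromosome arms — are among the most recurrent somatic events
in solid tumours, yet each one touches hundreds to thousands of genes at
once. The gene-dosage transcriptional cis-effect (more copies, more
transcript) is the obvious mechanistic link between a BCNG and a selectable
phenotype, but the effect is modest (a trisomy yields on the order of a
1.2–1.3-fold bulk increase) and not uniform across genes. `bcngdose`
implements a cohort-level analysis designed to isolate that cis-effect and
ask which classes of transcripts are most susceptible to it: transcripts
already up-regulated in tumours, transcripts under aberrantly active
enhancers, and cancer fitness genes.

## The analysis

The pipeline is organised around a *selected group vs control group*
comparison for a target chromosome:

1. **Arm-level CNA calling.** Segmented copy-number profiles are reduced to
   per-region calls over a catalog of chromosomal regions (by default 42: p
   and q arms of the 17 non-acrocentric autosomes, the 5 acrocentric
   autosomes as whole chromosomes, Xp, Xq and Y). A region is *gained* when
   segments with copy number above the cohort ploidy (2) cover **strictly
   more than 50%** of it, *lost* symmetrically; exactly 50% is neutral.
   Samples with zero broad CNAs have a *normal karyotype*, one or two
   *near-normal*, more than two *aberrant*. A p-arm loss coupled with a
   q-arm gain is flagged as an isochromosome-like pattern, i(Nq).
2. **Group construction.** The *selected* group carries the BCNG of
   interest (whole-chromosome gain, or an isochromosome pattern); the
   *control* group is neutral on every region of that chromosome but is
   otherwise unconstrained, so both groups share the background aberration
   landscape. Their gain/loss frequency profiles can be compared by Pearson
   correlation after removing the structurally forced entries of the target
   chromosome.
3. **Four contrasts.** Counts are TMM-normalized and tested with an exact
   conditional negative-binomial test: FC1 (all tumours vs normals), FC2
   (selected vs control — the dosage contrast), FC3 (control vs normals),
   FC4 (selected vs normals). Fold-changes are reported as signed linear
   values (ratios below 1 as minus the reciprocal, so ½ is −2).
4. **Transcript taxonomy.** *VT* are transcripts with BH-FDR < 0.05 in a
   contrast; *OverT* are VT with linear FC2 > 1.3; *PositiveT*/*NegativeT*
   are transcripts significantly up/down in both FC3 and FC4;
   *Over-PositiveT* and *Over-NegativeT* intersect OverT with those.
5. **NCDI.** For a transcript class, the density in region *n* is
   `x_n / X_n` (class members over all transcripts there); the normalized
   chromosomal distribution index rescales densities to sum to 100 across
   regions. A class concentrated where gains are frequent produces a high
   NCDI exactly there; NCDI profiles are correlated against per-region
   aberration frequencies, and can be recomputed inside TPM bins to control
   for expression level.
6. **Enrichment.** OverT are tested for enrichment or depletion within
   PositiveT, NegativeT and externally supplied gene sets (fitness
   transcripts, gained-enhancer targets, focal-amplification transcripts)
   by a one-sided hypergeometric test per region, with the direction chosen
   by the observed overlap vs its expectation and the fold reported with
   the same signed convention.

## The differential-expression engine

The two-group test is an exact conditional negative-binomial test,
implemented in the package rather than delegated, so its behaviour is fully
specified here:

- **Normalization.** Trimmed mean of M-values with the published defaults:
  30% two-sided trim on M, 5% on A, inverse-variance precision weights, and
  the reference column chosen as the one whose upper-quartile/library-size
  ratio is closest to the cohort mean. Factors are rescaled to geometric
  mean 1. (The test suite cross-checks the factors against an independent
  implementation to ~1e-8.)
- **Expression filter.** Transcripts must exceed 1 count-per-million in at
  least `min(group sizes)` samples; all-zero transcripts are always
  dropped. The filter keeps dispersion estimation away from degenerate
  rows; the threshold is an argument.
- **Dispersion.** Libraries are equalized to their geometric-mean effective
  size (rounded pseudo-counts); per-group conditional log-likelihoods (which
  do not involve the mean) are evaluated on a 49-point log-spaced grid of
  dispersions from 1e-4 to 5. The cohort-common dispersion is the continuous
  maximizer of the average log-likelihood; per-transcript values maximize
  their own log-likelihood plus `prior_n = 10` transcripts' worth of the
  cohort average — shrinkage in the style of weighted-likelihood empirical
  Bayes.
- **Test.** Conditional on a transcript's total count, the group-A sum is
  beta-binomial under the null of equal means; the two-sided p-value sums
  the probabilities of all outcomes no more likely than the observed one.
  Under a pure null simulation (2000 transcripts, 15 vs 15) the empirical
  p < 0.05 rate lands within Monte-Carlo error of 0.05 (this is asserted in
  the acceptance suite).
- **Fold-changes.** Ratios of normalized group means with a prior count of
  0.5, reported as log2 and signed linear values.

Ties in p-values are handled by the standard BH step-up (`stats::p.adjust`);
the monotonicity pass makes tied p-values share the adjusted value of the
largest rank.

## The synthetic cohort generator

No external data are required: the generator emits a complete study —
region catalog, transcript annotation, segmented copy-number profiles,
metadata, counts, gene sets — together with its ground truth, which the
pipeline never reads.

Default parameters describe a colon-adenocarcinoma-like cohort: 433 tumours
(223 CIN, 60 MSI, the rest genome-stable) and 41 normal samples; recurrent
gains on 20p/q, 13, 7p/q and 8q; recurrent losses on 18p/q, 8p, 17p, 14,
15, 4p/q, 21, 22 and 1p; isochromosome patterns i(8q) (24.2%), i(20q)
(13.4%), i(17q) (8.7%), i(1q) (6.7%) and i(5p) (4.6%). Whole-chromosome
gain events (defaults: chr20 25%, chr7 22%, chr8 12%) model single
mis-segregation events that gain both arms at once — without them a
whole-chromosome-gain group would almost never arise when one arm is
individually loss-prone (8p, say). MSI samples scale all event
probabilities by 0.2, reproducing their near-normal karyotypes.

Counts are negative-binomial with mean

```
mu = baseline * tumourEffect * (CN/2)^s * libraryFactor
```

where `baseline` is log-normal (meanlog `log(100)`, sdlog 1), the tumour
effect is a 2-fold up/down regulation for 15% + 15% of transcripts, the
library factor is log-normal (sdlog 0.2), and the dispersion is 0.1 —
values typical of bulk RNA-seq cohorts. The dosage sensitivity `s` depends
on the transcript's regulation class: 0.8 for up-regulated, 0.3 for
down-regulated, 0.55 for unregulated transcripts. The `(CN/2)^s` form is
the simplest model that is multiplicative in copy number and allows
class-specific sensitivity; `s = 0.55` makes a trisomy produce a 1.25-fold
bulk increase, the middle of the 1.2–1.3 band expected of bulk genes, while
the up/down asymmetry is what generates the positive caricature effect
(up-regulated transcripts disproportionately crossing the OverT threshold)
as an emergent property of the pipeline rather than a hard-coded label.
Gain events draw CN 3 vs 4 at 75%/25%; losses render CN 1. Each event is
drawn per region (isochromosomes and whole-chromosome gains claim both arms
first) and rendered as a segment covering a uniform 55–100% of the region,
anchored at a random end, so the >50% caller must genuinely recover it;
uncovered stretches are emitted at CN 2.

Per region the generator simulates 150 transcripts by default — enough for
stable density statistics while keeping a full 42-region cohort around 6300
transcripts. Transcript positions are uniform within the region, lengths
log-normal (median 1.5 kb), biotypes drawn as 55% protein-coding, 20%
lincRNA, 25% other non-coding.

Synthetic gene sets (fitness / enhancer-target / focal-amplification
stand-ins) sample 5% of the transcriptome with weight
`geneset_enrichment_factor` (default 3) on dosage-sensitive up-regulated
transcripts, so downstream enrichment has a known truth.

**What the generator does not emulate:** subclonal or allele-specific copy
number, focal events, correlated gene programmes (regulation classes are
assigned independently of position except through CNA events), GC or
length biases in counting, batch effects, and tumour purity. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean dosage model, not robustness to every artefact of real cohorts.

## Design choices where the method is genuinely open

- **Region layout.** The 42-region composition is not uniquely determined
  by its count; the default takes p/q arms of the non-acrocentric
  autosomes, whole acrocentrics, Xp/Xq and Y, and the layout is fully
  configurable via a region table.
- **Mixed arms.** An arm with, say, 40% gained and 40% lost bases passes
  neither threshold and stays neutral; gained and lost fractions are
  computed independently and can never both exceed 0.5.
- **Ploidy.** Calls compare against a fixed cohort ploidy of 2; no
  per-tumour ploidy re-centering is attempted.
- **Profile similarity.** Both the gain and the loss entries of the target
  chromosome are excluded before correlating (the gain side is 0%/100% by
  construction; the loss side is similarly constrained for isochromosome
  groups).
- **Controls.** Any non-neutral call on the target chromosome excludes a
  sample from the control group, including isochromosome patterns.
- **OverT significance.** The FDR condition for OverT refers to the FC2
  contrast itself — significance should come from the comparison the
  fold-change comes from. A `vt_scope = "fc1"` switch instead fixes the VT
  universe by the cohort-level contrast and reuses it, since either reading
  of the taxonomy is defensible.
- **Group-level PositiveT/NegativeT** require significance in both FC3 and
  FC4, mirroring the per-contrast definitions that each carry an FDR
  condition.
- **Enrichment universe.** Each per-region test uses the transcripts that
  entered differential-expression testing (post filter), since transcripts
  never tested can be neither VT nor OverT; passing the full annotation
  instead gives the all-transcripts universe.
- **TPM binning.** The per-transcript summary is the mean TPM over the
  selected group's samples; bins are half-open `[lo, hi)` with the last bin
  closed, and edges are user-supplied (no canonical edges exist).
- **NCDI degeneracies.** Regions with no transcripts are dropped (reducing
  `T`) so profiles always sum to 100. Note that NCDI is density-weighted:
  merging two regions does *not* average their NCDI values, and no such
  consistency is asserted.

## Numerical notes and problem sizes

Coordinates are 0-based half-open throughout. All stochastic stages derive
their streams from the single config seed with fixed per-stage offsets, so
each stage is reproducible both standalone and inside the pipeline, and
identical configs give byte-identical outputs. The test and acceptance
suites run on deliberately compact problems chosen for statistical
resolution per unit time: null calibration on 2000 transcripts at 15 vs 15;
dosage recovery and caricature checks on 6-region toy genomes with 80–100
transcripts per region and cohorts of 60–100 tumours; hypergeometric oracle
checks by exhaustive subset enumeration up to a universe of 12; arm-caller
oracle checks against per-base brute force on 100 random toy profiles.

## Known limitations

- The exact test covers two-group comparisons only; no GLM designs,
  covariates or batch correction.
- Arm calls assume integer copy numbers against diploid ploidy; highly
  polyploid tumours would need upstream re-centering.
- The enrichment grid reports raw hypergeometric p-values per cell, with no
  correction across cells, matching how such tables are conventionally
  reported; treat borderline cells accordingly.
- CIN/MSI labels are consumed as given metadata; the package does not
  re-derive instability status from molecular data.
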