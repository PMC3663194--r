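---
title: "Hemolysis QC for cell-free microRNA measurements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemolysis QC for cell-free microRNA measurements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoqc)
```

## The problem

Red blood cells are loaded with microRNAs, several of which (miR-16,
miR-451, miR-92a, ...) have also been proposed as plasma or serum disease
biomarkers. Even low-level hemolysis during blood collection — often
invisible to the eye — releases that cargo into plasma and can raise a
candidate biomarker's apparent level several-fold. `hemoqc` packages the
standard desk-side workflow for quantifying this confounder: score
hemolysis spectrophotometrically, compare matched hemolyzed and
non-hemolyzed plasma by un-normalized relative quantification, tier
microRNAs by susceptibility, and validate candidates against a graded RBC
spike-in series.

## Hemolysis scoring from absorbance spectra

Free hemoglobin's Soret band peaks near 414 nm, so the optical density at
414 nm (A414) is the quantitative hemolysis readout. Design choices:

* **Strict threshold.** A sample is `hemolyzed` iff A414 > 0.2 OD; a
  reading of exactly 0.2 is non-hemolyzed. Typical clean plasma reads
  0.12–0.18 OD, so the boundary is rarely touched, but the strict rule is
  stated so the call is reproducible at the boundary.
* **Linear interpolation.** Instruments scan on different grids (1 nm,
  2 nm). `absorbance_at()` interpolates linearly between bracketing points;
  nearest-neighbor extraction was rejected because different grids would
  disagree about the same underlying spectrum.
* **Relative degree.** The degree of hemolysis is the ratio of a sample's
  A414 to its matched reference. When replicate readings exist, two
  collapsing conventions are provided (`hemolysis_degree()`): ratio of
  replicate means (default) and mean of per-replicate ratios. For realistic
  replicate scatter they differ within printed rounding, and published
  tables rarely state which was used, so neither is asserted as canonical.
* **Q-bands.** Oxyhemoglobin's secondary peaks at 541 and 576 nm appear
  only at high hemoglobin levels. `detect_q_bands()` requires, in each
  window (±5 nm), a grid-point local maximum at least 0.02 OD above the
  window's linear baseline. The 0.02 OD prominence is small enough to fire
  on visibly banded spectra and large enough to ignore interpolation
  noise; requiring *both* windows rejects isolated bumps.
* **Corrupt input.** Optical densities below −0.05 are rejected rather
  than clamped: a small negative baseline is instrument offset, a large
  one is a data error that silent clamping would hide.

## Cq handling and detectability

Cq tables carry an explicit undetected state (serialized as
`"Undetermined"`); numeric Cqs must lie in (0, 40].

* **Replicate collapsing** averages duplicates on the Cq scale ("average
  of duplicates"). When duplicates disagree about detection, the default
  is conservative: the pair collapses to undetected, because a dropout at
  moderate Cq usually signals stochastic amplification near the limit and
  trusting the surviving replicate inflates low-abundance calls. The
  `detected_only` policy is available for platforms where dropouts are
  known to be technical.
* **Detection** is strict Cq < 35. The strictness reconciles the two
  common phrasings of the rule ("detected with Cq < 35" and "Cq > 35
  excluded") at the boundary value 35.
* **Detectability filter**: a microRNA enters the comparison when detected
  in at least 4 of the plasma samples under study (configurable), and
  assays with no detection anywhere are dropped globally. The filter is
  idempotent, and detection counts are monotone in the Cq cutoff.

## Relative quantification

For a matched pair, `FC = 2^-(Cq_H - Cq_NH)` — no endogenous-control
normalization, because the analysis exists precisely to find out which
species are stable enough to serve as controls. One-sided detections are
reported as statuses (`hemolyzed_only`, `nonhemolyzed_only`), never as
pseudo-count fold changes: a species absent from non-hemolyzed plasma is
evidence of RBC origin, not a number. Independent runs (separate RNA
isolations) are summarized as arithmetic mean ± SD of per-run fold
changes, matching the way validation tables are usually presented; a
geometric alternative is exposed. In the rare case where the two runs make
*conflicting* one-sided detections, the combined status falls back to
`both_undetected` — there is no usable fold change and no consistent
one-sided story.

For heatmap export, log2 fold changes are clipped at ±3.3 (≈ ±10-fold),
the conventional dynamic range for such figures.

The miR-451/miR-23a indicator (`hemolysis_ratio()`) is provided for the
situation where only RNA, not plasma, is available: the Cq difference
between a hemolysis-stable and an RBC-enriched species grows with
contamination. No verdict threshold is applied — the pairing is
community practice rather than a validated constant, and the default assay
identifiers are configuration.

## Susceptibility tiers

Per microRNA, the number of pairs with mean fold change ≥ 2 determines the
tier (all pairs / two / one); "elevated" is inclusive (≥ 2.0) to reconcile
">2-fold" with "at least twofold" phrasings. `stable` requires every
evaluable fold change inside the symmetric multiplicative band
[2/3, 1.5]. Species decreased more than the band, or varying outside it
without reaching 2-fold, are `indeterminate` — the tiering makes no claim
about decreases, which in practice are a small minority. The
`elevated_all_pairs` tier requires a design of ≥ 3 pairs; in a single-pair
study an elevated microRNA is simply `elevated_one_pair`.

`hemolysis_specific` species — detected in RBC lysate and hemolyzed plasma
but never in non-hemolyzed plasma — are identified on the *unfiltered*
assay set: by construction they cannot pass a plasma detectability filter.

Subset selection (`select_subsets()`) restricts to pairs with extensive
hemolysis (A414 degree ≥ 2, a cutoff that in typical cohorts separates
visibly hemolyzed collections from borderline ones) and demands, for the
"changing" subset, elevation in *every* such pair plus concordant ordering
of fold change with hemolysis degree. The ordering clause operationalizes
the qualitative idea that a genuinely RBC-driven increase should track the
degree of contamination; it is deliberately strict, and species whose fold
changes are large but discordantly ordered join neither subset. The
"unaffected" subset (endogenous-control candidates) uses the same ±1.5
band as the stable tier. The two subsets are disjoint by construction.

## Dilution-series analysis

Trajectories are computed on per-point mean Cqs (independent series are
averaged per point, which shrinks point scatter by ≈ 1/√2 for two series).
A microRNA is `affected` only when **both** hold:

* Cq range (max − min over points) ≥ 1.1 cycles. The bound comes from the
  observed behavior of stable species, which stay within 1.1 cycles across
  the whole series, while validated susceptible species move 1.5–2.4
  cycles — leaving a margin between the classes.
* Spearman rank correlation of Cq vs %RBC ≤ −0.8 (Cq falls, abundance
  rises). Spearman rather than Pearson or a regression on log-fraction:
  the series includes the 0% baseline (log undefined) and only an ordinal
  trend is claimed. Midranks handle ties; a constant trajectory scores 0.

Requiring both conditions matters in practice: a species can trend down
convincingly yet move only ~1 cycle (too little to matter), and a noisy
species can span a wide range with no trend. `net_shift` (Cq at 0% minus
Cq at the top fraction) is reported alongside the range; they can differ
because the range uses extremes and the shift uses endpoints. At least 4
detected points are required, otherwise the status is
`insufficient_data`.

On a noise-free synthetic series the affected boundary has closed form:
`k* = (2^1.1 − 1)/f_max`, about 915 at the default top fraction of
0.125 %RBC.

## The synthetic-data generator

The generator exists so every stage of the pipeline can be validated
against planted truth at desk scale. Its mixing model treats each
microRNA's measured quantity as clean-plasma abundance plus a
contribution proportional to the lysed-RBC volume fraction `f`:

```
Cq(f) = baseline_cq − log2(1 + f·k) + N(0, noise_sd)
```

with censoring to the undetected state beyond Cq 40. `k` is the RBC
enrichment factor: the RBC-derived linear abundance contributed per unit
lysed volume fraction, relative to the plasma baseline. This
linear-abundance mixing is the minimal model consistent with a volumetric
spike-in design and 2^−ΔCq semantics; it implies the exact identity
`FC(f vs 0) = 1 + f·k`, which the tests verify to machine precision
through the full pipeline.

Interfaces express contamination as %RBC by volume (the convention of
dilution tables); conversion to the fraction happens in one internal
helper. Defaults, chosen once as realistic study conditions:

* **Baselines** uniform in 24–34 cycles, the usual range for plasma
  microRNAs measured without pre-amplification.
* **Susceptible** `k` log-uniform in [800, 20000]: at the 0.125 %RBC top
  fraction this yields 1–4.7-cycle shifts, bracketing the 1.5–2.4-cycle
  shifts observed for validated susceptible species.
* **Stable** `k` uniform in [0, 80]: ≤ 0.15-cycle shift at the top
  fraction, comfortably inside the ±1.5-fold band.
* **Specific** species have nominal baseline Cq 45 (≥ the censor limit, so
  they never appear in clean plasma) and `k` log-uniform in [2^22, 2^24],
  putting their pure-lysate Cq near 21–23 — abundant in RBCs, detectable
  in hemolyzed plasma, absent otherwise.
* **Noise** is Gaussian on the Cq scale, sd 0.25 cycles per replicate (a
  typical qPCR technical error); heavier-tailed dropout is represented
  solely by censoring. Each of the 2 independent runs is measured in
  duplicate and duplicates are collapsed by Cq mean, mirroring the
  duplicate-reaction design of real studies.
* **Pair contamination** defaults to {0.05, 0.125, 0.25} %RBC — mild to
  heavy hemolysis, A414 degree ratios ≈ 2.4–7.8 under the spectrum
  calibration below.
* **Label proportions** default to 0.45/0.45/0.10
  (susceptible/stable/specific): a balanced test-bed with a specific
  minority, not an estimate of any real plasma composition.

Synthetic absorbance spectra are a gently sloping plasma background plus a
Soret Gaussian (center 414 nm, σ 15 nm) and two Q-band Gaussians (541/576
nm, amplitude 10% of the Soret peak). The Soret amplitude is scaled so
that A414 reproduces the calibration line
`A414(f) = 0.143 + 3.864·f_pct` exactly — the line through a clean-plasma
reading of 0.143 OD and 0.626 OD at 0.125 %RBC. Under this calibration the
0.008 %RBC point classifies non-hemolyzed and every point from 0.016 %RBC
up classifies hemolyzed, matching the measured series' pattern.

Seeds are mandatory arguments and drive all randomness; there is no hidden
global state. Scenario configurations round-trip through flat YAML.

## Problem sizes and validation strategy

The package validates itself at these scales, chosen as the smallest sizes
at which every behavior of interest is exercised:

* the default synthetic paired study: 200 microRNAs × 3 pairs × 2 runs ×
  2 duplicates (plus the RBC sample). At noise 0.25 the pipeline recovers
  ≥ 95% of planted susceptible and stable labels and 100% of specific
  species; at noise 0 recovery is exact. The residual stable-label misses
  are real borderline cases — stable species near k = 80 sit close to the
  1.5-fold band edge at the heaviest contamination.
* tier-structure properties: 1000 random 20 × 3 fold-change tables
  checked for tier nesting and partition, with periodic brute-force
  re-classification.
* printed measurement tables (six matched pairs' A414 values, the
  six-point dilution A414 series, and four stable microRNAs' Cq
  trajectories) shipped under `inst/extdata/` as fixed numeric anchors.

What the synthetic generator does **not** emulate — and what passing its
tests therefore cannot show: compartmentalization of microRNAs into
exosomes or protein complexes (which could make RBC contributions
non-additive), platelet contamination, anemia effects, inter-subject
baseline variation, amplification-efficiency differences between assays,
and any disease signal. The generator validates the *computations*, not
the biology; conclusions about real samples rest on the measured inputs.

## Known limitations

* The subset-selection ordering clause is stricter than qualitative
  published usage; real cohorts contain strongly elevated species whose
  fold changes are discordant with hemolysis degree (run-to-run scatter at
  high fold changes is large), and those are deliberately excluded here.
* Tiering judges elevation on across-run mean fold changes, not per-run
  votes; with two runs a single outlier run can move a borderline species
  across the 2-fold line.
* The miR-451/miR-23a indicator has no packaged verdict threshold.
* No absolute quantification, standard curves, or efficiency modeling:
  all conclusions are relative, within-pair or within-series.
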