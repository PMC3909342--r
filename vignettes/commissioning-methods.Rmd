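---
title: "Methods: commissioning MRI-only dose calculation against CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: commissioning MRI-only dose calculation against CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mridose)
library(dplyr)
```

## The commissioning question

An MRI-only radiotherapy workflow replaces the planning CT with surrogate
electron-density information — here, bulk density overrides. Whether that is
clinically acceptable is a *cohort* question: given a set of patients with
both CT and density-corrected MRI dose calculations, how large are the
per-patient deviations in clinically relevant DVH points, and does an agreed
fraction of patients stay within an agreed tolerance? `mridose` implements
each stage of that analysis: density override construction, DVH-point
extraction, cohort statistics, and the acceptance criterion.

## Density overrides and the HU calibration

Three override geometries are supported, mirroring common practice:

* `unit` — the entire body water-equivalent (HU 0);
* `bulk` — body at HU 0 plus segmented bone at a bone-specific HU;
* `bulk_cavity` — additionally, segmented air cavities at −1000 HU (the
  Hounsfield-scale definition of air; the value is configurable).

Bowel gas pockets are deliberately never auto-segmented: their amount and
location vary between fractions, so only explicitly supplied cavity masks
are honoured.

Bone electron density is age-dependent for the femur: the bundled table
anchors it at 1.33 g/cm³ (30 years) and 1.22 g/cm³ (90 years) and
`interpolate_electron_density()` interpolates linearly between the anchors.
Ages up to 20 years outside the anchor interval extrapolate with a warning;
beyond that the call errors, since a straight line through two adult anchors
has no support there. The cranium is age-independent at 1.61 g/cm³.

The density→HU calibration of the original CT scanner is not available, so
`hu_for_group()` ships two modes:

* **direct lookup** (default) returns the tabulated HU for each diagnostic
  group at its mean age — cranium 971; femur 349 (66.8 y), 356 (64.7 y),
  309 (78.8 y);
* **linear** interpolates the density at an arbitrary age and maps it
  through a least-squares line fitted to the three femur (density, HU)
  pairs. Those three pairs are collinear to numerical precision
  (slope 1818.2 HU·cm³/g, residuals < 10⁻⁹ HU), so the fit reproduces them
  exactly; the cranium point is ~10 HU off that line, which is why the
  age-independent entry always uses direct lookup rather than a single
  global line.

One consequence worth stating: a line reverse-engineered from bone points
alone does not pass near (1.0 g/cm³, 0 HU) — this fit predicts about
−128 HU at water density. The fitted object therefore stores `water_hu` as
a *diagnostic* of the calibration's domain of validity (bone-range
densities), not as a constraint. The calibration must not be used to assign
soft-tissue HUs; soft tissue is handled by the body override, not the line.

## The DVH engine and its conventions

`cumulative_dvh()` builds the exact empirical cumulative curve from the
multiset of in-mask voxel doses: for every distinct dose, the fraction of
structure volume receiving at least that dose. No binning and no smoothing
— every extracted point is an order statistic of the voxel doses, which
makes the engine bit-reproducible and directly checkable against a
brute-force counting oracle (the test suite does exactly that).

The point definitions:

* **D_x%** — the smallest tabulated dose whose exceedance fraction is
  ≤ x/100; equivalently the minimum dose within the hottest x% of the
  structure (a lower-boundary empirical quantile). When x spans less than
  one voxel, the hottest voxel itself is returned.
* **D_median ≡ D_50%** under the same rule. On even counts with ties this
  picks the dose at the boundary of the hottest half — e.g. for voxel doses
  1..10 Gy, D_median = 6 Gy. We chose to derive the median strictly from the
  D_x% rule rather than averaging central order statistics, so that
  D_median, D_50% and the oracle all agree identically.
* **D_x cm³** — converted to D_x% via the structure volume (voxel volume =
  spacing product, mm³ → cm³ with factor 10⁻³); requesting more volume than
  the structure has is an error.
* **V_x Gy** — percentage of structure volume receiving ≥ x Gy.
* **D_mean / D_max** — arithmetic mean / maximum of in-mask doses.

Commercial planning systems typically interpolate their DVH tables; an
optional `interpolate = TRUE` mode evaluates D_x% by linear interpolation of
the cumulative curve for comparison. The exact voxel-counting rule remains
the default because its output is exactly testable. Masks are binary;
partial-volume weighting at structure boundaries is out of scope because
each vendor applies its own (undocumented) rule.

## Cohort statistics

The comparison quantity is the per-patient percentage difference with
respect to CT, Δ = 100·(D_MRI − D_CT)/D_CT. Per diagnostic group ×
structure × DVH point × modality, `summarize_diffs()` reports the sample
mean, SD (n−1 denominator) and the **conservative interval** mean ± 2·SD.
Two caveats are intentional and documented rather than "fixed":

* mean ± 2·SD is an approximate *population* interval — the range expected
  to contain ~95% of individual patients' deviations — not a confidence
  interval of the mean. Commissioning asks about individual patients, which
  is why this construction is the acceptance surface. A t-based 95% CI of
  the mean is emitted alongside for comparison (`ci_mean_low/high`).
* Group SDs are taken from each diagnostic group individually, never pooled
  across groups.

`one_way_anova()` computes the classical between/within sum-of-squares
decomposition directly (and is verified against `stats::aov` to 10⁻⁸).
The F test is inherently one-tailed; the significance level is α = 0.05.
When the ANOVA is significant, `tukey_hsd()` runs all pairwise comparisons
via the studentized-range distribution, with the Tukey–Kramer standard
error for unequal group sizes (verified against `stats::TukeyHSD`). Two
degenerate cases are flagged rather than silently propagated: zero
within-group variance with unequal means (F = ∞, p = 0,
`zero_within_variance`) and fully identical data (F undefined,
`all_identical`).

The ANOVA treats CT and the MRI variants as independent groups although the
same patients underlie all of them. This replicates standard commissioning
practice and is conservative for detecting modality shifts; a
`paired = TRUE` flag in `analyze_cohort()` instead centres values within
patient first. Assumptions are checked by per-group Shapiro–Wilk and a
median-centred Levene (Brown–Forsythe) test — the latter implemented as the
package's own ANOVA applied to absolute deviations from group medians, and
cross-checked against `car::leveneTest`. No multiplicity correction is
applied across DVH points or structures beyond Tukey's own family-wise
control; that matches how such commissioning tables are conventionally
reported, and the decision matrix makes every comparison visible rather
than filtering.

`power_mean_difference()` gives the exact two-sided power of one-sample,
paired, or two-sample t designs via the noncentral t distribution. It
includes the (tiny) wrong-direction rejection term, so power at zero effect
equals α exactly. At the worked-example parameters (baseline 1.94 Gy, SD
0.03 Gy, 2% detectable difference, n = 21, one-sample) the computed power
is 0.9999 — essentially saturated. A commonly quoted figure of 96% for
these inputs is not reproducible under any of the three supported designs;
the function asserts no particular design and simply reports the exact
value for the design requested.

Prescription-dose stratification (used e.g. for rectum in prostate
cohorts) is handled by a `stratify_by` column option that splits structures
before analysis, dropping (with a warning) strata with fewer than two
patients, rather than by a separate two-way model.

## The reliability criterion

The acceptance rule "approximately 95% of patients within tolerance"
is operationalised as: the conservative interval mean ± 2·SD must lie
entirely within [−tolerance, +tolerance], **boundaries inclusive**, with a
default tolerance of 2%. Inclusivity matters: a cell whose interval edge
lands exactly on the boundary (e.g. 0.2 ± 1.8 → [−1.6, 2.0]) passes. The
signed `margin` (tolerance minus the worse edge's distance from zero) is
always reported so near-boundary cells are visible; when the inputs are
one-decimal rounded summaries, decisions inherit that rounding and should
be read with the margin in hand.

The criterion statement (95% coverage) and its interval operationalisation
are not formally equivalent when the mean is off-centre — mean ± 2·SD covers
~95.4% of a Normal population when centred and the rule is stricter than
literal 95% coverage for shifted means. The implemented rule is the
interval containment above; both formulations are stated here deliberately.

The tolerance itself descends from a quadrature budget:
`quadrature_combine()` aggregates independent percentage uncertainties as a
root sum of squares (1% CT ⊕ 2% MRI = 2.236…%, reported to one decimal as
2.2%), and `required_mri_uncertainty()` inverts the rule to give the
largest MRI-specific uncertainty a total budget admits. The budget type
accepts arbitrary labelled components; no default component table is
shipped beyond the 1%/2% worked example, because full clinical budgets are
institution-specific.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws Δ ~ Normal(μ, σ) independently per patient ×
structure × DVH point × modality, with (μ, σ) defaulting to the bundled
reference summaries (σ = half-width/2, since the published ± values are two
standard deviations; the table caption itself does not restate this, so the
derivation is flagged here). CT values sit at fixed per-point baselines
(configurable, optionally jittered); MRI values are CT·(1 + Δ/100).
Group sizes default to the reference cohort: 18 head-and-neck, 21 prostate,
10 vesica, 8 pelvic, with rectum strata of 12 and 9 prostate patients.

Two optional departures from the Normal-independent model are provided,
both off by default because the reference data specify no correlation or
tail structure: a shared per-patient component (`patient_sd`) inducing
within-patient correlation across DVH points, and a contamination mixture
(`contam_prob`, `contam_scale`) emulating heavy-tailed outliers such as
bowel-gas dose artefacts.

`simulate_dose_pair()` builds a voxel-level toy phantom: spherical body,
central PTV at prescription dose with exponential radial falloff, a bone
shell, an air cavity and an offset OAR, and an MRI dose equal to CT scaled
by a per-patient factor plus an optional smooth spatial field. It exists to
exercise the raster → DVH → statistics pipeline end to end (e.g. a uniform
+2% perturbation must propagate to exactly +2.0% in every D-type point, by
scale equivariance); it does not emulate beams, arcs, MLC sequences,
scanner images, registration error or geometric distortion. Consequently,
passing tests demonstrate the *statistical machinery* is correct under the
stated model, not that any particular clinic's MRI-only workflow meets the
criterion — that requires the clinic's own paired dose data.

## Numerical choices and problem sizes

* Exact quantiles on the dose multiset; ties are well-defined (doses are
  compared as doubles, no binning).
* Criterion boundaries inclusive; interval arithmetic on unrounded values
  by default.
* Degenerate inputs are flagged, not guessed: empty masks, zero CT values,
  n < 2 cells, constant groups.
* Reproducibility: every stochastic function takes a seed; the acceptance
  script derives all its seeds from one `--seed`.
* Test problem sizes were chosen so the full suite completes in about a
  minute while still giving sharp statistical checks: DVH/oracle agreement
  on ~1000 random grids of up to ~2000 voxels; ANOVA/Tukey against
  reference implementations on 100 random datasets; parameter recovery on
  500 simulated cohorts (≥ 99% of recovered means within 3·SD/√n of the
  generating values); null calibration of the ANOVA on 2000 simulated
  cohorts against a ±3·SE Monte-Carlo band.

## Known limitations

* No DICOM RT Dose / RT Structure Set parsing; rasters are NIfTI, masks
  pre-rasterised and binary.
* No biological dose conversion (EQD2, gEUD), no NTCP/TCP weighting of the
  criterion, no spatial localisation of dose differences — the DVH-point
  comparison is deliberately a similarity summary without spatial
  information.
* The linear HU calibration is valid only over the bone density range it
  was fitted on.
* The independence assumption across modalities in the ANOVA is a
  replication of field practice, not a modelling endorsement; use
  `paired = TRUE` for the conservative alternative.
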