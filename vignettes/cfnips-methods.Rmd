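---
title: "Bin-based NIPS calling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based NIPS calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cfnips` calls fetal chromosome aneuploidies from shallow shotgun
sequencing of cell-free DNA in maternal plasma. This vignette explains the
statistical model the pipeline rests on, what each tunable parameter does
and why its default is what it is, what the bundled simulator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made.

## The mixture model

Circulating cfDNA is a mixture: a fraction `1 − f` of fragments is
maternal and a fraction `f` (the fetal fraction, typically 4–25%) is
placental. For a bin `b` with maternal copy number `m_b` and fetal copy
number `c_b`, the expected relative coverage is proportional to

```
copy_mix(b) = ((1 − f) · m_b + f · c_b) / 2.
```

A fetal trisomy (`c_b = 3` on one chromosome) therefore raises that
chromosome's coverage by a factor `1 + f/2`; a fetus mosaic for the trisomy
in a fraction `m` of its cells raises it by `1 + f·m/2`; a twin gestation
contributes two fetal terms `f1 c1 + f2 c2`. At `f = 0.10` a trisomy is a
5% excess — the entire pipeline exists to make the background quiet enough
that a 5% excess is tens of robust standard deviations.

Everything is computed on a fixed genome tiling of 50 kb bins (0-based
half-open coordinates) with a per-bin GC fraction and a usability mask.
Counts are assumed to be deduplicated unique-mapping read counts per bin;
alignment is out of scope.

## Normalization stages

The normalization is a fixed four-stage sequence. Stage tags
(`SCALED → GC_CORRECTED → DENOISED → SMOOTHED`) only advance, so applying
the pipeline to already-normalized data is an exact no-op, which makes the
full normalization idempotent at fixed models.

**Scaling.** Each sample's bin counts are divided by its autosomal total,
removing sequencing depth. All downstream statistics are depth-invariant.

**GC correction.** GC bias varies between samples (library chemistry and
cluster-calling drift), so a single cohort-level curve cannot remove it:
a shared curve shifts every sample, the plate median and the training MAD
identically, and the Z-scores do not move. Each sample is therefore
corrected against its own loess fit of scaled bin value on GC fraction
(span 0.3, degree 2, over usable autosomal bins):
`corrected = value × mean(curve) / curve(gc)`. The training-median curve
fitted by `fit_gc_model()` serves as the reference expectation and as the
degenerate-GC guard. GC-rich chromosomes benefit most: with per-sample bias
present, the training MAD of a GC-shifted chromosome is inflated several
fold, and trisomies on it only separate after correction. After correction
each row is renormalized to its pre-correction autosomal total so
representations remain proportions. Evaluation outside the fitted GC range
uses the nearest endpoint.

**PCA denoising.** High-order artifacts that recur across samples (batch
and flow-cell structure) are removed by projecting each sample onto the
residual space of the top `k = 5` principal components fitted on
presumed-euploid training samples. The components are fitted only on usable
autosomal bins *excluding chromosomes 13, 18 and 21*, so a trisomy cannot
leak into the subspace and be subtracted from itself; bins outside the
model (including X and Y) pass through untouched. `k = 0` disables the
stage; `k` must stay below the training size.

**Smoothing.** Bin-level winsorization followed by a 5-bin centred rolling
median. The winsor limits are the training 1st/99th percentiles of the
ratio of a bin's value to its *local* (5-bin rolling median) level.
Expressing limits locally matters twice over: a whole-chromosome trisomy is
uniformly elevated and must not be clamped, and a genuine multi-bin
segmental event (a maternal duplication) must survive so the ideogram can
show it — both hold because their local level is elevated along with the
bins, while an isolated artifact spike towers over its neighbourhood and is
clamped. Chromosomes with fewer than 5 usable bins pass through.

One honest caveat, measured on simulated cohorts: a rolling median halves
the *per-bin* across-sample spread, but slightly inflates (~15%) the
across-sample spread of whole-chromosome sums on clean data, because
overlapping median windows positively correlate neighbouring bins. No
bin-level transform can reduce the irreducible counting noise of a sum.
The smoother's value is robustness — with sporadic artifact bins present,
chromosome-representation MAD drops — and Z calibration is unaffected
because the training σ is fitted on smoothed data too. The test suite
asserts exactly this.

## The calling statistic

Chromosome `i`'s representation is its share of the autosomal signal,
`chrRep_i = chrTotalRC_i / Σ_{j=1..22} chrTotalRC_j` (X and Y use the same
autosomal denominator). The Z-score is

```
Z = (x − μ) / σ
```

with `μ` the median representation of the sample's plate (plates are the
12-sample library pools; plates smaller than 8 fall back to the training
median) and `σ` the median absolute deviation of the training cohort's
representations, scaled by 1.4826 so that Z reads in standard-deviation
units. Calls: `Z ≤ 4` negative, `Z > 8` positive, between the two review.
Both cutoffs are interpreted on the normal-consistent MAD scale and are
exposed in the configuration.

Microdeletion/duplication regions (a DiGeorge-like region on chromosome 22
and a 1p36-like terminal region ship for the toy genome; an hg19
coordinate asset is bundled under `extdata`) are scored identically with
the region's bins as the unit: negative Z means deletion. A region needs at
least 5 usable bins.

## Review screens

Before a positive is reported, two maternal-event screens run:

* **Partial duplication.** The ideogram track (bin value ÷ euploid training
  bin median; euploid expectation 1.0) is segmented by recursive binary
  splitting, accepting a split when the SSE reduction exceeds
  `10 · σ² · log n` with σ estimated robustly (the larger of the
  differenced and the global MAD — the global term guards against the
  autocorrelation smoothing introduces). A maternal one-copy gain over a
  chromosome fraction `s` elevates those bins by `(1 − f)/2 ≈ 0.45`,
  producing a short segment near ratio 1.5, while a trisomy elevates the
  whole track near `1 + f/2`. The flag fires when an elevated segment
  (mean > 1.1) covers less than 70% of bins and the rest sit in
  [0.97, 1.03]; flagged calls are reported as suspected maternal variation.
* **Global abnormality.** If 3 or more autosomes outside 13/18/21 have
  |Z| > 8 (the signature of, e.g., fibroid-shed DNA), any positive call is
  downgraded to suspected maternal.

Report precedence is fixed: read-depth QC failure (total < 9M reads;
sex-chromosome analyses additionally need 4.5M) > low fetal fraction
(< 5%, inclusive at the boundary) > maternal flags > calls. Mosaicism is
not called separately — it simply attenuates Z by the mosaic fraction.

## Fetal fraction

For male fetuses four estimators are computed and their median taken:
three X-underrepresentation forms — the mean-bin contrast
`2(1 − X̄/Ā)`, the median-bin contrast `2(1 − X_i/X_f)` against the run's
female-fetus samples, and interpolation between adult non-pregnant female
(two X copies, FF-equivalent 0) and male (one copy, FF-equivalent 1)
anchors — plus the Y inversion `(normalized Y − background) / slope`. The
Y background and slope come from regressing normalized Y counts on X-based
FF over a training pool containing female-fetus samples (which pin the
background) and male-fetus samples spanning an FF range of at least 0.05.
The median tolerates one missing method; fewer than three available values
is an error. Negative X-based FF (X over-representation) is preserved as
evidence of maternal X gains rather than clipped.

For female fetuses no Y signal exists, so fetal fraction is predicted by an
L1-regularized linear regression (glmnet, `alpha = 1`, penalty chosen by
10-fold cross-validation at `lambda.min`; fold assignment is internally
seeded so a fitted reference is reproducible) on bin counts normalized by
sample total but *not* GC-corrected, with chromosomes 13/18/21/X/Y excluded
from the features. The model trains on male-fetus samples whose consensus
FF is known. Real cfDNA carries FF-correlated autosomal coverage structure
(fragment-length effects); the simulator has no fragment model, so
`plant_female_ff_signal()` injects an explicit low-rank FF-correlated
perturbation for the regression to learn. This is a simulator construct: a
passing recovery test shows the estimator works when such structure exists,
not that the structure exists in any particular dataset. Fetal fraction
never modifies Z-scores.

## Sex-chromosome aneuploidy

Y bins are pre-filtered on adult training data: kept only if the mean adult
male count exceeds five times the mean adult female count *and* 150 reads —
this discards pseudoautosomal-like and low-mappability bins. Genetic sex is
male when the normalized Y count exceeds the female background plus three
background MADs (the published rule is an unstated absolute threshold; a
robust 3-MAD rule is this package's operationalization).

Classification happens in the (FFx, FFy) plane, with boundaries derived
from the mixture expectations rather than from a reproduced threshold
graph: a female fetus has FFy ≈ 0 and FFx of 0 / +f / −f for XX / 45,X /
47,XXX; a male fetus has FFy ≈ f and FFx of f / 0 / f for XY / 47,XXY /
47,XYY (for XYY, FFy ≈ 2f). All bands have half-width `tau = 0.02`, chosen
a factor ~3 above the simulated FFx noise; ambiguous combinations go to
review, never to a different definite karyotype. Two maternal guards are
applied first: FFx > 0.5 suppresses any fetal call as suspected maternal
45,X mosaicism, and clearly negative FFx carries a maternal 47,XXX flag.

## The simulator

`simulate_cohort()` draws negative-binomial counts around the mixture
expectations on a toy genome of 22 autosomes × 100 bins plus 100 X and 20 Y
bins of 50 kb. Defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| depth | 1.2e7 reads | shallow single-end shotgun scale |
| NB size | 5000 | chromosome-representation robust CV ≈ 0.2%, within the ≤ 0.3% calibration the Z separation assumes |
| GC | Beta(14, 21), chr13 +0.07, chr18 +0.04 | GC-rich chromosomes 13/18, so GC bias attacks exactly the chromosomes screened |
| GC-bias slope | N(0, 0.4) per sample | visible but correctable bias; the correction-rescue scenario raises the SD to 1.2 |
| fetal fraction | U(0.08, 0.15) | typical first-trimester range |
| plates | 12 samples | library pool size |
| Y background | 0.02 of a unit bin rate | female mis-mapping level; two pseudoautosomal-like and one low-mappability Y bin exercise the bin-selection rules |

Truth rows support trisomies 13/18/21, mosaic fractions, all six sex
karyotypes, twins (two fetal fractions, error above a 0.5 sum), maternal
segmental duplications, fetal segmental CNVs, global multi-chromosome
aberrations, and adult non-pregnant controls. Everything is reproducible
from a single seed; the genome itself is seeded separately so training and
test cohorts share bins.

What the simulator does **not** emulate: fragment-length distributions,
mappability structure, sequence-specific (non-GC) coverage bias,
between-plate batch effects beyond what PCA sees in training noise, and
real maternal CNV spectra. Passing tests therefore demonstrate that the
algorithms recover the signals the mixture model implies at realistic
noise, not clinical performance; clinical sensitivities and specificities
cannot be reproduced at this scale and are deliberately not claimed.

## Numerical and testing choices

* Problem sizes: training cohorts of 120 pregnancies plus 24 adult
  controls, validation cohorts of ~100–140 samples, 2,320-bin genome.
  These sizes give stable MAD references (≈ 8% relative error on σ) while
  keeping a full pipeline run under a minute.
* The bin-usability mask uses robust CV (MAD/median of depth-scaled
  counts) with a 0.3 ceiling, applied to autosomes and X only: Y-bin counts
  are bimodal across fetal sexes, so cross-sample CV is meaningless there
  and Y usability is delegated to the male/female selection rules.
  Zero-median bins are always masked.
* Loess is evaluated with `surface = "direct"` for deterministic
  prediction; GC values outside the fitted range clamp to endpoints.
* Segmentation ties break toward fewer segments (a split must strictly
  beat the penalty); minimum segment length 3 bins.
* Per-sample Z for a mosaic trisomy (25% trisomic cells at FF 0.10) is
  distributed around ≈ 5.5 with unit spread, so the detectability test
  asserts the median over six simulated samples rather than a single draw.
* QC and FF gates are inclusive at their boundaries (a sample at exactly
  9e6 reads or 5% FF passes).

## Known limitations

* Autosomal monosomies and translocations are not called (a Robertsonian
  trisomy presents as ordinary high-Z trisomy).
* The female-FF regression is only as good as the FF-correlated structure
  in its training data; with none, it degenerates to predicting the
  training mean, and low-FF female-fetus samples can evade the 5% gate.
* Distinguishing fetal 47,XXX from low-grade maternal X gains is not
  attempted; both route to review/flag.
* Redraw logic for borderline Z-scores below 4 is operational practice,
  not implemented.
* The plate median assumes plates are overwhelmingly euploid; a plate
  loaded with aberrant samples shifts μ and biases its neighbours' Z.
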