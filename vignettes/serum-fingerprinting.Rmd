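---
title: "Serum NMR fingerprinting of colorectal cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum NMR fingerprinting of colorectal cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrfp)
```

## The problem

Around a third of patients with resected early-stage colorectal cancer (eCRC)
relapse after surgery, and staging alone separates them poorly. The idea
implemented here is that a serum proton-NMR *fingerprint* — the whole binned
spectrum, not a handful of quantified metabolites — can measure how much an
early-stage patient's serum resembles that of patients with overt metastatic
disease (mCRC), and that this "metastatic-likeness" is prognostic for
relapse independently of stage.

The package implements the complete chain: a synthetic cohort generator,
spectral calibration/binning, probabilistic quotient normalization (PQN),
a PCA–canonical-analysis–kNN classifier with leave-one-out cross-validation
(LOOCV), projection of new samples, a univariate metabolite screen, and
survival analysis of the resulting high/low metabolomic risk label.

## The classifier

Let $X$ be the $n \times 156$ matrix of PQN-normalized bin integrals.

1. **PCA** (covariance, no autoscaling — bins share units): retain the
   smallest number $m$ of components whose cumulative explained variance
   reaches 99.9%. This very permissive rule is a *denoising* step, not a
   feature-selection step: it discards only directions with essentially no
   variance, which with $n \approx 140$ samples typically leaves
   $m \approx 15\text{–}40$.
2. **Canonical analysis**: the Fisher discriminant axis in score space,
   the leading eigenvector of $W^{-1}B$ with $W$ the pooled within-class
   and $B$ the between-class scatter. For two classes this is
   $a \propto W^{-1}(\mu_{\text{met}} - \mu_{\text{early}})$, normalized to
   unit pooled within-class variance and signed so metastatic means are
   positive.
3. **kNN** with $k = 9$ (odd, so no vote ties) on the one-dimensional
   canonical scores; distance ties break deterministically by training
   index.

LOOCV refits the *entire* chain — PQN reference, centering, PCA, canonical
axis — on each fold's $n-1$ samples, so the held-out sample never touches
its own fold's model. Because PQN and PCA never see labels, the
implementation computes those per-fold models once and refits only the
canonical axis and vote per label vector; this is exactly equivalent to a
full refit and makes permutation-null studies affordable. The positive
class is metastatic throughout: sensitivity is the fraction of mCRC samples
called metastatic, specificity the fraction of relapse-free eCRC samples
called early.

Risk stratification assigns "high" to every eCRC patient whose profile is
classified metastatic — the cross-validated call for non-relapsed
(training) patients, the projected call for relapsed patients, who are
never part of the training set. Using cross-validated rather than
resubstitution calls for training members is the leakage-free choice; it is
also conservative, since resubstitution specificity is systematically
higher.

## The synthetic cohort

No real data ship with the package; the generator produces cohorts with the
statistical structure the analysis assumes, at the study scale of 65
relapse-free eCRC, 29 relapsed eCRC and 75 mCRC patients.

**Concentrations.** Each of the 32 packaged serum signals is log-normal
with a marginal log-SD of `concentration_cv` (0.2). Group differences are
calibrated through the exact closed form
$\text{shift} = \sqrt{2}\,\sigma\,\Phi^{-1}((\delta+1)/2)$, which makes the
expected Cliff's delta of two equal-variance location-shifted distributions
equal to the target $\delta$; the default targets are the reference
early-vs-metastatic effect sizes (glutamine 0.330, histidine 0.280,
formate −0.212, the rest below 0.17 in magnitude; positive = lower in
metastatic serum). Because the delta of a location shift is invariant to
monotone transforms, calibrating on the log scale is exact.

**The latent disease-burden axis.** Relapsed eCRC patients draw their
concentrations from the metastatic-like distribution with probability
`relapsed_metastatic_fraction` (0.69, mirroring the observed 20/29
projection rate) and otherwise from the relapse-free one. Within every
group, part of each marker's variance is carried by a continuous latent
burden factor aligned with the group-shift direction, with marginal
variances held fixed (so the calibrated deltas are untouched). This gives
the cohort the low-dimensional "metastatic-likeness" structure that the
whole analysis presupposes: disease burden is a continuum, not a binary
switch.

**Spectra.** Each subject gets three frequency-domain spectra (sums of
Lorentzians on a uniform grid): NOESY (everything), CPMG (macromolecules
attenuated to 0.1), diffusion-edited (small molecules attenuated to 0.1).
Technical realism includes: a glucose anomeric doublet at 5.24 ppm with a
roof-effect asymmetry (so window-argmax calibration has a stable anchor), a
broad albumin-like baseline envelope under most of the spectrum, a residual
water hump near 4.7 ppm, an ethanol triplet/quartet in a random 20% of
samples (the default exclusion windows remove those regions), a global ppm
miscalibration (SD 0.01 ppm), one multiplicative dilution factor per
subject shared by its three spectra, and additive Gaussian noise.

Lipoprotein-subclass remodeling rides the same latent axis: the broad
mobile-lipid envelopes drift by 0.005 ppm and narrow by ~6% per unit of
metastatic-likeness, emulating the VLDL/LDL/HDL composition changes of
advanced disease. This is deliberate: the fingerprint is designed to carry
discriminative information *beyond* the 32 quantified window integrals
(which are area-preserving under these changes), reflecting the
super-biomarker character of whole-spectrum classification. Without it, a
32-marker panel with reference-scale marginal effect sizes spreads its
signal over too many weak independent directions for a PCA-CA-kNN chain to
collect at $n = 140$.

**Survival.** Relapse time is exponential with hazard
$h_0 e^{\beta \cdot \text{latent}}$ ($h_0 = 0.004$/month,
$\beta = \ln 3.6$ matching the reference high-vs-low risk hazard ratio);
stage III contributes to the latent score (hazard ratio ≈ 2.5), giving the
stage confounding that the multivariate model must adjust away. Other-cause
death (0.003/month) is independent; administrative censoring is at 72
months; cancer death follows relapse with hazard 0.05/month (median
post-relapse survival ≈ 14 months, matching the metastatic cohort's
reported median overall survival). Endpoints follow the standard
definitions: RFI (relapse), DFS (relapse or death), CSS (cancer death,
defined only after an observed relapse), OS (any death). Group membership
and relapse status are reconciled by rejection sampling; the unconditional
hazard model stays directly testable through `simulate_survival()`.

**Covariates** (stage, grade, nodal status, localization, adjuvant
chemotherapy) are drawn from margins conditional on metastatic-likeness
that reproduce the reference cohort tables, including the missing-data
fraction from neoadjuvantly treated rectal cancers.

## Preprocessing choices

* **Calibration**: rigid shift placing the window-argmax at 5.24 ppm,
  refined to sub-grid accuracy by a three-point parabolic vertex fit.
  Argmax-with-refinement is adequate at the fixture linewidths; fitting the
  full doublet is deliberately out of scope.
* **Binning**: trapezoidal integration of half-open 0.05-ppm bins over
  0.2–10.0 ppm (196 bins). The emulated workflow states only that water
  and ethanol regions were removed leaving 156 bins; the packaged default
  exclusions (water 4.50–5.15, ethanol 1.10–1.25 and 3.60–3.70, trims
  0.20–0.30 and 9.00–10.00) remove exactly 40 bins and live in
  configuration, not code.
* **PQN**: rows are scaled to the cohort-median total area only for
  *estimating* the reference (the element-wise median spectrum); each raw
  row is then divided by the median of its quotients against that
  reference. The per-row correction is therefore exactly scale-invariant,
  and re-applying the normalization with the stored reference returns unit
  factors (idempotence). Projection of new samples always reuses the
  training reference — no information leaks from test samples into the
  normalization. A documented limitation: when the two groups differ
  coherently in many bins, the median quotient absorbs a few percent of
  that compositional difference, slightly biasing recovered effect sizes —
  a property of PQN itself, visible here because the generator's truth is
  known.

## Univariate screen

Designated windows (fixture data; one window per metabolite, overlaps
permitted) are integrated per spectrum, divided by the PQN dilution
factors, and screened with the two-sided Wilcoxon rank-sum test
(normal approximation, tie-corrected variance, continuity correction —
appropriate at group sizes 65/75), Benjamini–Hochberg adjustment over the
32-metabolite panel at adjusted $\alpha = 0.05$, signed Cliff's delta
(positive = lower in metastatic serum), and a single-marker accuracy at the
pooled median threshold (values at the threshold go to the metastatic
side). In the pipeline the screen runs on CPMG spectra, where the broad
macromolecule signals that otherwise sit under several small-molecule
windows are attenuated tenfold — the standard practice for small-molecule
quantification.

## Survival analysis

Kaplan–Meier with Greenwood variance, log-rank tests, reverse Kaplan–Meier
median follow-up (censoring becomes the event; undefined when the curve
never crosses 0.5), and Cox proportional-hazards models with Efron tie
handling (Breslow available for cross-checks), Wald 95% intervals and
complete-case reporting. Stepwise selection is bidirectional as the
entry/stay wording implies: forward entry of the smallest Wald $p$ below
0.05, then backward elimination of anything at or above 0.05, ties broken
by candidate order, duplicates ignored.

## Problem sizes and what the tests show

The shipped checks run LOOCV at the full study scale ($65+75$ training
samples, 156 bins), the permutation null with 200 label permutations at
$n = 140$, effect-size recovery at $10^3$ subjects per group, Cox recovery
at 500 per arm, and the end-to-end demo on 20 seeds at the default cohort.
Passing them shows the chain is internally consistent and recovers the
generator's truth at these scales; it does not certify performance on real
serum spectra, whose peak overlap, baseline behaviour and between-subject
correlation structure are richer than the fixture model (notably:
J-coupling fine structure, pH-dependent chemical shifts, and lipoprotein
subband profiles are not simulated; the study-scale LOOCV accuracy of the
synthetic demo sits a few points below the reference 70% for exactly the
reasons discussed above).

## Known limitations

* The true excluded-bin windows of the source analysis are unrecoverable;
  only the 156-bin count is honoured.
* Calibration can anchor on the lipid 5.31 ppm envelope in diffusion-edited
  spectra when glucose is suppressed below it; the anchor is consistent
  within a pulse sequence, so the feature space is unaffected.
* PQN compositional bias (above) slightly attenuates positive effect sizes
  and inflates negative ones in the quantified table.
* With one canonical axis, two-dimensional "score plots" show CA1 against a
  residual principal component — a presentation choice only.
* At the default operating point (~63% LOOCV accuracy), the 29 relapse
  events give the log-rank test of the high/low risk split only moderate
  power: the split reaches conventional significance in roughly half of
  simulated cohorts, even though the enrichment (odds ratio 2–4) is almost
  always in the right direction. Reproducing a strongly significant split
  in most cohorts would require a classifier nearer the reference 70%
  accuracy than the calibrated marginal effect sizes support.
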