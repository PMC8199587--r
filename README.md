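# nmrfp

Serum NMR metabolomic fingerprinting and relapse-risk stratification for
colorectal cancer cohorts.

About a third of patients with resected early-stage colorectal cancer (eCRC)
relapse, and TNM staging separates them imperfectly. `nmrfp` implements a
whole-spectrum ("fingerprint") approach: a PCA–canonical-analysis–kNN
classifier is trained to tell relapse-free eCRC serum from metastatic (mCRC)
serum on binned 1H-NMR spectra, relapsed patients are projected through the
fitted model, and the resulting high/low *metabolomic risk* label is
evaluated as a prognostic factor for the recurrence-free interval (RFI) with
Kaplan–Meier, log-rank and Cox models.

The core classifier, for a PQN-normalized bin matrix $X$:

1. covariance PCA retaining components explaining 99.9% of variance;
2. a Fisher canonical axis $a \propto W^{-1}(\mu_{\text{met}} -
   \mu_{\text{early}})$ in score space (unit within-class variance,
   metastatic side positive);
3. k-nearest neighbours ($k = 9$) on the canonical scores.

Leave-one-out cross-validation refits the entire chain (PQN reference,
centering, PCA, canonical axis) per fold, so no information leaks from the
held-out sample. Sensitivity/specificity/accuracy are reported with the
metastatic class positive.

Because no patient-level data are deposited anywhere, the package ships a
first-class synthetic cohort generator (`cohort_spec()`, `simulate_cohort()`,
`generate_cohort()`) reproducing the study conditions: 65 relapse-free / 29
relapsed / 75 metastatic elderly patients, 32 quantifiable serum signals with
reference effect sizes (Cliff's delta: glutamine 0.330, histidine
0.280, formate −0.212, …), three pulse sequences per sample (NOESY, CPMG,
diffusion-edited), realistic artifacts (water, sporadic ethanol, protein
baseline, miscalibration, dilution, noise), and survival endpoints driven by
a latent disease-burden score (high-vs-low hazard ratio 3.6). See the
methods vignette (`vignettes/serum-fingerprinting.Rmd`) for every modelling
choice.

## Worked example

```r
library(nmrfp)

report <- run_demo(seed = 1)
report
```

```
== serum NMR fingerprint report (seed 1, config cf90e93a) ==

LOOCV discrimination (early relapse-free vs metastatic):
 pulse_seq   n  accuracy sensitivity specificity k var_threshold
     NOESY 140 0.6642857   0.6666667   0.6615385 9         0.999
      CPMG 140 0.5714286   0.5866667   0.5538462 9         0.999
 Diffusion 140 0.6714286   0.6800000   0.6615385 9         0.999

Relapsed patients projected metastatic: 19/29 (65.5%)

Relapse by metabolomic risk: OR 3.66, Fisher p 0.00653
RFI log-rank by risk: chi2 8.45, p 0.00364
Univariate screen, adjusted p < 0.05: Alanine, 3-Hydroxybutyrate, Dimethylsulfone, Glutamine, 3-Methyl-2-oxovalerate

Stepwise multivariate Cox (RFI):
        term  estimate       hr conf_low conf_high     p_value
   risk_high 1.0907704 2.976566 1.318741  6.718488 0.008636287
 local_right 1.0413708 2.833098 1.296265  6.191979 0.009041707
    grade_g3 1.0040684 2.729363 1.196433  6.226361 0.017022451
 adjuvant_no 0.8329449 2.300082 1.017529  5.199243 0.045310499
```

Reading it: the leave-one-out accuracy for separating relapse-free early
from metastatic serum per pulse sequence (~57–67%), the fraction of relapsed
patients whose fingerprint is classified metastatic (19/29), the relapse
enrichment of the high-risk group (odds ratio 3.7), the log-rank split of
the recurrence-free interval by metabolomic risk (p = 0.004), the
metabolites passing the FDR-adjusted univariate screen, and the stepwise
multivariate Cox model in which the metabolomic risk label stays prognostic
(HR ≈ 3.0) after adjustment. Numbers vary seed to seed; the acceptance test
quantifies the qualitative findings over 20 seeds.

Individual stages are ordinary functions on tibbles and compose with the
pipe: `assemble_matrix()` → `pqn_normalize()` → `fit_fingerprint()` /
`loocv_evaluate()` → `project_fingerprint()` → `stratify_risk()` →
`km_estimate()` / `cox_fit()` / `stepwise_cox()`, with `tidy()`, `glance()`
and `autoplot()` methods on the fitted objects.

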