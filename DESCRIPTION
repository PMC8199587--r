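Package: nmrfp
Title: Serum NMR Metabolomic Fingerprinting and Relapse Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for one-dimensional proton NMR serum fingerprinting of
    colorectal cancer cohorts. Provides a synthetic cohort generator
    (Lorentzian spectra for NOESY, CPMG and diffusion-edited pulse sequences,
    plus clinical and survival tables), spectral calibration and binning,
    probabilistic quotient normalization, a PCA-canonical-analysis-kNN
    classifier with leave-one-out cross-validation and projection of new
    samples, a univariate metabolite screen (Wilcoxon rank-sum,
    Benjamini-Hochberg adjustment, Cliff's delta, median-threshold
    accuracy), and Kaplan-Meier / Cox survival analysis of the resulting
    high/low metabolomic risk label, including stepwise covariate selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
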