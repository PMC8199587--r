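#' Mean shift reproducing a target Cliff's delta
#'
#' For two equal-variance normal distributions separated by the returned
#' mean difference, the expected Cliff's delta equals `delta`. Closed form:
#' `shift = sqrt(2) * sigma * qnorm((delta + 1) / 2)`.
#'
#' @param delta Target signed Cliff's delta, `|delta| < 1`.
#' @param sigma Common group standard deviation, `> 0`.
#' @return Mean difference in the units of `sigma`.
#' @examples
#' delta_to_mean_shift(0.330, 1)
#' @export
delta_to_mean_shift <- function(delta, sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  if (any(abs(delta) > 1)) stop("|delta| must not exceed 1", call. = FALSE)
  if (any(abs(delta) == 1))
    stop("|delta| = 1 is unattainable by a finite shift", call. = FALSE)
  sqrt(2) * sigma * stats::qnorm((delta + 1) / 2)
}

#' Draw metabolite concentrations for one subject
#'
#' Concentrations are log-normal. The relapse-free early-CRC group sits at
#' the baseline of the signature library; the metastatic group is shifted on
#' the log scale by `-delta_to_mean_shift(delta, sdlog)` per metabolite, so
#' a positive target delta means lower levels in metastatic serum. Relapsed
#' early-stage subjects draw from the metastatic-like distribution with
#' probability `spec$relapsed_metastatic_fraction`, otherwise from the
#' relapse-free distribution; the realized component is returned in
#' attribute `"metastatic_like"` (0/1).
#'
#' Within a group, part of each marker's biological variance is carried by a
#' continuous latent disease-burden factor aligned with the group-shift
#' direction (`burden_loading` scales its contribution, capped so no
#' marginal variance is exceeded). Marginal log-variances stay at
#' `concentration_cv^2` for every marker, so the calibrated Cliff's deltas
#' are unaffected; the factor only correlates the markers the way a common
#' metastatic-likeness axis does. The subject's draw on this factor is
#' returned in attribute `"burden"`.
#'
#' @param spec A [cohort_spec()].
#' @param group `"eCRC_free"`, `"eCRC_relapsed"` or `"mCRC"`.
#' @param signatures Signature library.
#' @param burden_loading Scale of the latent burden factor relative to the
#'   group shift (1 = one within-group SD of burden moves a marker as much
#'   as the early-to-metastatic shift, up to the variance cap).
#' @return Named concentration vector with attributes `metastatic_like`,
#'   `burden`.
#' @export
sample_concentrations <- function(spec, group = c("eCRC_free", "eCRC_relapsed",
                                                  "mCRC"),
                                  signatures = metabolite_signatures(),
                                  burden_loading = 1) {
  group <- match.arg(group)
  win <- if (missing(signatures)) signature_windows() else
    signature_windows(signatures)
  sdlog <- spec$concentration_cv
  deltas <- rep(0, nrow(win)); names(deltas) <- win$name
  deltas[names(spec$target_deltas)] <- spec$target_deltas
  shift <- vapply(deltas, function(d)
    if (d == 0) 0 else delta_to_mean_shift(d, sdlog), 0)
  metastatic_like <- switch(group,
    eCRC_free = 0L,
    mCRC = 1L,
    eCRC_relapsed = as.integer(stats::runif(1) < spec$relapsed_metastatic_fraction))
  loading <- sign(shift) * pmin(burden_loading * abs(shift), sdlog)
  resid_sd <- sqrt(sdlog^2 - loading^2)
  burden <- stats::rnorm(1)
  meanlog <- log(win$base_conc) -
    (if (metastatic_like) shift else 0) - burden * loading
  conc <- exp(stats::rnorm(nrow(win), mean = meanlog, sd = resid_sd))
  names(conc) <- win$name
  attr(conc, "metastatic_like") <- metastatic_like
  attr(conc, "burden") <- burden
  conc
}

#' Simulate survival endpoints from a latent metastatic-likeness score
#'
#' Relapse time is exponential with hazard
#' `baseline_hazard * exp(log_hr_high_risk * latent_risk)`; other-cause
#' death is an independent exponential; cancer death follows relapse with
#' its own hazard; everyone is administratively censored. Emitted endpoints:
#' recurrence-free interval (RFI, relapse), disease-free survival (DFS,
#' relapse or death, whichever first), overall survival (OS, any death) and
#' cancer-specific survival (CSS, cancer death after relapse; `NA` unless a
#' relapse was observed).
#'
#' @param latent_risk Numeric vector of latent risk scores (0 = low).
#' @param params A [survival_sim_params()].
#' @return A tibble with `<endpoint>_months` / `<endpoint>_event` columns,
#'   one row per element of `latent_risk`.
#' @export
simulate_survival <- function(latent_risk, params = survival_sim_params()) {
  n <- length(latent_risk)
  cens <- params$admin_censor_months
  relapse <- stats::rexp(n, rate = pmax(
    params$baseline_hazard * exp(params$log_hr_high_risk * latent_risk),
    1e-12))
  if (params$baseline_hazard == 0) relapse <- rep(Inf, n)
  other <- if (params$death_other_cause_hazard > 0)
    stats::rexp(n, params$death_other_cause_hazard) else rep(Inf, n)
  cancer_death <- relapse + if (params$post_relapse_death_hazard > 0)
    stats::rexp(n, params$post_relapse_death_hazard) else rep(Inf, n)

  rfi_event <- as.integer(relapse <= pmin(other, cens))
  rfi_months <- pmin(relapse, other, cens)
  death <- pmin(other, cancer_death)
  dfs_first <- pmin(relapse, other)
  dfs_event <- as.integer(dfs_first <= cens)
  dfs_months <- pmin(dfs_first, cens)
  os_event <- as.integer(death <= cens)
  os_months <- pmin(death, cens)
  css_event <- ifelse(rfi_event == 1,
                      as.integer(cancer_death <= pmin(other, cens)),
                      NA_integer_)
  css_months <- ifelse(rfi_event == 1, pmin(cancer_death, other, cens),
                       NA_real_)
  tibble::tibble(rfi_months, rfi_event, dfs_months, dfs_event,
                 css_months, css_event, os_months, os_event)
}

# Table-1/Table-3-style covariate margins, conditional on metastatic-likeness
simulate_covariates <- function(metastatic_like) {
  n <- length(metastatic_like)
  draw <- function(levels, p_hi, p_lo) {
    ifelse(metastatic_like == 1,
           levels[1 + findInterval(stats::runif(n), cumsum(p_hi))],
           levels[1 + findInterval(stats::runif(n), cumsum(p_lo))])
  }
  stage <- draw(c("I", "II", "III", NA),
                c(0.00, 0.35, 0.50, 0.15), c(0.06, 0.51, 0.39, 0.04))
  grade <- draw(c("1", "2", "3", NA),
                c(0.03, 0.74, 0.18, 0.05), c(0.09, 0.69, 0.18, 0.04))
  nodal <- draw(c("N0", "N1", "N2", NA),
                c(0.28, 0.40, 0.17, 0.15), c(0.56, 0.22, 0.18, 0.04))
  localization <- draw(c("left_rectum", "right"),
                       c(0.48, 0.52), c(0.70, 0.30))
  adjuvant_ct <- draw(c("yes", "no"), c(0.80, 0.20), c(0.59, 0.41))
  tibble::tibble(stage, grade, nodal, localization, adjuvant_ct)
}

#' Simulate a complete synthetic cohort in memory
#'
#' Draws per-subject metabolite concentrations, clinical covariates,
#' survival endpoints and three spectra (NOESY, CPMG, diffusion-edited) per
#' subject. Deterministic given `spec$seed`. Relapse status is made
#' consistent with group membership: relapsed early-stage subjects are
#' resampled until an observed relapse occurs within follow-up, relapse-free
#' subjects until none does. Stage III adds to the latent hazard score
#' (hazard ratio ~2.5), giving the cohort a stage confounder that the
#' multivariate analysis must adjust away.
#'
#' @param spec A [cohort_spec()].
#' @param signatures Signature library.
#' @param pulse_seqs Which pulse sequences to synthesize.
#' @param ppm_range,n_points Spectrum grid; the default is wider than the
#'   0.2-10.0 ppm binning range so calibration shifts never uncover it.
#' @return A list of class `synthetic_cohort`: `clinical` (one row per
#'   subject incl. ground-truth `metastatic_like`), `concentrations`
#'   (subjects x 32 tibble of true concentrations), `spectra` (list of
#'   [nmr_spectrum()]), `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            signatures = metabolite_signatures(),
                            pulse_seqs = c("NOESY", "CPMG", "Diffusion"),
                            ppm_range = c(0.1, 10.1),
                            n_points = 8500) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  groups <- rep(c("eCRC_free", "eCRC_relapsed", "mCRC"),
                c(spec$n_ecrc_free, spec$n_ecrc_relapsed, spec$n_mcrc))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  conc_rows <- vector("list", n)
  metastatic_like <- integer(n)
  burden <- numeric(n)
  for (i in seq_len(n)) {
    ci <- sample_concentrations(spec, groups[i], signatures)
    metastatic_like[i] <- attr(ci, "metastatic_like")
    burden[i] <- attr(ci, "burden")
    conc_rows[[i]] <- ci
  }
  # lipoprotein-subclass remodeling along the same latent axis: the broad
  # lipid envelopes drift by a few mHz and narrow slightly (VLDL-ward
  # composition) with disease burden
  lipid_shift <- 0.005 * (metastatic_like + burden)
  lipid_width <- exp(-0.06 * (metastatic_like + burden))
  # dilution is a property of the prepared sample: one draw per subject,
  # shared by its three spectra
  dilution <- if (spec$dilution_sd > 0)
    stats::rlnorm(n, 0, spec$dilution_sd) else rep(1, n)
  covar <- simulate_covariates(metastatic_like)
  stage_weight <- if (spec$survival$log_hr_high_risk != 0)
    log(2.5) / spec$survival$log_hr_high_risk else 0
  latent <- metastatic_like +
    stage_weight * as.integer(!is.na(covar$stage) & covar$stage == "III")

  surv <- simulate_survival(latent, spec$survival)
  # enforce group-consistent relapse status by rejection resampling
  for (i in seq_len(n)) {
    want <- switch(groups[i], eCRC_free = 0L, eCRC_relapsed = 1L, NA_integer_)
    if (is.na(want)) next
    tries <- 0
    while (surv$rfi_event[i] != want) {
      tries <- tries + 1
      if (tries > 10000)
        stop("cannot realise relapse status for subject ", ids[i],
             " under these survival parameters", call. = FALSE)
      surv[i, ] <- simulate_survival(latent[i], spec$survival)
    }
  }
  # metastatic subjects: no recurrence endpoints; survival from the
  # post-relapse (advanced disease) hazard
  is_m <- groups == "mCRC"
  if (any(is_m)) {
    nm <- sum(is_m)
    death <- pmin(
      if (spec$survival$post_relapse_death_hazard > 0)
        stats::rexp(nm, spec$survival$post_relapse_death_hazard) else rep(Inf, nm),
      if (spec$survival$death_other_cause_hazard > 0)
        stats::rexp(nm, spec$survival$death_other_cause_hazard) else rep(Inf, nm))
    cens <- spec$survival$admin_censor_months
    surv$rfi_months[is_m] <- NA_real_; surv$rfi_event[is_m] <- NA_integer_
    surv$css_months[is_m] <- NA_real_; surv$css_event[is_m] <- NA_integer_
    surv$os_months[is_m] <- pmin(death, cens)
    surv$os_event[is_m] <- as.integer(death <= cens)
    surv$dfs_months[is_m] <- surv$os_months[is_m]
    surv$dfs_event[is_m] <- surv$os_event[is_m]
  }

  spectra <- vector("list", n * length(pulse_seqs))
  si <- 0
  for (i in seq_len(n)) {
    for (ps in pulse_seqs) {
      si <- si + 1
      spectra[[si]] <- synthesize_spectrum(
        conc_rows[[i]], pulse_seq = ps, spec = spec, signatures = signatures,
        ppm_range = ppm_range, n_points = n_points,
        macro_center_shift = lipid_shift[i],
        macro_width_factor = lipid_width[i],
        dilution = dilution[i],
        sample_id = ids[i])
    }
  }
  conc <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids),
    tibble::as_tibble(do.call(rbind, conc_rows)))
  clinical <- dplyr::bind_cols(
    tibble::tibble(id = ids, group = groups,
                   metastatic_like = metastatic_like),
    covar, surv)
  structure(list(clinical = clinical, concentrations = conc,
                 spectra = spectra, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$clinical), " subjects, ",
      length(x$spectra), " spectra\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort on disk
#'
#' Writes three spectra per subject (`<id>_<pulse_seq>.tsv`) and one
#' clinical table (`clinical.csv`) to `dir`. Byte-identical re-runs for a
#' fixed `spec` (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if missing).
#' @param ... Passed to [simulate_cohort()].
#' @return Invisibly, a list with `clinical_path` and `spectra_paths`.
#' @export
generate_cohort <- function(spec = cohort_spec(), dir, ...) {
  cohort <- simulate_cohort(spec, ...)
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character(length(cohort$spectra))
  for (i in seq_along(cohort$spectra)) {
    sp <- cohort$spectra[[i]]
    paths[i] <- file.path(dir, paste0(sample_id(sp), "_", pulse_seq(sp), ".tsv"))
    write_spectrum(sp, paths[i])
  }
  clin_path <- file.path(dir, "clinical.csv")
  df <- cohort$clinical
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, sprintf("%.6g", v)))
  utils::write.csv(df, clin_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(list(clinical_path = clin_path, spectra_paths = paths))
}
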