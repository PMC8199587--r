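#' Survival-simulation parameters
#'
#' Hazard model used by the synthetic cohort: relapse time is exponential
#' with hazard `baseline_hazard * exp(log_hr_high_risk * latent_risk)`,
#' other-cause death is an independent exponential, and everyone is
#' administratively censored at `admin_censor_months`. Death after relapse
#' (the cancer-specific endpoint) uses `post_relapse_death_hazard`.
#'
#' @param baseline_hazard Relapse hazard (1/month) at latent risk 0.
#' @param log_hr_high_risk Log hazard ratio per unit latent risk; default
#'   `log(3.6)`, the magnitude of the high-versus-low metabolomic risk effect
#'   the generator is calibrated to.
#' @param admin_censor_months Administrative censoring horizon (months).
#' @param death_other_cause_hazard Other-cause death hazard (1/month).
#' @param post_relapse_death_hazard Cancer-death hazard after relapse
#'   (1/month).
#' @return A list of class `survival_sim_params`.
#' @export
survival_sim_params <- function(baseline_hazard = 0.004,
                                log_hr_high_risk = log(3.6),
                                admin_censor_months = 72,
                                death_other_cause_hazard = 0.003,
                                post_relapse_death_hazard = 0.05) {
  stopifnot(baseline_hazard >= 0, death_other_cause_hazard >= 0,
            post_relapse_death_hazard >= 0, admin_censor_months >= 0)
  structure(list(
    baseline_hazard = baseline_hazard,
    log_hr_high_risk = log_hr_high_risk,
    admin_censor_months = admin_censor_months,
    death_other_cause_hazard = death_other_cause_hazard,
    post_relapse_death_hazard = post_relapse_death_hazard
  ), class = "survival_sim_params")
}

#' Specification of a synthetic colorectal-cancer cohort
#'
#' Bundles every tunable of the generator: group sizes (relapse-free early
#' CRC, relapsed early CRC, metastatic CRC), the per-metabolite signed
#' Cliff's delta targets for the early-versus-metastatic contrast,
#' biological and technical variation, the fraction of relapsed early-stage
#' patients whose serum profile is drawn from the metastatic-like
#' distribution, and the survival model.
#'
#' Defaults reproduce the study conditions the package emulates: 65/29/75
#' patients, Table-of-32 effect sizes with glutamine 0.330 and histidine
#' 0.280, and a 0.69 metastatic-like fraction among relapsed patients.
#'
#' @param n_ecrc_free,n_ecrc_relapsed,n_mcrc Group sizes.
#' @param target_deltas Named numeric vector of signed Cliff's deltas
#'   (positive = lower in metastatic serum); defaults to
#'   [default_target_deltas()].
#' @param concentration_cv Biological log-scale SD of metabolite
#'   concentrations.
#' @param dilution_sd Log-scale SD of the per-sample multiplicative dilution
#'   factor.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param miscalibration_sd SD (ppm) of the global chemical-shift
#'   miscalibration.
#' @param relapsed_metastatic_fraction Probability that a relapsed
#'   early-stage patient draws metastatic-like concentrations.
#' @param survival A [survival_sim_params()] object.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A list of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec$n_mcrc
#' @export
cohort_spec <- function(n_ecrc_free = 65,
                        n_ecrc_relapsed = 29,
                        n_mcrc = 75,
                        target_deltas = default_target_deltas(),
                        concentration_cv = 0.2,
                        dilution_sd = 0.15,
                        noise_sd = 0.005,
                        miscalibration_sd = 0.01,
                        relapsed_metastatic_fraction = 0.69,
                        survival = survival_sim_params(),
                        seed = 1L) {
  stopifnot(n_ecrc_free >= 0, n_ecrc_relapsed >= 0, n_mcrc >= 0,
            concentration_cv > 0, dilution_sd >= 0, noise_sd >= 0,
            miscalibration_sd >= 0)
  if (relapsed_metastatic_fraction < 0 || relapsed_metastatic_fraction > 1)
    stop("`relapsed_metastatic_fraction` must lie in [0, 1]", call. = FALSE)
  if (any(abs(target_deltas) > 1))
    stop("|target delta| must not exceed 1", call. = FALSE)
  if (is.null(names(target_deltas)) || any(!nzchar(names(target_deltas))))
    stop("`target_deltas` must be a named vector", call. = FALSE)
  known <- unique(metabolite_signatures()$name)
  unknown <- setdiff(names(target_deltas), known)
  if (length(unknown))
    stop("unknown metabolite(s) in `target_deltas`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  stopifnot(inherits(survival, "survival_sim_params"))
  structure(list(
    n_ecrc_free = as.integer(n_ecrc_free),
    n_ecrc_relapsed = as.integer(n_ecrc_relapsed),
    n_mcrc = as.integer(n_mcrc),
    target_deltas = target_deltas,
    concentration_cv = concentration_cv,
    dilution_sd = dilution_sd,
    noise_sd = noise_sd,
    miscalibration_sd = miscalibration_sd,
    relapsed_metastatic_fraction = relapsed_metastatic_fraction,
    survival = survival,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_ecrc_free, " eCRC relapse-free / ",
      x$n_ecrc_relapsed, " eCRC relapsed / ", x$n_mcrc, " mCRC; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Read or write a cohort specification as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  x$target_deltas <- as.list(x$target_deltas)
  x$survival <- unclass(x$survival)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  cohort_spec(
    n_ecrc_free = x$n_ecrc_free, n_ecrc_relapsed = x$n_ecrc_relapsed,
    n_mcrc = x$n_mcrc,
    target_deltas = unlist(x$target_deltas),
    concentration_cv = x$concentration_cv, dilution_sd = x$dilution_sd,
    noise_sd = x$noise_sd, miscalibration_sd = x$miscalibration_sd,
    relapsed_metastatic_fraction = x$relapsed_metastatic_fraction,
    survival = do.call(survival_sim_params, x$survival),
    seed = x$seed
  )
}
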