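#' Kaplan-Meier product-limit estimate
#'
#' Wraps the product-limit estimator; at tied times events are handled
#' before censorings. A time-0 row with survival 1 is prepended.
#'
#' @param times Non-negative follow-up times (months).
#' @param events 0/1 event indicators.
#' @return A tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `std_err` (Greenwood).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("no observations", call. = FALSE)
  if (any(times < 0)) stop("negative time", call. = FALSE)
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- tibble::tibble(
    time = c(0, fit$time), n_risk = c(length(times), fit$n.risk),
    n_event = c(0, fit$n.event), n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv), std_err = c(0, fit$surv * fit$std.err))
  structure(out, class = c("km_curve", class(out)))
}

#' Log-rank test between survival curves
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group label per observation (>= 2 non-empty groups).
#' @return List: `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  stopifnot(length(times) == length(events), length(times) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab == 0)) stop("empty group", call. = FALSE)
  if (sum(events) == 0) stop("no events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(tab) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Kaplan-Meier with the event indicator flipped (death censors, censoring
#' is the "event"); returns the median of that curve, or `NA` when the
#' curve never reaches 0.5.
#'
#' @param times Follow-up times.
#' @param death_events 0/1 death indicators.
#' @return Median follow-up (months) or `NA_real_`.
#' @export
reverse_km_median_followup <- function(times, death_events) {
  stopifnot(length(times) == length(death_events))
  fit <- survival::survfit(survival::Surv(times, 1 - death_events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  if (is.null(med)) NA_real_ else as.numeric(med)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron handling of ties (Breslow available),
#' Wald confidence intervals, and complete-case handling of missing
#' covariates (the complete-case count is reported, mirroring standard
#' clinical tables).
#'
#' @param data Data frame of covariates and outcome columns.
#' @param time,event Column names of the outcome.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A tibble of class `cox_screen` with one row per model term:
#'   `term`, `estimate` (log HR), `hr`, `conf_low`, `conf_high`,
#'   `p_value`; attributes `n_complete`, `n_events`, `selected`, `fit`.
#' @export
cox_fit <- function(data, time, event, covariates, ties = "efron") {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  miss <- setdiff(c(time, event, covariates), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[stats::complete.cases(data[, c(time, event, covariates)]), ,
            drop = FALSE]
  if (nrow(d) < 2 || sum(d[[event]]) < 1)
    stop("not enough complete-case events to fit", call. = FALSE)
  for (cv in covariates)
    if (length(unique(d[[cv]])) < 2)
      stop("constant covariate: ", cv, call. = FALSE)
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  s <- summary(fit)
  co <- s$coefficients
  out <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = exp(co[, "coef"]),
    conf_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    conf_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"])
  structure(out, n_complete = nrow(d), n_events = sum(d[[event]]),
            selected = covariates, fit = fit,
            class = c("cox_screen", class(out)))
}

#' @export
glance.cox_screen <- function(x, ...) {
  tibble::tibble(n_complete = attr(x, "n_complete"),
                 n_events = attr(x, "n_events"),
                 n_terms = nrow(x))
}

#' Stepwise Cox covariate selection
#'
#' Bidirectional selection: forward entry of the candidate with the
#' smallest Wald p below `p_enter`, followed after each entry by backward
#' elimination of any retained covariate whose p rises to `p_stay` or
#' above. Ties are broken by candidate order; duplicate candidates are
#' ignored. The final model is refit on complete cases of the selected
#' covariates.
#'
#' @inheritParams cox_fit
#' @param candidates Character vector of candidate covariate columns.
#' @param p_enter,p_stay Entry and stay thresholds (default 0.05).
#' @return A `cox_screen` for the selected model, or an empty tibble of the
#'   same class (attribute `selected` = character(0)) when nothing enters.
#' @export
stepwise_cox <- function(data, time, event, candidates,
                         p_enter = 0.05, p_stay = 0.05, ties = "efron") {
  candidates <- unique(candidates)
  selected <- character(0)
  term_p <- function(vars, target) {
    f <- cox_fit(data, time, event, vars, ties = ties)
    # a factor covariate can expand to several terms; take its smallest p
    min(f$p_value[startsWith(f$term, target)])
  }
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    ps <- vapply(remaining, function(cand)
      tryCatch(term_p(c(selected, cand), cand), error = function(e) NA_real_),
      0)
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= p_enter) break
    selected <- c(selected, remaining[which.min(ps)])
    repeat {
      if (length(selected) < 2) break
      fit <- cox_fit(data, time, event, selected, ties = ties)
      worst <- vapply(selected, function(v)
        min(fit$p_value[startsWith(fit$term, v)]), 0)
      if (max(worst) < p_stay) break
      selected <- setdiff(selected, names(which.max(worst)))
    }
  }
  if (!length(selected)) {
    out <- tibble::tibble(term = character(), estimate = numeric(),
                          hr = numeric(), conf_low = numeric(),
                          conf_high = numeric(), p_value = numeric())
    return(structure(out, n_complete = NA_integer_, n_events = NA_integer_,
                     selected = character(0),
                     class = c("cox_screen", class(out))))
  }
  cox_fit(data, time, event, selected, ties = ties)
}

#' Kaplan-Meier plot by group
#'
#' @param data Data frame with outcome columns and a grouping column.
#' @param time,event,group Column names.
#' @return A ggplot step-curve plot.
#' @export
plot_km <- function(data, time, event, group) {
  d <- data[!is.na(data[[time]]) & !is.na(data[[event]]), ]
  curves <- dplyr::group_modify(
    dplyr::group_by(d, .data[[group]]),
    ~ tibble::as_tibble(km_estimate(.x[[time]], .x[[event]])))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data[[group]])) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability") +
    ggplot2::theme_minimal()
}
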