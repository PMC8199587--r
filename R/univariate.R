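#' Quantify metabolite signals from calibrated spectra
#'
#' Integrates each signature's designated quantification window
#' (trapezoidal rule) in every spectrum. Windows may overlap; each
#' metabolite uses one fixed window even when it has several multiplets.
#'
#' @param spectra List of calibrated [nmr_spectrum()] objects.
#' @param signatures Signature library (see [metabolite_signatures()]).
#' @param dilution_factors Optional named per-sample factors (e.g. from
#'   [pqn_normalize()]) to divide out.
#' @return Tibble: `sample_id` plus one column per metabolite (32 with the
#'   packaged library).
#' @export
quantify_metabolites <- function(spectra,
                                 signatures = metabolite_signatures(),
                                 dilution_factors = NULL) {
  win <- signature_windows(signatures)
  rows <- lapply(spectra, function(sp) {
    rng <- range(sp$ppm)
    outside <- win$quant_lo < rng[1] - 1e-9 | win$quant_hi > rng[2] + 1e-9
    if (any(outside))
      stop("quantification window outside spectral range for: ",
           paste(win$name[outside], collapse = ", "), call. = FALSE)
    stats::setNames(integrate_windows(sp, win$quant_lo, win$quant_hi),
                    win$name)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = vapply(spectra, sample_id, "")),
    tibble::as_tibble(do.call(rbind, rows)))
  if (!is.null(dilution_factors)) {
    f <- dilution_factors[out$sample_id]
    if (any(is.na(f)))
      stop("missing dilution factor for some samples", call. = FALSE)
    out[win$name] <- out[win$name] / f
  }
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Normal approximation with mid-ranks for ties, tie-corrected variance and
#' continuity correction. Degenerate input (every value identical across
#' both groups) returns p = 1.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  if (length(unique(c(x, y))) == 1) return(1)
  stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Signed Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`: positive when
#' `x` tends to exceed `y`. Computed from mid-ranks, which is exact and
#' scales to large samples.
#'
#' @param x,y Numeric samples (here: early and metastatic values, so a
#'   positive delta means lower levels in the metastatic group).
#' @return Signed delta in `[-1, 1]`.
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))  # -0.556
#' @export
cliffs_delta <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("empty group", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # #{x>y} + 0.5 #{x=y}
  2 * u / (nx * ny) - 1
}

#' Classification accuracy of a single marker at its pooled median
#'
#' The threshold is the pooled median. When the marker is higher in the
#' early group (positive delta) values below the threshold are called
#' metastatic, otherwise values above; values exactly at the threshold are
#' assigned to the metastatic side.
#'
#' @param values Numeric marker values.
#' @param labels `"early"` / `"metastatic"` per value.
#' @return Fraction correctly classified.
#' @export
median_threshold_accuracy <- function(values, labels) {
  labels <- as.character(labels)
  if (!length(values)) stop("empty input", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) != 2)
    stop("both classes must be present", call. = FALSE)
  pos <- if ("metastatic" %in% classes) "metastatic" else classes[2]
  thr <- stats::median(values)
  d <- cliffs_delta(values[labels != pos], values[labels == pos])
  pred_pos <- if (d >= 0) values <= thr else values >= thr
  mean(pred_pos == (labels == pos))
}

#' Univariate screen over all quantified metabolites
#'
#' Per metabolite: two-sided Wilcoxon rank-sum p, Benjamini-Hochberg
#' adjusted p (over the full panel), signed Cliff's delta
#' (early vs metastatic), and the pooled-median single-marker accuracy.
#' Rows are sorted by raw p; `significant` flags adjusted p < alpha.
#'
#' @param concentrations Tibble from [quantify_metabolites()] (`sample_id`
#'   plus metabolite columns).
#' @param labels `"early"` / `"metastatic"` per row.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Tibble: `metabolite`, `p_value`, `p_adjusted`, `effect_size`,
#'   `median_threshold_accuracy`, `significant`.
#' @export
univariate_table <- function(concentrations, labels, alpha = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(concentrations))
  mets <- setdiff(names(concentrations), "sample_id")
  pos <- if ("metastatic" %in% labels) "metastatic" else sort(unique(labels))[2]
  res <- purrr::map_dfr(mets, function(m) {
    v <- concentrations[[m]]
    x <- v[labels != pos]; y <- v[labels == pos]
    tibble::tibble(
      metabolite = m,
      p_value = wilcoxon_rank_sum(x, y),
      effect_size = cliffs_delta(x, y),
      median_threshold_accuracy = median_threshold_accuracy(v, labels))
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res$significant <- res$p_adjusted < alpha
  dplyr::arrange(
    dplyr::select(res, "metabolite", "p_value", "p_adjusted", "effect_size",
                  "median_threshold_accuracy", "significant"),
    .data$p_value)
}

#' Boxplots of metabolite levels by group
#'
#' @param concentrations Tibble from [quantify_metabolites()].
#' @param labels Group label per row.
#' @param metabolites Which metabolites to show (default: first 2 by name).
#' @return A ggplot object.
#' @export
plot_metabolite_boxes <- function(concentrations, labels,
                                  metabolites = NULL) {
  mets <- setdiff(names(concentrations), "sample_id")
  if (is.null(metabolites)) metabolites <- utils::head(mets, 2)
  d <- tidyr::pivot_longer(
    dplyr::mutate(concentrations[, c("sample_id", metabolites)],
                  group = as.character(labels)),
    dplyr::all_of(metabolites),
    names_to = "metabolite", values_to = "level")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$level,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
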