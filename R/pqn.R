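#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution from a binned feature matrix. When no
#' `reference` is supplied it is estimated from the data: rows are first
#' scaled to a common total area (the cohort median; toggle with
#' `total_area`) and the reference is their element-wise median. Each raw
#' row is then divided by the median of its quotients against the reference
#' (quotients taken over bins where the reference is positive), so the
#' per-row correction is fully scale-invariant. When a stored `reference`
#' is supplied (e.g. when normalizing new samples against a training
#' cohort) no reference is re-estimated and the area step is skipped:
#' applying the normalization to its own output therefore yields dilution
#' factors of exactly 1.
#'
#' @param binned A `binned_spectra` tibble (see [assemble_matrix()]), or any
#'   tibble with a `sample_id` column and numeric feature columns.
#' @param reference Optional stored reference vector (named as the bin
#'   columns).
#' @param strategy Which rows define the reference: all samples
#'   (`"median_all"`, default) or a subset given by `reference_rows`
#'   (`"median_reference_group"`).
#' @param reference_rows Logical or integer row index, used with
#'   `strategy = "median_reference_group"`.
#' @param total_area Scale rows to the median total area before estimating
#'   the reference (default TRUE). Ignored when `reference` is supplied.
#' @return A list of class `pqn_result`: `normalized` (same shape as
#'   input), `report` (list with `reference`, `factors` tibble, `strategy`).
#' @examples
#' m <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                     b1 = c(1, 2, 1), b2 = c(2, 4, 2), b3 = c(3, 6, 3))
#' pqn_normalize(m)$report$factors
#' @export
pqn_normalize <- function(binned, reference = NULL,
                          strategy = c("median_all", "median_reference_group"),
                          reference_rows = NULL, total_area = TRUE) {
  strategy <- match.arg(strategy)
  X <- bin_values(binned)
  if (is.null(reference) && nrow(X) < 3)
    stop("PQN needs at least 3 samples to estimate a reference", call. = FALSE)
  areas <- rowSums(X)
  zero <- which(areas == 0 | apply(X, 1, function(r) all(r == 0)))
  if (length(zero))
    stop("all-zero sample(s): ", paste(rownames(X)[zero], collapse = ", "),
         call. = FALSE)
  if (is.null(reference)) {
    U <- if (total_area) X * (stats::median(areas) / areas) else X
    ref_rows <- if (strategy == "median_reference_group") {
      if (is.null(reference_rows))
        stop("`reference_rows` required for strategy 'median_reference_group'",
             call. = FALSE)
      U[reference_rows, , drop = FALSE]
    } else U
    reference <- apply(ref_rows, 2, stats::median)
  } else {
    if (length(reference) != ncol(X))
      stop("stored reference length does not match the bin grid", call. = FALSE)
    if (!is.null(names(reference)) &&
        !identical(names(reference), colnames(X)))
      stop("stored reference bins do not match the matrix bins", call. = FALSE)
  }
  pos <- reference > 0
  if (!any(pos)) stop("reference has no positive bins", call. = FALSE)
  factors <- apply(X[, pos, drop = FALSE], 1,
                   function(r) stats::median(r / reference[pos]))
  if (any(factors <= 0))
    stop("non-positive dilution factor for sample(s): ",
         paste(rownames(X)[factors <= 0], collapse = ", "), call. = FALSE)
  V <- X / factors
  structure(list(
    normalized = rebuild_binned(V, binned),
    report = list(
      reference = stats::setNames(as.numeric(reference), colnames(X)),
      factors = tibble::tibble(sample_id = rownames(X),
                               dilution_factor = unname(factors)),
      strategy = strategy)
  ), class = "pqn_result")
}

#' @export
print.pqn_result <- function(x, ...) {
  f <- x$report$factors$dilution_factor
  cat("<pqn_result> ", nrow(x$normalized), " samples; dilution factors ",
      sprintf("%.3g", min(f)), "-", sprintf("%.3g", max(f)), "\n", sep = "")
  invisible(x)
}
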