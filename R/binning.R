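#' Default spectral exclusion windows
#'
#' Regions removed before pattern recognition: residual water, the ethanol
#' CH3 triplet and CH2 quartet, and upfield/downfield noise trims. With the
#' default 0.05 ppm grid these windows remove exactly 40 of 196 bins,
#' leaving the 156-bin feature space.
#'
#' @return A tibble with columns `region`, `lo`, `hi` (ppm).
#' @export
default_exclusions <- function() {
  tibble::tibble(
    region = c("water", "ethanol CH3", "ethanol CH2",
               "downfield trim", "upfield trim"),
    lo = c(4.50, 1.10, 3.60, 9.00, 0.20),
    hi = c(5.15, 1.25, 3.70, 10.00, 0.30)
  )
}

#' Define a spectral binning grid
#'
#' @param lo,hi Grid limits (ppm); defaults 0.2 and 10.0.
#' @param width Bin width (ppm); default 0.05. `(hi - lo) / width` must be
#'   integral.
#' @param exclusions Tibble of exclusion windows (`lo`, `hi`), within the
#'   grid and non-overlapping; bins overlapping any window are dropped
#'   entirely. Default [default_exclusions()].
#' @return A list of class `bin_grid` with bin edges and the retained-bin
#'   index.
#' @examples
#' g <- bin_grid()
#' g$n_bins          # 196
#' sum(g$retained)   # 156
#' @export
bin_grid <- function(lo = 0.2, hi = 10.0, width = 0.05,
                     exclusions = default_exclusions()) {
  stopifnot(hi > lo, width > 0)
  n <- (hi - lo) / width
  if (abs(n - round(n)) > 1e-8)
    stop("(hi - lo) / width must be an integer number of bins", call. = FALSE)
  n <- as.integer(round(n))
  edges <- lo + width * (0:n)
  if (nrow(exclusions)) {
    if (any(exclusions$lo >= exclusions$hi))
      stop("exclusion windows must have lo < hi", call. = FALSE)
    if (any(exclusions$lo < lo - 1e-9) || any(exclusions$hi > hi + 1e-9))
      stop("exclusion windows must lie within [lo, hi]", call. = FALSE)
    ord <- order(exclusions$lo)
    ex <- exclusions[ord, ]
    if (nrow(ex) > 1 && any(ex$lo[-1] < ex$hi[-nrow(ex)] - 1e-9))
      stop("exclusion windows must not overlap", call. = FALSE)
  }
  eps <- width * 1e-6
  excluded <- rep(FALSE, n)
  for (i in seq_len(nrow(exclusions))) {
    excluded <- excluded |
      (edges[1:n] < exclusions$hi[i] - eps &
       edges[2:(n + 1)] > exclusions$lo[i] + eps)
  }
  structure(list(lo = lo, hi = hi, width = width, exclusions = exclusions,
                 edges = edges, n_bins = n, retained = !excluded),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", x$n_bins, " bins of ", x$width, " ppm on [", x$lo, ", ",
      x$hi, "]; ", sum(x$retained), " retained after ", nrow(x$exclusions),
      " exclusion window(s)\n", sep = "")
  invisible(x)
}

# integral of the piecewise-linear spectrum over [lo_i, hi_i], vectorized
# over windows; exact trapezoid with interpolated window endpoints
integrate_windows <- function(spectrum, lo, hi) {
  x <- spectrum$ppm; y <- spectrum$intensity
  if (min(lo) < x[1] - 1e-9 || max(hi) > x[length(x)] + 1e-9)
    stop(sprintf("spectrum covers [%.4g, %.4g] ppm but integration needs [%.4g, %.4g]",
                 x[1], x[length(x)], min(lo), max(hi)), call. = FALSE)
  cumint <- c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  cum_at <- function(p) {
    k <- findInterval(p, x, rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), length(x) - 1L)
    frac <- (p - x[k])
    yk <- y[k] + (y[k + 1L] - y[k]) * frac / (x[k + 1L] - x[k])
    cumint[k] + frac * (y[k] + yk) / 2
  }
  cum_at(hi) - cum_at(lo)
}

#' Reduce a calibrated spectrum to retained-bin integrals
#'
#' Each bin's value is the trapezoidal integral of the spectrum over the
#' half-open bin `[edge_i, edge_{i+1})`; bins overlapping an exclusion
#' window are dropped.
#'
#' @param spectrum A calibrated [nmr_spectrum()] covering the grid.
#' @param grid A [bin_grid()].
#' @return Named numeric vector of length `sum(grid$retained)`; names are
#'   `ppm_<bin center>`.
#' @export
bin_spectrum <- function(spectrum, grid = bin_grid()) {
  stopifnot(inherits(spectrum, "nmr_spectrum"), inherits(grid, "bin_grid"))
  n <- grid$n_bins
  vals <- integrate_windows(spectrum, grid$edges[1:n], grid$edges[2:(n + 1)])
  centers <- (grid$edges[1:n] + grid$edges[2:(n + 1)]) / 2
  out <- vals[grid$retained]
  names(out) <- sprintf("ppm_%.3f", centers[grid$retained])
  out
}

#' Assemble calibrated, binned spectra into a feature matrix
#'
#' Calibrates every spectrum to the glucose anchor (optional), bins it on
#' the shared grid, and stacks the retained-bin vectors into a samples-by-
#' bins tibble. Rows keep the input order.
#'
#' @param spectra List of [nmr_spectrum()] objects sharing one pulse
#'   sequence, with unique sample ids.
#' @param grid A [bin_grid()].
#' @param calibrate Calibrate each spectrum before binning (default TRUE).
#' @return A tibble of class `binned_spectra`: `sample_id` plus one column
#'   per retained bin. Attributes: `bin_edges` (tibble `lo`, `hi`,
#'   `center`), `pulse_seq`, `calibration` (per-sample shift).
#' @export
assemble_matrix <- function(spectra, grid = bin_grid(), calibrate = TRUE) {
  stopifnot(length(spectra) >= 1)
  ids <- vapply(spectra, sample_id, "")
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ps <- unique(vapply(spectra, pulse_seq, ""))
  if (length(ps) != 1)
    stop("mixed pulse sequences: ", paste(ps, collapse = ", "), call. = FALSE)
  shifts <- numeric(length(spectra))
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (calibrate) {
      sp <- calibrate_to_glucose(sp)
      shifts[i] <- attr(sp, "calibration_shift")
    }
    rows[[i]] <- bin_spectrum(sp, grid)
  }
  values <- do.call(rbind, rows)
  n <- grid$n_bins
  centers <- (grid$edges[1:n] + grid$edges[2:(n + 1)]) / 2
  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = ids), out)
  structure(out,
            bin_edges = tibble::tibble(
              lo = grid$edges[1:n][grid$retained],
              hi = grid$edges[2:(n + 1)][grid$retained],
              center = centers[grid$retained]),
            pulse_seq = ps,
            calibration = tibble::tibble(sample_id = ids, shift = shifts),
            class = c("binned_spectra", class(out)))
}

# internal: numeric matrix of bin values (rownames = sample ids)
bin_values <- function(binned) {
  m <- as.matrix(binned[, setdiff(names(binned), "sample_id")])
  rownames(m) <- binned$sample_id
  m
}

# internal: rebuild a binned_spectra tibble from a numeric matrix, keeping
# the template's attributes
rebuild_binned <- function(values, template) {
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(values)),
    tibble::as_tibble(as.data.frame(values, check.names = FALSE)))
  structure(out,
            bin_edges = attr(template, "bin_edges"),
            pulse_seq = attr(template, "pulse_seq"),
            calibration = attr(template, "calibration"),
            class = c("binned_spectra", class(tibble::tibble())))
}
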