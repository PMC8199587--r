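#' Packaged serum metabolite signature library
#'
#' A fixture table of the 32 serum metabolite and macromolecule signals that
#' the univariate screen quantifies. Each signature carries one or more
#' Lorentzian peak definitions (chemical-shift center, relative height,
#' linewidth), a molecular-weight class that controls pulse-sequence
#' attenuation in the synthetic spectra, a designated quantification window,
#' and a baseline serum concentration in arbitrary units. Chemical-shift
#' positions are standard serum assignments; they are fixture data, not
#' measured claims.
#'
#' @return A tibble with one row per peak and columns `name`, `center_ppm`,
#'   `relative_height`, `linewidth`, `weight_class`
#'   (`"small_molecule"`/`"macromolecule"`), `quant_lo`, `quant_hi`,
#'   `base_conc`.
#' @examples
#' sig <- metabolite_signatures()
#' dplyr::n_distinct(sig$name)  # 32
#' @export
metabolite_signatures <- function() {
  cached <- get0(".signature_cache", envir = the_cache)
  if (!is.null(cached)) return(cached)
  # name | peaks "center:height" ; | class | quant window | baseline conc
  def <- list(
    list("Glutamine",               "2.12:0.6,2.44:1.0",          "small_molecule", c(2.42, 2.48), 0.60),
    list("Histidine",               "7.05:1.0,7.75:0.8",          "small_molecule", c(7.00, 7.10), 0.08),
    list("Formate",                 "8.45:1.0",                   "small_molecule", c(8.43, 8.47), 0.03),
    list("Alanine",                 "1.48:1.0",                   "small_molecule", c(1.46, 1.51), 0.40),
    list("Proline",                 "2.01:0.5,4.13:1.0",          "small_molecule", c(4.11, 4.16), 0.20),
    list("Valine",                  "0.99:1.0,1.04:1.0",          "small_molecule", c(0.97, 1.06), 0.25),
    list("3-Methyl-2-oxovalerate",  "0.90:0.6,1.10:1.0",          "small_molecule", c(1.08, 1.13), 0.03),
    list("Tyrosine",                "6.90:1.0,7.19:0.9",          "small_molecule", c(6.87, 6.93), 0.06),
    list("Acetate",                 "1.92:1.0",                   "small_molecule", c(1.90, 1.94), 0.05),
    # anomeric doublet with a roof effect so the taller line is a stable
    # calibration anchor for window-argmax alignment
    list("Glucose",                 "3.25:0.6,3.42:0.8,3.49:1.0,3.74:0.7,3.85:0.5,5.24:0.55,5.2463:0.38",
                                                                  "small_molecule", c(3.40, 3.55), 5.00),
    list("Isoleucine",              "0.94:1.0,1.01:0.8",          "small_molecule", c(0.99, 1.03), 0.07),
    list("3-Hydroxybutyrate",       "1.20:1.0,2.31:0.6,4.16:0.4", "small_molecule", c(1.18, 1.22), 0.10),
    list("Leucine",                 "0.96:1.0,1.71:0.5",          "small_molecule", c(0.94, 0.98), 0.15),
    list("Glycoproteins",           "2.04:1.0",                   "macromolecule",  c(2.00, 2.10), 1.20),
    list("Lactate",                 "1.33:1.0,4.11:0.3",          "small_molecule", c(1.31, 1.35), 2.00),
    list("Lipoproteins bCH2",       "1.57:1.0",                   "macromolecule",  c(1.52, 1.62), 1.00),
    list("Lipoproteins N(CH3)3",    "3.22:1.0",                   "macromolecule",  c(3.20, 3.26), 0.90),
    list("Cholesterol",             "0.66:1.0",                   "macromolecule",  c(0.62, 0.70), 0.50),
    list("Creatinine",              "3.05:1.0,4.06:0.6",          "small_molecule", c(4.04, 4.08), 0.09),
    list("Citrate",                 "2.54:1.0,2.66:1.0",          "small_molecule", c(2.50, 2.56), 0.12),
    list("Lipoproteins CHCH",       "5.31:1.0",                   "macromolecule",  c(5.27, 5.36), 0.80),
    list("Glutamate",               "2.09:0.6,2.35:1.0",          "small_molecule", c(2.32, 2.37), 0.10),
    list("Lipoproteins CH2n",       "1.28:1.0",                   "macromolecule",  c(1.25, 1.31), 2.50),
    list("N,N-Dimethylglycine",     "2.93:1.0",                   "small_molecule", c(2.91, 2.95), 0.02),
    list("Lipoproteins CHCH2CH",    "2.77:1.0",                   "macromolecule",  c(2.72, 2.82), 0.40),
    list("Lipoproteins CH3",        "0.88:1.0",                   "macromolecule",  c(0.84, 0.92), 1.80),
    list("Pyruvate",                "2.38:1.0",                   "small_molecule", c(2.36, 2.40), 0.08),
    list("Phenylalanine",           "7.33:0.8,7.37:0.6,7.42:1.0", "small_molecule", c(7.40, 7.45), 0.06),
    list("Dimethylsulfone",         "3.15:1.0",                   "small_molecule", c(3.13, 3.17), 0.01),
    list("Glycine",                 "3.56:1.0",                   "small_molecule", c(3.54, 3.58), 0.25),
    list("Lipoproteins CHCH2CH2",   "2.00:1.0",                   "macromolecule",  c(1.97, 2.03), 0.60),
    list("Creatine",                "3.03:1.0,3.93:0.7",          "small_molecule", c(3.91, 3.95), 0.04)
  )
  out <- purrr::map_dfr(def, function(d) {
    pk <- strsplit(strsplit(d[[2]], ",")[[1]], ":")
    tibble::tibble(
      name            = d[[1]],
      center_ppm      = vapply(pk, function(p) as.numeric(p[1]), 0),
      relative_height = vapply(pk, function(p) as.numeric(p[2]), 0),
      linewidth       = if (d[[3]] == "macromolecule") 0.03 else 0.004,
      weight_class    = d[[3]],
      quant_lo        = d[[4]][1],
      quant_hi        = d[[4]][2],
      base_conc       = d[[5]]
    )
  })
  assign(".signature_cache", out, envir = the_cache)
  out
}

the_cache <- new.env(parent = emptyenv())

#' Default group effect sizes for the synthetic cohort
#'
#' Signed Cliff's delta targets for the early-versus-metastatic contrast used
#' by the generator, one per packaged metabolite signal. Positive values mean
#' lower levels in the metastatic group.
#'
#' @return A named numeric vector of length 32 (names match
#'   [metabolite_signatures()]).
#' @export
default_target_deltas <- function() {
  c(
    "Glutamine" = 0.330, "Histidine" = 0.280, "Formate" = -0.212,
    "Alanine" = 0.168, "Proline" = 0.168, "Valine" = 0.163,
    "3-Methyl-2-oxovalerate" = -0.163, "Tyrosine" = 0.139,
    "Acetate" = -0.137, "Glucose" = 0.126, "Isoleucine" = 0.117,
    "3-Hydroxybutyrate" = -0.107, "Leucine" = 0.103,
    "Glycoproteins" = 0.097, "Lactate" = -0.093,
    "Lipoproteins bCH2" = 0.075, "Lipoproteins N(CH3)3" = 0.073,
    "Cholesterol" = 0.070, "Creatinine" = 0.068, "Citrate" = 0.065,
    "Lipoproteins CHCH" = 0.051, "Glutamate" = -0.045,
    "Lipoproteins CH2n" = 0.045, "N,N-Dimethylglycine" = -0.044,
    "Lipoproteins CHCH2CH" = 0.039, "Lipoproteins CH3" = 0.035,
    "Pyruvate" = -0.028, "Phenylalanine" = -0.024,
    "Dimethylsulfone" = -0.018, "Glycine" = -0.012,
    "Lipoproteins CHCH2CH2" = 0.012, "Creatine" = -0.010
  )
}

# internal: signatures collapsed to one row per metabolite (quant windows etc.)
signature_windows <- function(signatures) {
  if (missing(signatures)) {
    cached <- get0(".windows_cache", envir = the_cache)
    if (!is.null(cached)) return(cached)
    signatures <- metabolite_signatures()
    out <- dplyr::distinct(signatures, .data$name, .data$weight_class,
                           .data$quant_lo, .data$quant_hi, .data$base_conc)
    assign(".windows_cache", out, envir = the_cache)
    return(out)
  }
  dplyr::distinct(signatures, .data$name, .data$weight_class,
                  .data$quant_lo, .data$quant_hi, .data$base_conc)
}
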