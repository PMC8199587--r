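# shared fixtures built in code

# tiny cohort spec for fast end-to-end tests
tiny_spec <- function(seed = 1, ...) {
  cohort_spec(n_ecrc_free = 12, n_ecrc_relapsed = 4, n_mcrc = 12,
              seed = seed, ...)
}

# full concentration vector at the signature baselines
baseline_concentrations <- function() {
  sig <- metabolite_signatures()
  w <- dplyr::distinct(sig, name, base_conc)
  stats::setNames(w$base_conc, w$name)
}

# a clean spectrum with no technical artifacts, for exact-value tests
clean_spectrum <- function(concentrations = baseline_concentrations(),
                           pulse_seq = "NOESY", n_points = 8500,
                           ppm_range = c(0.1, 10.1), sample_id = "clean",
                           spec = cohort_spec(noise_sd = 0, dilution_sd = 0,
                                              miscalibration_sd = 0)) {
  synthesize_spectrum(concentrations, pulse_seq, spec,
                      ppm_range = ppm_range, n_points = n_points,
                      water_scale = 0, ethanol_prob = 0, protein_scale = 0,
                      sample_id = sample_id)
}

# binned matrix of two Gaussian classes with non-proportional mean profiles
# (so PQN cannot cancel the group difference), for classifier tests on a
# controlled geometry; gap scales the profile difference in noise SDs
separable_binned <- function(n_per_class = 20, p = 30, gap = 8, seed = 99) {
  set.seed(seed)
  mu0 <- runif(p, 5, 8)
  mu1 <- mu0 + gap * 0.3 * runif(p, -1, 1)
  X <- rbind(
    matrix(rnorm(n_per_class * p, sd = 0.3), n_per_class, p, byrow = FALSE) +
      matrix(mu0, n_per_class, p, byrow = TRUE),
    matrix(rnorm(n_per_class * p, sd = 0.3), n_per_class, p, byrow = FALSE) +
      matrix(mu1, n_per_class, p, byrow = TRUE))
  X <- pmax(X, 0.1)
  colnames(X) <- sprintf("b%02d", seq_len(p))
  tibble::tibble(sample_id = sprintf("S%03d", seq_len(2 * n_per_class))) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

separable_labels <- function(n_per_class = 20)
  rep(c("early", "metastatic"), each = n_per_class)

# independent pairwise counting oracle for Cliff's delta (sort/count based,
# distinct from the rank-sum implementation)
delta_oracle <- function(x, y) {
  ys <- sort(y)
  gt <- sum(as.numeric(findInterval(x, ys, left.open = TRUE)))  # #{y < x}
  ge <- sum(as.numeric(findInterval(x, ys)))                    # #{y <= x}
  npairs <- as.numeric(length(x)) * length(y)
  (gt - (npairs - ge)) / npairs
}
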