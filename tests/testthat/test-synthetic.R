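test_that("delta_to_mean_shift closed form matches a Monte-Carlo pairwise count", {
  expect_equal(delta_to_mean_shift(0, 1.7), 0)
  expect_equal(delta_to_mean_shift(-0.4, 2), -delta_to_mean_shift(0.4, 2))

  set.seed(101)
  shift <- delta_to_mean_shift(0.330, 1.0)
  x <- rnorm(1e5, mean = shift)
  y <- rnorm(1e5)
  expect_equal(delta_oracle(x, y), 0.330, tolerance = 0.01)

  expect_error(delta_to_mean_shift(1, 1), "unattainable")
  expect_error(delta_to_mean_shift(1.2, 1), "exceed 1")
  expect_error(delta_to_mean_shift(0.2, 0), "positive")
})

test_that("signature library carries the 32-signal serum panel", {
  sig <- metabolite_signatures()
  win <- dplyr::distinct(sig, name, quant_lo, quant_hi)
  expect_equal(nrow(win), 32)
  expect_true(all(sig$linewidth > 0))
  expect_true(all(sig$center_ppm >= 0.2 & sig$center_ppm <= 10.0))
  expect_true(all(win$quant_lo < win$quant_hi))
  expect_setequal(names(default_target_deltas()), unique(sig$name))
})

test_that("group concentrations are exchangeable under null deltas and mirror mCRC at fraction 1", {
  null_spec <- cohort_spec(target_deltas = c(Glutamine = 0),
                           seed = 1)
  set.seed(11)
  draws <- function(spec, group, n)
    t(replicate(n, as.numeric(sample_concentrations(spec, group)[1:5])))
  a <- draws(null_spec, "eCRC_free", 300)
  b <- draws(null_spec, "mCRC", 300)
  for (j in 1:5)
    expect_gt(stats::ks.test(a[, j], b[, j])$p.value, 0.001)

  mirror <- cohort_spec(relapsed_metastatic_fraction = 1, seed = 1)
  set.seed(12)
  r <- replicate(200, sample_concentrations(mirror, "eCRC_relapsed")["Glutamine"])
  m <- replicate(200, sample_concentrations(mirror, "mCRC")["Glutamine"])
  expect_gt(stats::ks.test(r, m)$p.value, 0.001)
  set.seed(13)
  flags <- replicate(50, attr(sample_concentrations(mirror, "eCRC_relapsed"),
                              "metastatic_like"))
  expect_true(all(flags == 1L))

  expect_error(cohort_spec(target_deltas = c(NotAMetabolite = 0.1)),
               "NotAMetabolite")
})

test_that("generator calibration: empirical deltas on true concentrations hit their targets", {
  spec <- cohort_spec(seed = 5)
  set.seed(500)
  n <- 4000  # +/-0.05 band; delta-hat SE ~0.013 here, so all 32 comparisons are sharp
  e <- t(replicate(n, as.numeric(sample_concentrations(spec, "eCRC_free"))))
  m <- t(replicate(n, as.numeric(sample_concentrations(spec, "mCRC"))))
  nm <- names(sample_concentrations(spec, "eCRC_free"))
  targets <- default_target_deltas()[nm]
  emp <- vapply(seq_along(nm), function(j) cliffs_delta(e[, j], m[, j]), 0)
  expect_true(all(abs(emp - targets) < 0.05),
              info = paste("worst:", nm[which.max(abs(emp - targets))]))
  # glutamine specifically within +/-0.08 of 0.330
  expect_equal(unname(emp[nm == "Glutamine"]), 0.330, tolerance = 0.08 / 0.33)
})

test_that("spectrum synthesis is linear, signal-localized and validates input", {
  spec0 <- cohort_spec(noise_sd = 0, dilution_sd = 0, miscalibration_sd = 0)
  zero <- baseline_concentrations() * 0
  sp <- synthesize_spectrum(zero, "NOESY", spec0, water_scale = 0,
                            ethanol_prob = 0, protein_scale = 0)
  expect_true(all(sp$intensity == 0))

  conc <- baseline_concentrations()
  s1 <- clean_spectrum(conc)
  s2 <- clean_spectrum(conc * 2)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-12)

  bad <- conc; bad["Lactate"] <- -1
  expect_error(clean_spectrum(bad), "Lactate")
})

test_that("a single Lorentzian's quantification window integral matches numeric integration", {
  sig <- metabolite_signatures()
  one <- sig[sig$name == "Acetate", ]  # singlet, isolated
  conc <- baseline_concentrations() * 0
  conc["Acetate"] <- 3
  spec0 <- cohort_spec(noise_sd = 0, dilution_sd = 0, miscalibration_sd = 0)
  sp <- synthesize_spectrum(conc, "NOESY", spec0, n_points = 2^16,
                            water_scale = 0, ethanol_prob = 0,
                            protein_scale = 0)
  got <- quantify_metabolites(list(sp))$Acetate
  oracle <- stats::integrate(function(x)
    3 * one$relative_height / (1 + ((x - one$center_ppm) / (one$linewidth / 2))^2),
    one$quant_lo, one$quant_hi, rel.tol = 1e-10)$value
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("survival simulation honours the hazard model and endpoint definitions", {
  p0 <- survival_sim_params(log_hr_high_risk = 0)
  set.seed(21)
  s <- simulate_survival(rep(c(0, 1), each = 500), p0)
  ks <- suppressWarnings(
    stats::ks.test(s$rfi_months[1:500], s$rfi_months[501:1000]))
  expect_gt(ks$p.value, 0.01)

  pz <- survival_sim_params(admin_censor_months = 0)
  set.seed(22)
  z <- simulate_survival(rep(0, 20), pz)
  expect_true(all(z$rfi_months == 0) && all(z$rfi_event == 0))
  expect_true(all(z$os_months == 0))

  set.seed(23)
  arm <- rep(c(0, 1), each = 500)
  d <- simulate_survival(arm, survival_sim_params())
  d$risk <- arm
  fit <- cox_fit(d, "rfi_months", "rfi_event", "risk")
  expect_equal(fit$estimate, log(3.6), tolerance = 0.15 / log(3.6))

  # endpoint consistency
  set.seed(24)
  s2 <- simulate_survival(rnorm(400), survival_sim_params())
  expect_true(all(is.na(s2$css_event) == (s2$rfi_event == 0)))
  expect_true(all(s2$dfs_months <= s2$os_months + 1e-9))
  expect_true(all(s2$rfi_months >= s2$dfs_months - 1e-9))
})

test_that("cohort generation is deterministic and bookkeeps subjects and spectra", {
  co <- simulate_cohort(cohort_spec(seed = 7), pulse_seqs = "NOESY",
                        n_points = 600)
  expect_equal(nrow(co$clinical), 169)
  expect_equal(length(co$spectra) * 3, 507 * 1)  # one pulse sequence here

  co3 <- simulate_cohort(tiny_spec(seed = 3), n_points = 600)
  expect_equal(length(co3$spectra), 3 * nrow(co3$clinical))
  expect_true(all(co3$clinical$rfi_event[co3$clinical$group == "eCRC_relapsed"] == 1))
  expect_true(all(co3$clinical$rfi_event[co3$clinical$group == "eCRC_free"] == 0))
  expect_true(all(is.na(co3$clinical$rfi_months[co3$clinical$group == "mCRC"])))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  one <- cohort_spec(n_ecrc_free = 2, n_ecrc_relapsed = 1, n_mcrc = 2, seed = 9)
  generate_cohort(one, dir1, n_points = 500)
  generate_cohort(one, dir2, n_points = 500)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  solo_dir <- withr::local_tempdir()
  solo <- cohort_spec(n_ecrc_free = 0, n_ecrc_relapsed = 0, n_mcrc = 1, seed = 2)
  generate_cohort(solo, solo_dir, n_points = 500)
  clin <- utils::read.csv(file.path(solo_dir, "clinical.csv"))
  expect_equal(nrow(clin), 1)
  expect_equal(length(list.files(solo_dir, pattern = "tsv$")), 3)
  expect_true(is.na(clin$rfi_event))
})
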