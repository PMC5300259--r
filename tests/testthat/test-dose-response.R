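# Hill activation/inhibition fitters, pH conversion and the scalar
# sensitivity statistics.

test_that("exact Hill data are recovered to numerical precision in both modes", {
  conc <- 10^seq(-0.5, 2.5, length.out = 8)
  ser <- hill_series(ec50 = 3.7, nh = 1.3, conc = conc)
  for (mode in c("fix_to_observed", "free_predicted")) {
    # fix_to_observed normalizes to the largest observed response, so exact
    # recovery holds when that response is effectively saturating
    f <- fit_activation(ser, mode)
    expect_equal(f$ec50, 3.7, tolerance = if (mode == "fix_to_observed")
      0.02 else 1e-6)
    expect_equal(f$n_h, 1.3, tolerance = if (mode == "fix_to_observed")
      0.02 else 1e-6)
    expect_true(f$converged)
  }
  f <- fit_activation(ser, "free_predicted")
  expect_equal(f$r_max, -1000, tolerance = 1e-5)
  expect_true(f$saturated)
})

test_that("fits are equivariant under response rescaling", {
  conc <- 10^seq(0, 3, length.out = 7)
  ser <- hill_series(ec50 = 30, nh = 1.1, conc = conc, rmax_pA = -500)
  ser2 <- ser; ser2$response <- ser$response * 3.7
  f1 <- fit_activation(ser, "free_predicted")
  f2 <- fit_activation(ser2, "free_predicted")
  expect_equal(f1$ec50, f2$ec50, tolerance = 1e-8)
  expect_equal(f1$n_h, f2$n_h, tolerance = 1e-8)
  expect_equal(f2$r_max, 3.7 * f1$r_max, tolerance = 1e-6)
})

test_that("activation fitter matches the brute-force grid oracle within 1% SSE", {
  withr::with_seed(404, {
    for (rep in 1:12) {
      ec50 <- 10^stats::runif(1, -0.5, 3)
      nh <- stats::runif(1, 0.7, 2.2)
      conc <- 10^seq(log10(ec50) - 1.5, log10(ec50) + 1.5, length.out = 8)
      noise <- sample(c(0, 0.02), 1) # fraction of max response
      ser <- hill_series(ec50, nh, conc, rmax_pA = -800,
                         noise_sd = noise * 800)
      f <- fit_activation(ser, "free_predicted")
      # compare on the fitter's own normalized scale (dominant sign is
      # negative/inward here)
      y <- 100 * (-ser$response) / max(abs(ser$response))
      sse_fit <- (f$residual_rms * 100 / max(abs(ser$response)))^2 * length(y)
      sse_oracle <- oracle_hill_sse(conc, y, free_max = TRUE)
      expect_lte(sse_fit, sse_oracle * 1.01 + 1e-10)
      if (noise == 0) expect_equal(f$ec50, ec50, tolerance = 1e-5)
    }
  })
})

test_that("free-predicted mode rescues truncated curves that the fixed mode underestimates", {
  # truncated mutant-like series: true EC50 13.7 mM, largest tested
  # concentration 30 mM (~2.2 x EC50)
  conc <- c(100, 300, 1000, 3000, 10000, 30000)
  withr::with_seed(505, {
    ec_free <- ec_fixed <- numeric(60)
    for (i in 1:60) {
      ser <- hill_series(13655, 1.2, conc, rmax_pA = -2000, noise_sd = 15)
      ec_free[i] <- fit_activation(ser, "free_predicted")$ec50
      ec_fixed[i] <- fit_activation(ser, "fix_to_observed")$ec50
    }
  })
  expect_lt(abs(mean(ec_free) - 13655) / 13655, 0.15)
  # normalizing to the largest observed response biases the EC50 low
  expect_lt(mean(ec_fixed), mean(ec_free))
  expect_lt(mean(ec_fixed), 13655 * 0.85)
})

test_that("non-monotone or sign-mixed series are refused", {
  conc <- c(1, 3, 10, 30, 100)
  bad <- response_series("x", "glutamate", conc, c(-10, -300, -50, -700, -20))
  expect_error(fit_activation(bad), "monotone")
  mixed <- response_series("x", "glutamate", conc, c(30, -20, -50, -80, -100))
  expect_error(fit_activation(mixed), "sign")
})

test_that("exact inhibition data are recovered and reduce to the activation mirror", {
  conc <- 10^seq(0, 3.2, length.out = 9) # nM
  ser <- inhib_series(ic50 = 87, nh = 1, minimum = 0.36, conc = conc)
  f <- fit_inhibition(ser)
  expect_equal(f$ic50, 87, tolerance = 1e-6)
  expect_equal(f$n_h, 1, tolerance = 1e-6)
  expect_equal(f$minimum, 0.36, tolerance = 1e-6)
  # minimum = 0: the inhibition model is the mirror of the activation model,
  # so fitting 1 - response with the activation fitter gives the same IC50
  ser0 <- inhib_series(ic50 = 42, nh = 1.4, minimum = 0, conc = conc)
  fi <- fit_inhibition(ser0)
  mirror <- response_series("x", "zinc", conc, -(1 - ser0$response) * 1000)
  fa <- fit_activation(mirror, "free_predicted")
  expect_equal(fi$ic50, fa$ec50, tolerance = 1e-4)
  expect_equal(fi$n_h, fa$n_h, tolerance = 1e-4)
})

test_that("inhibition fitter matches the brute-force grid oracle within 1% SSE", {
  withr::with_seed(606, {
    for (rep in 1:12) {
      ic50 <- 10^stats::runif(1, 0.5, 2.5)
      nh <- stats::runif(1, 0.7, 2)
      mn <- stats::runif(1, 0, 0.6)
      conc <- 10^seq(log10(ic50) - 1.5, log10(ic50) + 1.5, length.out = 8)
      noise <- sample(c(0, 0.01), 1)
      ser <- inhib_series(ic50, nh, mn, conc, noise_sd = noise)
      f <- fit_inhibition(ser)
      sse_fit <- f$residual_rms^2 * length(conc)
      sse_oracle <- oracle_inhib_sse(conc, ser$response)
      expect_lte(sse_fit, sse_oracle * 1.01 + 1e-12)
      if (noise == 0) {
        expect_equal(f$ic50, ic50, tolerance = 1e-5)
        expect_equal(f$minimum, mn, tolerance = 1e-5)
      }
    }
  })
})

test_that("pH to activity conversion and proton/zinc statistics", {
  expect_equal(ph_to_activity(7), 1e-7)
  expect_equal(ph_to_activity(6.8), 1.585e-7, tolerance = 1e-3)
  expect_true(all(diff(ph_to_activity(seq(6, 8, by = 0.25))) < 0))
  expect_error(ph_to_activity(15), "pH")
  # equal responses give 100%
  expect_equal(proton_ratio_statistic(-50, -50), 100)
  expect_error(proton_ratio_statistic(-50, 0), "noise floor")
  # closed form: with half-inhibition at pH 6.8 and Hill slope 1.37 the
  # pH 6.8 / pH 7.6 current ratio is ~54% (the wild-type calibration)
  fH <- function(pH, pKa = 6.8, h = 1.37) 1 / (1 + (10^(-pH) / 10^(-pKa))^h)
  ratio <- 100 * fH(6.8) / fH(7.6)
  expect_equal(ratio, 54, tolerance = 0.01)
  # and the simulator reproduces it end to end
  wt <- read_kinetic_model(model_fixture("wt2A"))
  p68 <- -1000 * nmdarfx:::modulator_factor(wt, pH = 6.8)
  p76 <- -1000 * nmdarfx:::modulator_factor(wt, pH = 7.6)
  expect_equal(proton_ratio_statistic(p68, p76), ratio, tolerance = 1e-6)
  # zinc: no block 0%, full block 100%, wild-type calibration ~36%
  expect_equal(zinc_max_inhibition(-80, -80), 0)
  expect_equal(zinc_max_inhibition(0, -80), 100)
  fZn <- wt$zinc_residual + (1 - wt$zinc_residual) / (1 + 300 / wt$zinc_ic50)
  expect_equal(zinc_max_inhibition(-100 * fZn, -100), 36, tolerance = 0.5)
})

test_that("inhibitor series extracted from simulated traces recover the modulator parameters", {
  wt <- read_kinetic_model(model_fixture("wt2A"))
  meta <- cell_meta("oo", "oocyte", "WT2A")
  # zinc: tricine-buffered series at -20 mV with a zinc-free control epoch
  pz <- protocol_inhibition("zinc", c(10, 30, 100, 300, 1000),
                            glutamate = 30000, epoch_duration = 20000,
                            baseline_duration = 5000)
  trz <- simulate_current(wt, pz, meta, sample_interval = 50)
  trz <- baseline_correct(trz, nmdarfx:::baseline_window_of(trz))
  fz <- fit_inhibition(extract_response_series(trz, "zinc"))
  expect_equal(fz$ic50, wt$zinc_ic50, tolerance = 0.02)
  expect_equal(fz$minimum, wt$zinc_residual, tolerance = 0.02)
  # magnesium at -60 mV: IC50 at the reference potential, minimum ~ 0
  pm <- protocol_inhibition("magnesium", c(3, 10, 30, 100, 300),
                            glutamate = 30000, epoch_duration = 20000,
                            baseline_duration = 5000)
  trm <- simulate_current(wt, pm, meta, sample_interval = 50)
  trm <- baseline_correct(trm, nmdarfx:::baseline_window_of(trm))
  fm <- fit_inhibition(extract_response_series(trm, "magnesium"))
  expect_equal(fm$ic50, wt$mg_ic50_at_v, tolerance = 0.05)
  expect_lt(fm$minimum, 0.02)
  # protons on the activity axis; the most-alkaline epoch is the control,
  # which is itself slightly inhibited, shifting the operational IC50 a bit
  pp <- protocol_inhibition("proton", c(8.0, 7.6, 7.2, 6.8, 6.4, 6.0),
                            glutamate = 30000, epoch_duration = 20000,
                            baseline_duration = 5000)
  trp <- simulate_current(wt, pp, meta, sample_interval = 50)
  trp <- baseline_correct(trp, nmdarfx:::baseline_window_of(trp))
  fp <- fit_inhibition(extract_response_series(trp, "proton"))
  expect_equal(-log10(fp$ic50), wt$proton_ic50_pH, tolerance = 0.02)
})
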