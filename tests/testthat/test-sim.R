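# Receptor simulator: ODE vs closed-form equilibrium, conservation,
# monotonicity, mixtures, MTSEA construction, EC50 bisection, cohorts.

test_that("zero glutamate gives zero (or pure-noise) current", {
  m <- quick_model()
  p <- protocol(rbind(epoch(0, 500), epoch(500, 500, glycine = 100)),
                exchange_tau = 1)
  tr <- simulate_current(m, p, oocyte_meta(), sample_interval = 1)
  expect_true(all(tr$current == 0))
  trn <- simulate_current(m, p, oocyte_meta(), noise_sd = 2, seed = 7,
                          sample_interval = 1)
  expect_lt(abs(mean(trn$current)), 0.5)
  expect_equal(stats::sd(trn$current), 2, tolerance = 0.15)
})

test_that("ODE steady state matches the closed-form equilibrium to 1e-6", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      m <- random_model()
      glu <- stats::runif(1, 10, 5000)
      p <- step_protocol(glutamate = glu, duration = 40000, baseline = 100,
                         exchange_tau = 0.01)
      occ <- nmdarfx:::solve_open_occupancy(m, p, seq(0, 40100, by = 20))
      p_ode <- occ[length(occ)]
      p_eq <- equilibrium_open_prob(m, glu)
      expect_equal(p_ode, p_eq, tolerance = 1e-6)
      expect_true(all(occ >= -1e-9 & occ <= 1))
    }
  })
  # saturating agonist, no modulators: equals B/(1+B+Dr)
  m <- quick_model()
  expect_equal(equilibrium_open_prob(m, Inf), scheme_popen_max(m),
               tolerance = 1e-9)
  # degenerate gating limits
  expect_equal(equilibrium_open_prob(quick_model(beta = 0), 1e9), 0)
  m1 <- kinetic_model(k_on_glu = 0.01, k_off_glu = 0.05, beta = 0.3,
                      alpha = 0, k_des = 0, k_res = 0.01)
  expect_equal(equilibrium_open_prob(m1, 1e9), 1)
})

test_that("steady response is monotone in agonist and in each inhibitor", {
  m <- quick_model()
  glu <- 10^seq(-1, 5, length.out = 40)
  expect_true(all(diff(equilibrium_open_prob(m, glu)) >= 0))
  pHs <- seq(8.5, 6, length.out = 30) # increasing [H+]
  expect_true(all(diff(equilibrium_open_prob(m, 100, pH = pHs)) <= 0))
  zns <- 10^seq(0, 4, length.out = 30)
  expect_true(all(diff(equilibrium_open_prob(m, 100, zinc = zns)) <= 0))
  mgs <- 10^seq(-1, 4, length.out = 30)
  expect_true(all(diff(equilibrium_open_prob(m, 100, mg = mgs)) <= 0))
})

test_that("mixture current is the fraction-weighted sum of component currents", {
  m1 <- quick_model()
  m2 <- quick_model(beta = 0.1, k_off_glu = 0.2, n_channels = 400)
  p <- step_protocol(glutamate = 200, duration = 1000, baseline = 100)
  t1 <- simulate_current(m1, p, oocyte_meta(), sample_interval = 1)
  t2 <- simulate_current(m2, p, oocyte_meta(), sample_interval = 1)
  mx <- mixture_model(list(m1, m2), c(0.3, 0.7))
  tmx <- simulate_current(mx, p, oocyte_meta(), sample_interval = 1)
  expect_equal(tmx$current, 0.3 * t1$current + 0.7 * t2$current,
               tolerance = 1e-9)
  # contaminant population enters with its stated fraction
  mx2 <- mixture_model(list(m1), 1, contaminant = m2,
                       contamination_fraction = 0.02)
  tmx2 <- simulate_current(mx2, p, oocyte_meta(), sample_interval = 1)
  expect_equal(tmx2$current, 0.98 * t1$current + 0.02 * t2$current,
               tolerance = 1e-9)
  expect_error(mixture_model(list(m1), 1, contaminant = m2,
                             contamination_fraction = 0.05), "0.03")
})

test_that("apparent EC50 matches the closed form and responds to unbinding rate", {
  withr::with_seed(202, {
    for (rep in 1:5) {
      m <- random_model()
      expect_equal(apparent_ec50(m, "glutamate"), scheme_ec50(m),
                   tolerance = 1e-5)
    }
  })
  m <- quick_model()
  m2 <- quick_model(k_off_glu = 2 * m$k_off_glu)
  expect_gt(apparent_ec50(m2, "glutamate"), apparent_ec50(m, "glutamate"))
  # glycine axis: half point of the co-agonist factor
  expect_equal(apparent_ec50(m, "glycine"), m$glycine_ec50, tolerance = 1e-5)
  # calibrated wild-type fixture
  wt <- read_kinetic_model(model_fixture("wt2A"))
  expect_equal(apparent_ec50(wt, "glutamate"), 3.7, tolerance = 0.1)
})

test_that("MTSEA construction: fixed point, worked potentiation, exact inversion", {
  # fixed point: pre-treatment open probability equal to the conductance
  # ratio with full lock-open gives potentiation 1
  m <- quick_model(beta = 0.3, alpha = 0.3, k_des = 0, k_res = 0.01,
                   gamma_mtsea_ratio = 0.5, popen_after_mtsea = 1)
  expect_equal(scheme_popen_max(m), 0.5, tolerance = 1e-9)
  ex <- simulate_mtsea_experiment(m, glutamate = 1e6)
  expect_equal(ex$potentiation, 1, tolerance = 1e-5)
  # conductance ratio 0.70 with pre-treatment open probability 0.278 gives
  # 252% potentiation (the di-heteromeric wild-type calibration)
  # P = B/(1+B+Dr) => B = P*(1+Dr)/(1-P); here Dr = 0.5.
  B <- 0.278 * 1.5 / (1 - 0.278)
  mwt <- kinetic_model(k_on_glu = 0.01, k_off_glu = 0.05, beta = 0.3 * B,
                       alpha = 0.3, k_des = 0.005, k_res = 0.01,
                       gamma_mtsea_ratio = 0.70, popen_after_mtsea = 1)
  expect_equal(scheme_popen_max(mwt), 0.278, tolerance = 1e-12)
  ex2 <- simulate_mtsea_experiment(mwt, glutamate = 1e7)
  expect_equal(ex2$potentiation, 0.70 / 0.278, tolerance = 1e-4)
  expect_equal(popen_from_mtsea(ex2$potentiation, 0.70)$value, 0.278,
               tolerance = 1e-4)
  # randomized models: conductance-ratio inversion of simulated potentiation
  # recovers the equilibrium open probability at the test condition
  withr::with_seed(303, {
    for (rep in 1:4) {
      m <- random_model()
      glu <- stats::runif(1, 50, 2000)
      ex <- simulate_mtsea_experiment(m, glutamate = glu)
      # the potentiation ratio cancels every multiplicative modulator
      # factor, so the inversion recovers the gating-only open probability
      p_true <- equilibrium_open_prob(m, glu)
      est <- popen_from_mtsea(ex$potentiation, m$gamma_mtsea_ratio)
      expect_equal(est$value, p_true, tolerance = 1e-6)
    }
  })
})

test_that("cohorts: zero variability collapses to identical cells; CV propagates; reproducible", {
  wt <- read_kinetic_model(model_fixture("wt2A"))
  p <- list(step = step_protocol(glutamate = 100, duration = 500,
                                 baseline = 100))
  cfg0 <- cohort_config(wt, p, n_cells = 3, cv_between_cells = 0,
                        cv_tempo = 0, cv_channels = 0, noise_sd = 0,
                        seed = 11, sample_interval = 1)
  co0 <- make_cohort(cfg0)
  expect_identical(co0[[1]]$traces$step$current, co0[[2]]$traces$step$current)
  expect_identical(co0[[2]]$traces$step$current, co0[[3]]$traces$step$current)
  # same seed, same cohort (bit-reproducible)
  cfgn <- cohort_config(wt, p, n_cells = 3, cv_between_cells = 0.2,
                        noise_sd = 5, seed = 12, sample_interval = 1)
  expect_identical(make_cohort(cfgn)[[2]]$traces$step$current,
                   make_cohort(cfgn)[[2]]$traces$step$current)
  # per-rate jitter propagates into the EC50 spread within a factor of 2
  cfg <- cohort_config(wt, p, n_cells = 40, cv_between_cells = 0.3,
                       cv_tempo = 0, seed = 13, sample_interval = 1)
  co <- make_cohort(cfg)
  ec50s <- vapply(co, function(cell) scheme_ec50(cell$model), numeric(1))
  cv_obs <- stats::sd(ec50s) / mean(ec50s)
  expect_gt(cv_obs, 0.3 / 2)
  expect_lt(cv_obs, 0.3 * 2)
  # shared-tempo variability rescales time constants but leaves EC50 alone
  cfgt <- cohort_config(wt, p, n_cells = 10, cv_between_cells = 0,
                        cv_tempo = 0.4, seed = 14, sample_interval = 1)
  cot <- make_cohort(cfgt)
  ec50t <- vapply(cot, function(cell) scheme_ec50(cell$model), numeric(1))
  expect_equal(max(ec50t) - min(ec50t), 0, tolerance = 1e-9)
  koffs <- vapply(cot, function(cell) cell$model$k_off_glu, numeric(1))
  expect_gt(stats::sd(koffs) / mean(koffs), 0.1)
})
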