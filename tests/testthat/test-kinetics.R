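# Deactivation fitting, rise time, charge transfer and MK-801 block onset.

test_that("noiseless bi-exponential decay is recovered exactly, with the closed-form weighted tau", {
  tr <- baseline_correct(biexp_trace(a_f = -80, tau_f = 41, a_s = -20,
                                     tau_s = 384), c(0, 90))
  f <- fit_deactivation(tr, 300)
  expect_equal(f$amp_fast, -80, tolerance = 1e-6)
  expect_equal(f$amp_slow, -20, tolerance = 1e-6)
  expect_equal(f$tau_fast, 41, tolerance = 1e-6)
  expect_equal(f$tau_slow, 384, tolerance = 1e-6)
  expect_equal(f$percent_fast, 80, tolerance = 1e-6)
  # amplitude-fraction weights: 0.8*41 + 0.2*384 = 109.6 ms
  expect_equal(f$tau_w, 109.6, tolerance = 1e-6)
  expect_false(f$single_exponential)
  # invariant ordering: fast < weighted < slow, same-sign amplitudes
  expect_true(f$tau_fast <= f$tau_w && f$tau_w <= f$tau_slow)
  expect_identical(sign(f$amp_fast), sign(f$amp_slow))
})

test_that("single-exponential input collapses to one component and is flagged", {
  tr <- baseline_correct(biexp_trace(a_f = -100, tau_f = 50, a_s = 0,
                                     tau_s = 51), c(0, 90))
  f <- fit_deactivation(tr, 300)
  expect_true(f$single_exponential)
  expect_equal(f$amp_slow, 0)
  expect_equal(f$tau_fast, 50, tolerance = 1e-6)
  expect_equal(f$tau_w, f$tau_fast)
})

test_that("weighted tau is invariant to which component is labelled fast", {
  # generate with the larger tau first; the fitter must re-sort
  tr <- baseline_correct(biexp_trace(a_f = -20, tau_f = 384, a_s = -80,
                                     tau_s = 41), c(0, 90))
  f <- fit_deactivation(tr, 300)
  expect_lt(f$tau_fast, f$tau_slow)
  expect_equal(f$tau_w, 109.6, tolerance = 1e-6)
})

test_that("bi-exponential fitter matches the brute-force grid oracle within 1% SSE", {
  withr::with_seed(707, {
    for (rep in 1:10) {
      tf <- stats::runif(1, 10, 60)
      ts <- tf * stats::runif(1, 3, 12)
      af <- -stats::runif(1, 40, 120)
      as_ <- -stats::runif(1, 5, 40)
      noise <- sample(c(0, 0.5), 1)
      tr <- baseline_correct(biexp_trace(af, tf, as_, ts, si = 1,
                                         noise_sd = noise), c(0, 90))
      f <- fit_deactivation(tr, 300)
      idx <- tr$time >= 300
      sse_fit <- f$residual_rms^2 * sum(idx)
      sse_oracle <- oracle_biexp_sse(tr$time[idx], tr$current[idx])
      expect_lte(sse_fit, sse_oracle * 1.01 + 1e-8)
      if (noise == 0) {
        expect_equal(f$tau_fast, tf, tolerance = 1e-5)
        expect_equal(f$tau_slow, ts, tolerance = 1e-5)
      }
    }
  })
})

test_that("rise time: closed form for an exponential rise; sample-interval floor for a step", {
  # mono-exponential rise: t90 - t10 = tau * ln(9)
  tau <- 2.17
  p <- protocol(rbind(epoch(0, 100), epoch(100, 200, glutamate = 1000,
                                           glycine = 100)),
                exchange_tau = 0.01)
  tt <- seq(0, 300, by = 0.02)
  cur <- ifelse(tt >= 100, -100 * (1 - exp(-(tt - 100) / tau)), 0)
  tr <- new_trace(tt, cur, p, hek_meta())
  expect_equal(rise_time_10_90(tr, 2), tau * log(9), tolerance = 1e-3)
  # instantaneous step: bounded by the sampling interval
  tr2 <- baseline_correct(square_trace(si = 1), c(50, 450))
  expect_lte(rise_time_10_90(tr2, 2), 1)
})

test_that("charge transfer: worked product, zero case, and quadrature agreement", {
  # mutant-column worked numbers: 5.1 pA/pF x 18 ms, printed rounded to 92
  expect_equal(round(charge_transfer(5.1, 18)), 92)
  expect_equal(charge_transfer(0, 100), 0)
  # for an instant-rise bi-exponential the product equals the integral
  tr <- baseline_correct(biexp_trace(a_f = -80, tau_f = 41, a_s = -20,
                                     tau_s = 384), c(0, 90))
  f <- fit_deactivation(tr, 300)
  # peak of the decay-only response is Amp_fast + Amp_slow
  peak_density <- abs(f$amp_fast + f$amp_slow) / tr$cell$capacitance
  product <- charge_transfer(peak_density, f$tau_w)
  tg <- seq(0, 20 * f$tau_slow, by = 0.5)
  quad <- pracma::trapz(tg, abs(-80 * exp(-tg / 41) - 20 * exp(-tg / 384))) /
    tr$cell$capacitance
  expect_equal(product, quad, tolerance = 0.01)
})

test_that("block onset: closed-form recovery, plateau handling, and the open-probability premise", {
  # noiseless decline with tau 3 s at 0.2 uM: k_on = 1/(3000*0.2)
  tr <- baseline_correct(block_trace(tau_on = 3000, plateau = 0), c(0, 900))
  bk <- fit_block_onset(tr, 3)
  expect_equal(bk$tau_on, 3000, tolerance = 1e-5)
  expect_equal(bk$k_on, 1 / (3000 * 0.2), tolerance = 1e-5)
  expect_equal(bk$plateau_fraction, 0, tolerance = 1e-6)
  # with a residual plateau the decaying component is still recovered
  tr2 <- baseline_correct(block_trace(tau_on = 3000, plateau = -40,
                                      amp = -460), c(0, 900))
  bk2 <- fit_block_onset(tr2, 3)
  expect_equal(bk2$tau_on, 3000, tolerance = 1e-4)
  expect_equal(bk2$plateau_fraction, -40 / -500, tolerance = 1e-4)
  # exponential-plus-plateau fitter vs grid oracle on noisy declines
  withr::with_seed(808, {
    for (rep in 1:8) {
      tau <- stats::runif(1, 1500, 8000)
      pl <- -stats::runif(1, 0, 60)
      tr3 <- baseline_correct(block_trace(tau_on = tau, plateau = pl,
                                          amp = -500, block_dur = 25000,
                                          noise_sd = 1), c(0, 900))
      bk3 <- fit_block_onset(tr3, 3)
      idx <- tr3$time >= 3000
      sse_fit <- bk3$residual_rms^2 * sum(idx)
      sse_oracle <- oracle_exp_plateau_sse(tr3$time[idx], tr3$current[idx])
      expect_lte(sse_fit, sse_oracle * 1.01 + 1e-8)
    }
  })
  # mechanistic premise: in a simulated receptor the onset rate equals
  # k_block * [MK-801] * P_open when block is slow relative to gating
  m <- quick_model(k_des = 0.005, k_res = 0.01, k_block_mk = 5e-4)
  p_open <- scheme_popen_max(m)
  pmk <- protocol_mk801(glutamate = 1e5, mk801 = 0.2,
                        agonist_duration = 10000, block_duration = 120000,
                        baseline_duration = 2000, exchange_tau = 100)
  trs <- baseline_correct(simulate_current(m, pmk, oocyte_meta(),
                                           sample_interval = 100),
                          c(0, 1500))
  bks <- fit_block_onset(trs, 3)
  expect_equal(1 / bks$tau_on, m$k_block_mk * 0.2 * p_open, tolerance = 0.02)
  # refuses a non-declining epoch
  flat <- baseline_correct(block_trace(tau_on = 1e9), c(0, 900))
  expect_error(fit_block_onset(flat, 3), "declining")
})
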