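## Time-course analysis: bi-exponential deactivation with amplitude-weighted
## tau, 10-90% rise time, Iss/Ipeak, charge transfer, and single-exponential
## MK-801 block onset.

biexp_pred <- function(t, a_f, tau_f, a_s, tau_s)
  a_f * exp(-t / tau_f) + a_s * exp(-t / tau_s)

## Deterministic multi-start bi-exponential fit. For each (tau_f, tau_s)
## pair on a decade-spaced grid the amplitudes are solved by linear least
## squares; the best start is refined with Levenberg-Marquardt.
fit_biexp <- function(t, y, single = FALSE) {
  # t is time since the decay origin (amplitudes are referenced to t = 0;
  # the first sample may sit later when a dead time is excluded)
  span <- max(t) - min(t)
  t0 <- t
  taus <- 10^seq(log10(max(span / 500, 1e-3)), log10(span * 2),
                 length.out = 10)
  lin_amp <- function(tf, ts) {
    X <- cbind(exp(-t0 / tf), exp(-t0 / ts))
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(NULL)
    list(a = cf, sse = sum((y - X %*% cf)^2))
  }
  if (single) {
    cand <- lapply(taus, function(tf) {
      X <- cbind(exp(-t0 / tf))
      cf <- stats::lm.fit(X, y)$coefficients
      list(start = list(a_f = unname(cf[[1]]), ltf = log(tf)),
           sse = sum((y - X * cf)^2))
    })
    cand <- cand[order(vapply(cand, function(x) x$sse, numeric(1)))]
    fit <- NULL
    for (st in cand) {
      fit <- robust_nlsLM(function(ctrl)
        minpack.lm::nlsLM(y ~ a_f * exp(-t0 / exp(ltf)), start = st$start,
                          control = ctrl))
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("single-exponential fit failed to converge")
    cf <- stats::coef(fit)
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    return(list(a_f = cf[["a_f"]], tau_f = exp(cf[["ltf"]]), a_s = 0,
                tau_s = NA_real_,
                se_tau_f = if (!is.null(vc))
                  exp(cf[["ltf"]]) * sqrt(vc["ltf", "ltf"]) else NA_real_,
                sse = sum(stats::resid(fit)^2), single = TRUE))
  }
  cand <- list()
  for (i in seq_along(taus)) for (j in seq_along(taus)) {
    if (j <= i) next
    la <- lin_amp(taus[i], taus[j])
    if (is.null(la)) next
    cand[[length(cand) + 1]] <-
      list(start = list(a_f = unname(la$a[1]), ltf = log(taus[i]),
                        a_s = unname(la$a[2]), lts = log(taus[j])),
           sse = la$sse)
  }
  cand <- cand[order(vapply(cand, function(x) x$sse, numeric(1)))]
  fit <- NULL
  for (st in cand[seq_len(min(5, length(cand)))]) {
    fit <- robust_nlsLM(function(ctrl)
      minpack.lm::nlsLM(
        y ~ a_f * exp(-t0 / exp(ltf)) + a_s * exp(-t0 / exp(lts)),
        start = st$start, control = ctrl))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("bi-exponential fit failed to converge")
  cf <- stats::coef(fit)
  tf <- exp(cf[["ltf"]]); ts <- exp(cf[["lts"]])
  af <- cf[["a_f"]]; as_ <- cf[["a_s"]]
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp
                 tmp <- af; af <- as_; as_ <- tmp }
  list(a_f = af, tau_f = tf, a_s = as_, tau_s = ts,
       sse = sum(stats::resid(fit)^2), single = FALSE)
}

#' Fit the deactivation time course after agonist removal
#'
#' Fits the two-component exponential
#' `I(t) = Amp_fast * exp(-t/tau_fast) + Amp_slow * exp(-t/tau_slow)`
#' to the current following glutamate removal (fit window starts
#' 3 x exchange_tau after `removal_time` to exclude exchange artifacts) and
#' derives the amplitude-weighted time constant
#' `tau_w = %fast * tau_fast + %slow * tau_slow` (amplitude-fraction
#' weights), the 10-90% rise time and Iss/Ipeak of the preceding agonist
#' pulse, peak and steady-state current densities (pA/pF, reported as
#' magnitudes), and the charge transfer `peak_density * tau_w`. If the two
#' fitted time constants collapse (within 5%) the fit falls back to a
#' single exponential with `amp_slow = 0` and is flagged.
#'
#' @param trace A baseline-corrected `nmda_trace` from a pulse protocol.
#' @param removal_time Time (ms) at which the agonist epoch ends.
#' @return A `deactivation_fit` list; see Details for fields.
#' @export
fit_deactivation <- function(trace, removal_time) {
  ep <- trace$protocol$epochs
  pulse <- which(abs(ep$start + ep$duration - removal_time) <
                   trace$sample_interval & ep$glutamate > 0)
  if (length(pulse) != 1)
    stop("removal_time must mark the end of a glutamate epoch")
  peak <- epoch_response(trace, pulse, "peak")
  ss <- epoch_response(trace, pulse, "steady")
  cap <- trace$cell$capacitance
  t_start <- removal_time + 3 * trace$protocol$exchange_tau
  idx <- trace$time >= t_start
  tt <- trace$time[idx] - removal_time
  yy <- trace$current[idx]
  tail_end <- mean(yy[tt >= max(tt) * 0.9])
  if (abs(tail_end) > 0.5 * max(abs(yy)))
    warning("post-removal window may be shorter than ~5 slow time constants")
  bi <- fit_biexp(tt, yy)
  if (!bi$single && (bi$tau_s - bi$tau_f) / bi$tau_s < 0.05) {
    bi <- fit_biexp(tt, yy, single = TRUE)
  } else if (!bi$single && sign(bi$a_f) != sign(bi$a_s)) {
    bi <- fit_biexp(tt, yy, single = TRUE)
  }
  amp_tot <- bi$a_f + bi$a_s
  pf <- 100 * bi$a_f / amp_tot
  tau_w <- if (bi$single) bi$tau_f else
    (bi$a_f * bi$tau_f + bi$a_s * bi$tau_s) / amp_tot
  peak_density <- if (is.na(cap)) NA_real_ else abs(peak) / cap
  ss_density <- if (is.na(cap)) NA_real_ else abs(ss) / cap
  ## diagnostic cross-check: numeric integral of the fitted decay per pF
  integral <- if (is.na(cap)) NA_real_ else {
    tg <- seq(0, 10 * (if (bi$single) bi$tau_f else bi$tau_s),
              length.out = 4000)
    pracma::trapz(tg, abs(biexp_pred(tg, bi$a_f, bi$tau_f, bi$a_s,
                                     ifelse(bi$single, 1, bi$tau_s)))) / cap
  }
  structure(list(
    cell_id = trace$cell$cell_id,
    amp_fast = bi$a_f, amp_slow = bi$a_s,
    tau_fast = bi$tau_f, tau_slow = if (bi$single) bi$tau_f else bi$tau_s,
    percent_fast = if (bi$single) 100 else pf,
    tau_w = tau_w,
    rise_10_90 = rise_time_10_90(trace, pulse),
    i_ss_over_i_peak = ss / peak,
    peak_density = peak_density, ss_density = ss_density,
    charge_transfer = if (is.na(cap)) NA_real_ else peak_density * tau_w,
    decay_integral = integral,
    residual_rms = sqrt(bi$sse / length(yy)),
    single_exponential = bi$single), class = "deactivation_fit")
}

#' 10-90% rise time of the response in an epoch
#'
#' Linear-interpolated times at which the current first crosses 10% and 90%
#' of the epoch's peak amplitude, measured from the epoch start; returns
#' their difference. Resolution is bounded below by the sampling interval.
#'
#' @param trace A baseline-corrected `nmda_trace`.
#' @param onset_epoch 1-based index of the epoch containing the rising phase.
#' @return Rise time (ms).
#' @export
rise_time_10_90 <- function(trace, onset_epoch) {
  ep <- trace$protocol$epochs
  t0 <- ep$start[onset_epoch]
  t1 <- t0 + ep$duration[onset_epoch]
  idx <- which(trace$time >= t0 & trace$time <= t1)
  y <- abs(trace$current[idx])
  tt <- trace$time[idx]
  ipk <- which.max(y)
  if (ipk == length(y)) {
    # monotone rise to the epoch end: accept only if flattened (within 2%
    # over the last tenth of the epoch), otherwise the peak lies beyond
    late <- y[tt >= t1 - 0.1 * ep$duration[onset_epoch]]
    if ((max(late) - min(late)) > 0.02 * max(y))
      stop("peak not reached within the epoch")
  }
  peak <- y[ipk]
  cross <- function(frac) {
    th <- frac * peak
    k <- which(y[seq_len(ipk)] >= th)[1]
    if (is.na(k)) stop("threshold not crossed")
    if (k == 1) return(tt[1])
    # linear interpolation between samples k-1 and k
    tt[k - 1] + (th - y[k - 1]) / (y[k] - y[k - 1]) * (tt[k] - tt[k - 1])
  }
  cross(0.9) - cross(0.1)
}

#' Synaptic charge transfer from peak amplitude and weighted tau
#'
#' The synaptic-like response is approximated as an instantaneously rising,
#' exponentially decaying current, whose integral is the product of the
#' peak amplitude density and the weighted decay time constant.
#'
#' @param peak_density Peak current density (pA/pF, positive magnitude).
#' @param tau_w Weighted deactivation time constant (ms).
#' @return Charge transfer (pA ms / pF).
#' @export
charge_transfer <- function(peak_density, tau_w) {
  stopifnot(peak_density >= 0, tau_w >= 0)
  peak_density * tau_w
}

#' Fit MK-801 block onset kinetics
#'
#' Fits `I(t) = plateau + Amplitude * exp(-t/tau_on)` to the current decline
#' during blocker co-application (window starts 3 x exchange_tau into the
#' epoch). The printed single-exponential form has no plateau term; the
#' additive plateau is reported separately for robustness and the fit
#' reduces to the pure exponential when it is 0. The microscopic
#' association rate is `k_on = 1 / (tau_on * [blocker])`.
#'
#' @param trace A baseline-corrected `nmda_trace`.
#' @param block_epoch 1-based index of the epoch with blocker present.
#' @return A `block_kinetics` list: `tau_on` (ms), `se_tau_on`, `k_on`
#'   (uM^-1 ms^-1), `blocker_concentration` (uM), `voltage` (mV),
#'   `plateau_fraction`, `residual_rms`, `cell_id`.
#' @export
fit_block_onset <- function(trace, block_epoch) {
  ep <- trace$protocol$epochs
  conc <- ep$mk801[block_epoch]
  if (conc <= 0) stop("block epoch has no MK-801")
  if (ep$glutamate[block_epoch] <= 0)
    stop("block epoch must have constant agonist present")
  t0 <- ep$start[block_epoch] + 3 * trace$protocol$exchange_tau
  t1 <- ep$start[block_epoch] + ep$duration[block_epoch]
  idx <- which(trace$time >= t0 & trace$time <= t1)
  tt <- trace$time[idx] - t0
  yy <- trace$current[idx]
  n <- length(yy)
  head_m <- mean(yy[seq_len(max(3, n %/% 20))])
  tail_m <- mean(yy[(n - max(3, n %/% 20)):n])
  if (abs(tail_m) > 0.95 * abs(head_m))
    stop("current is not declining during the block epoch")
  span <- max(tt)
  taus <- 10^seq(log10(span / 200), log10(span * 2), length.out = 12)
  cand <- lapply(taus, function(tau) {
    X <- cbind(1, exp(-tt / tau))
    cf <- stats::lm.fit(X, yy)$coefficients
    list(start = list(p = unname(cf[[1]]), a = unname(cf[[2]]),
                      ltau = log(tau)),
         sse = sum((yy - X %*% cf)^2))
  })
  cand <- cand[order(vapply(cand, function(x) x$sse, numeric(1)))]
  fit <- NULL
  for (st in cand) {
    fit <- robust_nlsLM(function(ctrl)
      minpack.lm::nlsLM(yy ~ p + a * exp(-tt / exp(ltau)),
                        start = st$start, control = ctrl))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("block-onset fit failed to converge")
  cf <- stats::coef(fit)
  tau_on <- exp(cf[["ltau"]])
  if (span < 2 * tau_on)
    warning("block epoch shorter than ~2 estimated onset time constants")
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se_tau <- if (!is.null(vc)) tau_on * sqrt(vc["ltau", "ltau"]) else NA_real_
  plateau_fraction <- cf[["p"]] / (cf[["p"]] + cf[["a"]])
  structure(list(
    cell_id = trace$cell$cell_id,
    tau_on = tau_on, se_tau_on = se_tau,
    k_on = 1 / (tau_on * conc),
    blocker_concentration = conc,
    voltage = ep$holding_potential[block_epoch],
    plateau_fraction = plateau_fraction,
    residual_rms = sqrt(sum(stats::resid(fit)^2) / n)),
    class = "block_kinetics")
}

#' Construct block kinetics from a measured onset rate
#'
#' Convenience constructor for computing relative open probability from
#' published or externally measured onset rates (rather than from a trace).
#'
#' @param inv_tau_on Onset rate 1/tau (ms^-1).
#' @param blocker_concentration Blocker concentration (uM).
#' @param voltage Holding potential (mV).
#' @param se_inv_tau Optional SE of the onset rate (ms^-1).
#' @param cell_id Identifier.
#' @return A `block_kinetics` list.
#' @export
block_kinetics <- function(inv_tau_on, blocker_concentration, voltage = -40,
                           se_inv_tau = NA_real_, cell_id = "") {
  stopifnot(inv_tau_on > 0, blocker_concentration > 0)
  tau <- 1 / inv_tau_on
  structure(list(cell_id = cell_id, tau_on = tau,
                 se_tau_on = if (is.na(se_inv_tau)) NA_real_ else
                   se_inv_tau / inv_tau_on^2,
                 k_on = 1 / (tau * blocker_concentration),
                 blocker_concentration = blocker_concentration,
                 voltage = voltage, plateau_fraction = 0,
                 residual_rms = NA_real_), class = "block_kinetics")
}
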