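## Canonical protocol builders for the experiment types in the study design:
## oocyte (TEVC) concentration-response series, HEK rapid-perfusion glutamate
## pulses, and oocyte MK-801 block onset. All return nmda_protocol objects.

rbind_epochs <- function(...) do.call(rbind, list(...))

#' Concentration-response protocol for an activating agonist
#'
#' A zero-agonist baseline epoch followed by one epoch per concentration,
#' ascending (cumulative application, as in bath-perfused TEVC recordings).
#'
#' @param axis `"glutamate"` or `"glycine"`.
#' @param concs Ascending test concentrations (uM).
#' @param glutamate_bg Background glutamate when titrating glycine (uM).
#' @param glycine_bg Background glycine when titrating glutamate (uM).
#' @param epoch_duration Duration of each concentration epoch (ms).
#' @param baseline_duration Duration of the leading agonist-free epoch (ms).
#' @param exchange_tau Bath exchange time constant (ms).
#' @param holding_potential Command potential (mV).
#' @param pH Solution pH.
#' @return An `nmda_protocol`.
#' @export
protocol_activation <- function(axis = c("glutamate", "glycine"), concs,
                                glutamate_bg = 30000, glycine_bg = 100,
                                epoch_duration = 30000,
                                baseline_duration = 10000,
                                exchange_tau = 2000, holding_potential = -40,
                                pH = 7.4) {
  axis <- match.arg(axis)
  stopifnot(length(concs) >= 1, all(diff(concs) > 0))
  starts <- baseline_duration + (seq_along(concs) - 1) * epoch_duration
  eps <- epoch(0, baseline_duration, pH = pH,
               holding_potential = holding_potential)
  for (i in seq_along(concs)) {
    glu <- if (axis == "glutamate") concs[i] else glutamate_bg
    gly <- if (axis == "glycine") concs[i] else glycine_bg
    eps <- rbind(eps, epoch(starts[i], epoch_duration, glutamate = glu,
                            glycine = gly, pH = pH,
                            holding_potential = holding_potential))
  }
  protocol(eps, exchange_tau = exchange_tau,
           label = paste0("cr_", axis))
}

#' Concentration-response protocol for an inhibitor
#'
#' A zero-agonist baseline, a control epoch (agonist, no inhibitor), then
#' one epoch per inhibitor level with the agonist maintained. For the
#' proton axis, `levels` are pH values (descending pH = ascending inhibitor)
#' and the control epoch uses the most alkaline pH in the series.
#'
#' @param axis `"proton"`, `"zinc"` or `"magnesium"`.
#' @param levels Inhibitor levels: pH values for `"proton"` (descending),
#'   nM for `"zinc"`, uM for `"magnesium"` (ascending).
#' @param glutamate,glycine Agonist concentrations (uM).
#' @param epoch_duration,baseline_duration,exchange_tau As in
#'   [protocol_activation()].
#' @param holding_potential Command potential (mV); the study design uses
#'   -20 mV for zinc, -60 mV for magnesium, -40 mV otherwise.
#' @param pH Solution pH for non-proton axes.
#' @return An `nmda_protocol`.
#' @export
protocol_inhibition <- function(axis = c("proton", "zinc", "magnesium"),
                                levels, glutamate = 30000, glycine = 100,
                                epoch_duration = 30000,
                                baseline_duration = 10000,
                                exchange_tau = 2000,
                                holding_potential = NULL, pH = 7.4) {
  axis <- match.arg(axis)
  if (is.null(holding_potential))
    holding_potential <- switch(axis, zinc = -20, magnesium = -60, -40)
  if (axis == "proton") {
    stopifnot(all(diff(levels) < 0)) # descending pH
  } else stopifnot(all(diff(levels) > 0))
  ctrl_pH <- if (axis == "proton") max(levels) else
    if (axis == "zinc") 7.3 else pH
  mk_ep <- function(start, level, control) {
    epoch(start, epoch_duration, glutamate = glutamate, glycine = glycine,
          pH = if (axis == "proton") (if (control) ctrl_pH else level) else ctrl_pH,
          zinc = if (axis == "zinc" && !control) level else 0,
          magnesium = if (axis == "magnesium" && !control) level else 0,
          holding_potential = holding_potential)
  }
  eps <- epoch(0, baseline_duration, pH = ctrl_pH,
               holding_potential = holding_potential)
  eps <- rbind(eps, mk_ep(baseline_duration, NA, control = TRUE))
  test_levels <- if (axis == "proton") levels[levels < ctrl_pH] else levels
  starts <- baseline_duration + epoch_duration +
    (seq_along(test_levels) - 1) * epoch_duration
  for (i in seq_along(test_levels))
    eps <- rbind(eps, mk_ep(starts[i], test_levels[i], control = FALSE))
  protocol(eps, exchange_tau = exchange_tau, label = paste0("cr_", axis))
}

#' Rapid-perfusion glutamate pulse protocol (synaptic-like response)
#'
#' Pre-pulse glycine-only epoch, a glutamate pulse (1.5 s "prolonged" or
#' 5 ms "brief" application), then glycine-only washout for the deactivation
#' time course.
#'
#' @param pulse_duration Glutamate application (ms).
#' @param glutamate,glycine Concentrations (uM).
#' @param pre_duration,post_duration Epoch durations around the pulse (ms).
#' @param exchange_tau Open-tip exchange time constant (ms), < 1 ms for
#'   theta-tube perfusion.
#' @param holding_potential Command potential (mV).
#' @return An `nmda_protocol`.
#' @export
protocol_pulse <- function(pulse_duration = 1500, glutamate = 30000,
                           glycine = 100, pre_duration = 100,
                           post_duration = 2500, exchange_tau = 0.5,
                           holding_potential = -60) {
  eps <- rbind_epochs(
    epoch(0, pre_duration, glycine = glycine,
          holding_potential = holding_potential),
    epoch(pre_duration, pulse_duration, glutamate = glutamate,
          glycine = glycine, holding_potential = holding_potential),
    epoch(pre_duration + pulse_duration, post_duration, glycine = glycine,
          holding_potential = holding_potential))
  protocol(eps, exchange_tau = exchange_tau,
           label = sprintf("pulse_%gms", pulse_duration))
}

#' MK-801 block onset protocol
#'
#' Baseline, an agonist-alone epoch long enough to reach steady state, then
#' co-application of MK-801 with the agonist maintained. Receptors are
#' activated at the composition's glutamate EC50 (the study-design
#' convention for block-rate comparisons).
#'
#' @param glutamate Glutamate (uM), typically the EC50.
#' @param glycine Glycine (uM).
#' @param mk801 Blocker concentration (uM).
#' @param agonist_duration Pre-block agonist epoch (ms).
#' @param block_duration Blocker co-application epoch (ms); should exceed
#'   twice the expected onset time constant.
#' @param baseline_duration,exchange_tau,holding_potential As elsewhere.
#' @return An `nmda_protocol`.
#' @export
protocol_mk801 <- function(glutamate, glycine = 100, mk801 = 0.2,
                           agonist_duration = 20000, block_duration = 40000,
                           baseline_duration = 5000, exchange_tau = 2000,
                           holding_potential = -40) {
  eps <- rbind_epochs(
    epoch(0, baseline_duration, holding_potential = holding_potential),
    epoch(baseline_duration, agonist_duration, glutamate = glutamate,
          glycine = glycine, holding_potential = holding_potential),
    epoch(baseline_duration + agonist_duration, block_duration,
          glutamate = glutamate, glycine = glycine, mk801 = mk801,
          holding_potential = holding_potential))
  protocol(eps, exchange_tau = exchange_tau, label = "mk801_onset")
}

#' Simulate an MTSEA potentiation experiment
#'
#' Simulates the steady agonist-evoked current of a GluN1(A652C)-containing
#' receptor before and after MTSEA modification (see [apply_mtsea()]) under
#' identical agonist conditions and returns the potentiation ratio
#' (current after / current before).
#'
#' @param model A `kinetic_model` (pre-treatment).
#' @param glutamate Test glutamate (uM); the study design uses the EC50 of
#'   the composition under test (saturating glutamate for the reference
#'   open-probability calibration).
#' @param glycine Glycine (uM).
#' @param meta A [cell_meta()]; defaults to an oocyte.
#' @param noise_sd,seed Noise settings passed to [simulate_current()].
#' @param steady_duration Duration of the agonist epoch (ms); long enough
#'   that the steady-state window is fully equilibrated.
#' @param exchange_tau Bath exchange time constant (ms).
#' @return A list with `potentiation` (ratio), `i_before`, `i_after` (pA,
#'   signed) and the two traces.
#' @export
simulate_mtsea_experiment <- function(model, glutamate, glycine = 100,
                                      meta = NULL, noise_sd = 0, seed = 1L,
                                      steady_duration = 60000,
                                      exchange_tau = 2000) {
  if (is.null(meta)) meta <- cell_meta("mtsea", "oocyte")
  prot <- protocol(rbind_epochs(
    epoch(0, 5000, holding_potential = -40),
    epoch(5000, steady_duration, glutamate = glutamate, glycine = glycine,
          holding_potential = -40)),
    exchange_tau = exchange_tau, label = "mtsea_steady")
  sim1 <- simulate_current(model, prot, meta, noise_sd = noise_sd,
                           seed = seed, sample_interval = 25)
  sim2 <- simulate_current(apply_mtsea(model), prot, meta,
                           noise_sd = noise_sd, seed = seed + 1L,
                           sample_interval = 25)
  b1 <- baseline_correct(sim1, c(0, 4000))
  b2 <- baseline_correct(sim2, c(0, 4000))
  i_before <- epoch_response(b1, 2, "steady")
  i_after <- epoch_response(b2, 2, "steady")
  list(potentiation = i_after / i_before, i_before = i_before,
       i_after = i_after, trace_before = b1, trace_after = b2)
}
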