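## Relative open-probability inference. Two routes:
##  - MK-801 onset kinetics: the blocker only binds open channels, so the
##    onset rate is proportional to open probability and
##    P_open(test) = P_open(ref) * k_on(test) / k_on(ref).
##  - MTSEA potentiation of GluN1(A652C) receptors: the reagent locks
##    channels open with altered conductance, so potentiation is inversely
##    proportional to the pre-treatment open probability and
##    P_open = (gamma_MTSEA / gamma_control) / Potentiation.

#' Open probability from relative MK-801 block kinetics
#'
#' `P_open(test) = popen_ref * k_on(test) / k_on(ref)`, valid when both
#' onset rates were measured at the same blocker concentration and holding
#' potential. The standard error is propagated from the onset-rate SEs by
#' the delta method. Estimates above 1 are clipped to 1 and flagged.
#'
#' @param kin_test,kin_ref `block_kinetics` for the test and reference
#'   receptor (see [fit_block_onset()], [block_kinetics()]).
#' @param popen_ref Reference open probability in (0, 1]; the study-design
#'   anchors are 0.278 for di-heteromeric WT GluN2A and 0.370 for
#'   tri-heteromeric WT 2A/2A.
#' @return An `open_prob_estimate` list: `value`, `se`, `method`,
#'   `reference_popen`, `clipped`.
#' @export
popen_from_mk801 <- function(kin_test, kin_ref, popen_ref = 0.278) {
  stopifnot(inherits(kin_test, "block_kinetics"),
            inherits(kin_ref, "block_kinetics"),
            popen_ref > 0, popen_ref <= 1)
  if (abs(kin_test$blocker_concentration - kin_ref$blocker_concentration) >
      1e-9 * kin_ref$blocker_concentration)
    stop("test and reference blocker concentrations differ; refusing")
  if (abs(kin_test$voltage - kin_ref$voltage) > 1e-9)
    stop("test and reference holding potentials differ; refusing")
  value <- popen_ref * kin_test$k_on / kin_ref$k_on
  rel_t <- if (is.na(kin_test$se_tau_on)) 0 else
    kin_test$se_tau_on / kin_test$tau_on
  rel_r <- if (is.na(kin_ref$se_tau_on)) 0 else
    kin_ref$se_tau_on / kin_ref$tau_on
  se <- value * sqrt(rel_t^2 + rel_r^2)
  clipped <- value > 1
  structure(list(value = min(value, 1), se = se, method = "MK801_relative",
                 reference_popen = popen_ref, clipped = clipped),
            class = "open_prob_estimate")
}

#' Open probability from MTSEA potentiation
#'
#' `P_open = gamma_ratio / potentiation` where `potentiation` is the current
#' after MTSEA treatment divided by the current before (a ratio: 3.12 for
#' "312% of control") and `gamma_ratio` the post/pre single-channel
#' conductance ratio. A potentiation below `gamma_ratio` would imply
#' P_open > 1 and yields a clipped, flagged estimate.
#'
#' @param potentiation Current ratio after/before treatment (> 0).
#' @param gamma_ratio Conductance ratio in (0, 1.5]; default 0.70, the value
#'   consistent with the di-heteromeric WT calibration (open probability
#'   0.278 at 252% potentiation).
#' @return An `open_prob_estimate` list.
#' @export
popen_from_mtsea <- function(potentiation, gamma_ratio = 0.70) {
  stopifnot(potentiation > 0, gamma_ratio > 0, gamma_ratio <= 1.5)
  value <- gamma_ratio / potentiation
  clipped <- value > 1
  structure(list(value = min(value, 1), se = NA_real_, method = "MTSEA",
                 reference_popen = NA_real_, clipped = clipped),
            class = "open_prob_estimate")
}

#' Fold change between a reference and a test value
#'
#' Oriented so the fold is >= 1 when the change goes in the named direction
#' (`"decrease"`: reference/test; `"increase"`: test/reference). Reported to
#' 2 significant figures by the table formatters; returned at full
#' precision here.
#'
#' @param reference,test Positive values (e.g. group-mean EC50s or open
#'   probabilities).
#' @param direction `"decrease"` or `"increase"`.
#' @return The fold change (ratio).
#' @export
fold_change <- function(reference, test, direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(reference > 0, test > 0)
  if (direction == "decrease") reference / test else test / reference
}
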