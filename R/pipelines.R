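## Cohort-level wrappers: run the per-cell estimators over a simulated (or
## loaded) cohort and collect tidy per-cell tables, the way the analysis
## scripts and acceptance checks consume them.

baseline_window_of <- function(trace) {
  ep <- trace$protocol$epochs
  i <- which(ep$glutamate == 0)[1]
  if (is.na(i)) stop("protocol has no zero-agonist epoch for baselining")
  # no exchange artifact precedes the very first epoch; otherwise skip the
  # settling time, but never more than half the epoch
  skip <- if (i == 1) 0 else
    min(3 * trace$protocol$exchange_tau, 0.5 * ep$duration[i])
  c(ep$start[i] + skip, ep$start[i] + ep$duration[i])
}

#' Fit concentration-response curves across a cohort
#'
#' Baseline-corrects each cell's trace, extracts the concentration-response
#' series and runs the activation or inhibition fitter.
#'
#' @param cohort Output of [make_cohort()].
#' @param protocol_name Name of the protocol within each cell's trace list.
#' @param axis Series axis (see [extract_response_series()]).
#' @param max_mode Passed to [fit_activation()] (activation axes only).
#' @return A data.frame of per-cell fit fields plus `composition`.
#' @export
fit_cr_cohort <- function(cohort, protocol_name, axis,
                          max_mode = "fix_to_observed") {
  rows <- lapply(cohort, function(cell) {
    tr <- cell$traces[[protocol_name]]
    tr <- baseline_correct(tr, baseline_window_of(tr))
    ser <- extract_response_series(tr, axis)
    fit <- if (axis %in% c("glutamate", "glycine"))
      fit_activation(ser, max_mode) else fit_inhibition(ser)
    cbind(data.frame(composition = cell$cell$composition),
          as.data.frame(unclass(fit)[vapply(unclass(fit), function(x)
            length(x) == 1, logical(1))]))
  })
  do.call(rbind, rows)
}

#' Fit deactivation kinetics across a cohort
#'
#' @param cohort Output of [make_cohort()].
#' @param protocol_name Name of the pulse protocol in each cell's traces.
#' @return A data.frame of per-cell `deactivation_fit` fields plus
#'   `composition`.
#' @export
fit_deactivation_cohort <- function(cohort, protocol_name) {
  rows <- lapply(cohort, function(cell) {
    tr <- cell$traces[[protocol_name]]
    tr <- baseline_correct(tr, baseline_window_of(tr))
    ep <- tr$protocol$epochs
    pulse <- which(ep$glutamate > 0)[1]
    fit <- fit_deactivation(tr, ep$start[pulse] + ep$duration[pulse])
    cbind(data.frame(composition = cell$cell$composition),
          as.data.frame(unclass(fit)[vapply(unclass(fit), function(x)
            length(x) == 1, logical(1))]))
  })
  do.call(rbind, rows)
}

#' Fit MK-801 block onset across a cohort
#'
#' @param cohort Output of [make_cohort()].
#' @param protocol_name Name of the MK-801 protocol in each cell's traces.
#' @return A data.frame of per-cell `block_kinetics` fields plus
#'   `composition` and the onset rate `inv_tau_on_per_s` (s^-1), the unit
#'   block rates are reported in.
#' @export
fit_block_cohort <- function(cohort, protocol_name) {
  rows <- lapply(cohort, function(cell) {
    tr <- cell$traces[[protocol_name]]
    tr <- baseline_correct(tr, baseline_window_of(tr))
    ep <- tr$protocol$epochs
    fit <- fit_block_onset(tr, which(ep$mk801 > 0)[1])
    cbind(data.frame(composition = cell$cell$composition),
          as.data.frame(unclass(fit)[vapply(unclass(fit), function(x)
            length(x) == 1, logical(1))]))
  })
  out <- do.call(rbind, rows)
  out$inv_tau_on_per_s <- 1000 / out$tau_on
  out
}

#' Per-cell open-probability estimates from a cohort block-fit table
#'
#' Applies the relative MK-801 method cell by cell against a reference
#' cohort's mean association rate.
#'
#' @param block_df Per-cell table from [fit_block_cohort()] (test group).
#' @param block_df_ref Per-cell table for the reference (WT) group.
#' @param popen_ref Reference open probability.
#' @return `block_df` with columns `popen` and `popen_se` appended.
#' @export
popen_mk801_cohort <- function(block_df, block_df_ref, popen_ref = 0.278) {
  kon_ref <- mean(block_df_ref$k_on)
  conc_ref <- block_df_ref$blocker_concentration[1]
  ref <- block_kinetics(inv_tau_on = kon_ref * conc_ref,
                        blocker_concentration = conc_ref,
                        voltage = block_df_ref$voltage[1])
  ests <- lapply(seq_len(nrow(block_df)), function(i) {
    kin <- block_kinetics(inv_tau_on = 1 / block_df$tau_on[i],
                          blocker_concentration = block_df$blocker_concentration[i],
                          voltage = block_df$voltage[i],
                          se_inv_tau = if ("se_tau_on" %in% names(block_df))
                            block_df$se_tau_on[i] / block_df$tau_on[i]^2
                          else NA_real_)
    popen_from_mk801(kin, ref, popen_ref)
  })
  block_df$popen <- vapply(ests, function(e) e$value, numeric(1))
  block_df$popen_se <- vapply(ests, function(e) e$se, numeric(1))
  block_df
}
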