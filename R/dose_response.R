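## Concentration-response estimation: Hill activation fits (with the
## "predicted maximum" mode for unsaturable curves), inhibition fits with a
## residual minimum, and the scalar proton/zinc sensitivity statistics.

#' Build a concentration-response series
#'
#' @param cell_id Cell identifier.
#' @param axis One of `"glutamate"`, `"glycine"`, `"proton_activity"`,
#'   `"zinc"`, `"magnesium"`.
#' @param concentration Strictly increasing concentrations (axis units:
#'   uM, except proton_activity = hydrogen-ion activity and zinc = nM).
#' @param response Responses, signed pA for activation series or fraction of
#'   control for inhibition series; same length as `concentration`.
#' @param background_conditions Optional list describing co-applied
#'   concentrations.
#' @return An object of class `response_series`.
#' @export
response_series <- function(cell_id, axis, concentration, response,
                            background_conditions = list()) {
  axis <- match.arg(axis, c("glutamate", "glycine", "proton_activity",
                            "zinc", "magnesium"))
  if (length(concentration) != length(response) || length(concentration) < 4)
    stop("need >= 4 concentration/response pairs of equal length")
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  if (!all(is.finite(response))) stop("responses must be finite")
  structure(list(cell_id = as.character(cell_id), axis = axis,
                 concentration = concentration, response = response,
                 background_conditions = background_conditions),
            class = "response_series")
}

#' Extract a concentration-response series from a simulated/recorded trace
#'
#' Reads the per-epoch test concentrations from the protocol annotation and
#' measures the steady response in each. For inhibitor axes the responses
#' are normalized to the annotated control epoch (agonist present, zero
#' inhibitor; most-alkaline epoch for the proton axis) and returned as
#' fractions of control on the appropriate axis (hydrogen-ion activity for
#' protons).
#'
#' @param trace A baseline-corrected `nmda_trace`.
#' @param axis Series axis (see [response_series()]); `"proton"` is accepted
#'   as an alias for `"proton_activity"`.
#' @return A `response_series`.
#' @export
extract_response_series <- function(trace, axis) {
  if (axis == "proton") axis <- "proton_activity"
  ep <- trace$protocol$epochs
  agonist <- ep$glutamate > 0
  if (axis %in% c("glutamate", "glycine")) {
    rows <- which(if (axis == "glutamate") ep$glutamate > 0 else
                  agonist & ep$glycine >= 0)
    conc <- ep[[axis]][rows]
    resp <- vapply(rows, function(i) epoch_response(trace, i, "steady"),
                   numeric(1))
    o <- order(conc)
    response_series(trace$cell$cell_id, axis, conc[o], resp[o],
                    background_conditions = list(
                      glutamate = if (axis == "glycine") max(ep$glutamate),
                      glycine = if (axis == "glutamate") max(ep$glycine)))
  } else {
    inh_col <- switch(axis, proton_activity = "pH", zinc = "zinc",
                      magnesium = "magnesium")
    rows <- which(agonist)
    lev <- ep[[inh_col]][rows]
    if (axis == "proton_activity") {
      ctrl_row <- rows[which.max(lev)]
      test <- rows
      conc <- 10^(-ep$pH[test])
    } else {
      ctrl_row <- rows[which(lev == 0)[1]]
      test <- rows[lev > 0]
      conc <- ep[[inh_col]][test]
    }
    if (is.na(ctrl_row)) stop("no control (zero-inhibitor) epoch annotated")
    ctrl <- epoch_response(trace, ctrl_row, "steady")
    resp <- vapply(test, function(i) epoch_response(trace, i, "steady"),
                   numeric(1)) / ctrl
    o <- order(conc)
    response_series(trace$cell$cell_id, axis, conc[o], resp[o],
                    background_conditions = list(glutamate = max(ep$glutamate),
                                                 glycine = max(ep$glycine)))
  }
}

hill_pred <- function(conc, ec50, nh, rmax) rmax / (1 + (ec50 / conc)^nh)

#' Fit an activation concentration-response curve (Hill equation)
#'
#' Fits `Response = Rmax / (1 + (EC50/[agonist])^nH)` to the series by
#' least squares on the normalized response (percent of the largest
#' observed response). In `fix_to_observed` mode Rmax is fixed at 100%; in
#' `free_predicted` mode Rmax is a free "predicted maximum" parameter, the
#' mode required when the curve cannot be saturated experimentally (the
#' situation for low-potency variants where the largest testable agonist
#' concentration sits near the EC50). Deterministic multi-start
#' initialization: an EC50 grid over the observed concentration range
#' crossed with Hill slopes {0.8, 1.2, 1.6}; the best sum-of-squares start
#' wins.
#'
#' @param series A [response_series()] (activation axis, responses in
#'   signed pA of consistent sign).
#' @param max_mode `"fix_to_observed"` or `"free_predicted"`.
#' @return A `hill_fit` list: `ec50`, `n_h`, `r_max` (signed pA),
#'   `saturated` (largest observed response >= 95% of fitted maximum),
#'   `se_ec50`, `residual_rms` (pA), `converged`, `max_mode`, `cell_id`.
#' @export
fit_activation <- function(series, max_mode = c("fix_to_observed",
                                                "free_predicted")) {
  max_mode <- match.arg(max_mode)
  stopifnot(inherits(series, "response_series"))
  r <- series$response
  scale_pA <- max(abs(r))
  if (scale_pA == 0) stop("all responses are zero")
  sgn <- sign(r[which.max(abs(r))])
  # responses must share the dominant sign, up to baseline noise near zero
  if (any(sgn * r < -0.1 * scale_pA))
    stop("activation responses must share one sign")
  y <- 100 * (sgn * r) / scale_pA
  conc <- series$concentration
  rho <- stats::cor(conc, y, method = "spearman")
  if (is.na(rho) || rho < 0.8)
    stop("series is not monotone (Spearman rho < 0.8); refusing to fit")
  free_max <- max_mode == "free_predicted"
  starts <- expand.grid(
    lec = log(exp(seq(log(min(conc)), log(max(conc)), length.out = 7))),
    nh = c(0.8, 1.2, 1.6))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(lec = starts$lec[i], nh = starts$nh[i])
    if (free_max) st$lrmax <- log(120)
    fml <- if (free_max) y ~ hill_pred(conc, exp(lec), nh, exp(lrmax)) else
      y ~ hill_pred(conc, exp(lec), nh, exp(log(100)))
    fit <- robust_nlsLM(function(ctrl)
      minpack.lm::nlsLM(fml, start = st,
                        lower = c(lec = log(min(conc)) - 12, nh = 0.3,
                                  lrmax = log(1))[seq_along(st)],
                        upper = c(lec = log(max(conc)) + 12, nh = 4,
                                  lrmax = log(1e5))[seq_along(st)],
                        control = ctrl))
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(cell_id = series$cell_id, ec50 = NA_real_,
                          n_h = NA_real_, r_max = NA_real_, saturated = NA,
                          se_ec50 = NA_real_, residual_rms = NA_real_,
                          converged = FALSE, max_mode = max_mode),
                     class = "hill_fit"))
  }
  cf <- stats::coef(best$fit)
  ec50 <- exp(cf[["lec"]])
  rmax_pct <- if (free_max) exp(cf[["lrmax"]]) else 100
  se_lec <- tryCatch(sqrt(diag(stats::vcov(best$fit)))[["lec"]],
                     error = function(e) NA_real_)
  structure(list(
    cell_id = series$cell_id,
    ec50 = ec50,
    n_h = cf[["nh"]],
    r_max = sgn * rmax_pct / 100 * scale_pA,
    saturated = max(y) >= 0.95 * rmax_pct,
    se_ec50 = ec50 * se_lec,
    residual_rms = sqrt(best$sse / length(y)) / 100 * scale_pA,
    converged = TRUE, max_mode = max_mode), class = "hill_fit")
}

inhib_pred <- function(conc, ic50, nh, minimum)
  (1 - minimum) / (1 + (conc / ic50)^nh) + minimum

#' Fit an inhibition concentration-response curve
#'
#' Fits `Response = (1 - minimum) / (1 + ([inhibitor]/IC50)^nH) + minimum`
#' (response as fraction of the zero-inhibitor control) by least squares,
#' with `minimum` (the residual response at saturating inhibitor)
#' constrained to [0, 1). Same deterministic multi-start strategy as
#' [fit_activation()].
#'
#' @param series A [response_series()] on an inhibitor axis, responses as
#'   fractions of control.
#' @return An `inhibition_fit` list: `ic50`, `n_h`, `minimum`, `se_ic50`,
#'   `residual_rms`, `converged`, `cell_id`.
#' @export
fit_inhibition <- function(series) {
  stopifnot(inherits(series, "response_series"))
  y <- series$response
  conc <- series$concentration
  if (any(y < -0.2) || any(y > 1.5))
    stop("inhibition responses must be normalized fractions of control")
  rho <- stats::cor(conc, y, method = "spearman")
  if (is.na(rho) || rho > -0.8)
    stop("series is not monotonically inhibited (Spearman rho > -0.8)")
  starts <- expand.grid(
    lic = seq(log(min(conc)), log(max(conc)), length.out = 7),
    nh = c(0.8, 1.2, 1.6))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- robust_nlsLM(function(ctrl)
      minpack.lm::nlsLM(y ~ inhib_pred(conc, exp(lic), nh, minimum),
                        start = list(lic = starts$lic[i], nh = starts$nh[i],
                                     minimum = max(0, min(y))),
                        lower = c(lic = log(min(conc)) - 12, nh = 0.3,
                                  minimum = 0),
                        upper = c(lic = log(max(conc)) + 12, nh = 4,
                                  minimum = 0.999),
                        control = ctrl))
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    return(structure(list(cell_id = series$cell_id, ic50 = NA_real_,
                          n_h = NA_real_, minimum = NA_real_,
                          se_ic50 = NA_real_, residual_rms = NA_real_,
                          converged = FALSE), class = "inhibition_fit"))
  cf <- stats::coef(best$fit)
  ic50 <- exp(cf[["lic"]])
  se_lic <- tryCatch(sqrt(diag(stats::vcov(best$fit)))[["lic"]],
                     error = function(e) NA_real_)
  structure(list(cell_id = series$cell_id, ic50 = ic50, n_h = cf[["nh"]],
                 minimum = cf[["minimum"]], se_ic50 = ic50 * se_lic,
                 residual_rms = sqrt(best$sse / length(y)),
                 converged = TRUE), class = "inhibition_fit")
}

#' Convert pH to hydrogen-ion activity
#'
#' Proton inhibition curves are fitted on the hydrogen-ion-activity axis;
#' activity = `10^(-pH)`.
#'
#' @param pH pH value(s) in (0, 14).
#' @return Hydrogen-ion activity.
#' @export
ph_to_activity <- function(pH) {
  stopifnot(all(pH > 0 & pH < 14))
  10^(-pH)
}

#' Proton-sensitivity ratio statistic
#'
#' Percentage of current remaining at pH 6.8 relative to pH 7.6, measured in
#' the same cell under identical agonist conditions; smaller values mean
#' stronger proton inhibition.
#'
#' @param resp_pH68,resp_pH76 Signed currents (pA) at pH 6.8 and 7.6.
#' @param noise_floor Refuse when `|resp_pH76|` is below this (pA).
#' @return Percent (100 * response at pH 6.8 / response at pH 7.6).
#' @export
proton_ratio_statistic <- function(resp_pH68, resp_pH76, noise_floor = 1e-6) {
  if (abs(resp_pH76) < noise_floor)
    stop("pH 7.6 reference response is below the noise floor")
  100 * abs(resp_pH68) / abs(resp_pH76)
}

#' Maximal zinc inhibition at 300 nM
#'
#' Percent inhibition of the agonist-evoked current by 300 nM nominal free
#' zinc (tricine-buffered), relative to the zinc-free control in the same
#' cell.
#'
#' @param resp_300nM,resp_control Signed currents (pA).
#' @param noise_floor Refuse when `|resp_control|` is below this (pA).
#' @return Percent inhibition.
#' @export
zinc_max_inhibition <- function(resp_300nM, resp_control, noise_floor = 1e-6) {
  if (abs(resp_control) < noise_floor)
    stop("control response is below the noise floor")
  100 * (1 - abs(resp_300nM) / abs(resp_control))
}
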