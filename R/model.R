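## Kinetic gating model: 6-state scheme
##
##   R  <-> RA <-> RA2 <-> O  -> B   (B absorbing, entered only from O
##                  ^                 at k_block_mk * [MK-801])
##                  v
##                  D
##
## Two sequential glutamate bindings (statistical factors 2k_on, k_on on;
## k_off, 2k_off off), opening beta / closing alpha from the doubly-bound
## state, desensitization k_des / k_res from the doubly-bound state.
## Glycine, protons, zinc and magnesium act as instantaneous multiplicative
## factors on the macroscopic current (Hill forms), not as explicit states:
## only their steady-state inhibition/activation curves are analyzed here.

RATE_FIELDS <- c("k_on_glu", "k_off_glu", "beta", "alpha", "k_des", "k_res",
                 "k_block_mk")

#' Construct a receptor kinetic model
#'
#' Parameters of the 6-state gating scheme plus modulator sensitivities and
#' channel/conductance scaling. Rates are per ms (binding rates per uM per
#' ms); concentrations uM except zinc (nM).
#'
#' @param k_on_glu,k_off_glu Glutamate binding/unbinding rates.
#' @param beta,alpha Channel opening/closing rates (ms^-1).
#' @param k_des,k_res Desensitization entry/recovery rates (ms^-1).
#' @param k_block_mk MK-801 open-channel block rate (uM^-1 ms^-1),
#'   irreversible on the time scale of an experiment.
#' @param glycine_ec50,glycine_hill Glycine co-agonist activation (uM).
#' @param proton_ic50_pH,proton_hill Proton inhibition: pH of half-maximal
#'   inhibition and Hill slope on the hydrogen-ion-activity axis.
#' @param zinc_ic50,zinc_hill,zinc_residual Zinc inhibition (IC50 in nM) with
#'   a residual (uninhibited) fraction at saturating zinc.
#' @param mg_ic50_at_v,mg_v_ref,mg_v_slope Magnesium block: IC50 (uM) at the
#'   reference potential `mg_v_ref` (mV), e-folding `mg_v_slope` mV per
#'   e-fold relief with depolarization.
#' @param n_channels Number of channels in the cell.
#' @param gamma Single-channel chord conductance (pS).
#' @param v_rev Reversal potential (mV).
#' @param gamma_mtsea_ratio Conductance ratio gamma_MTSEA/gamma_control after
#'   MTSEA modification of GluN1(A652C) receptors.
#' @param popen_after_mtsea Open probability the channel is pinned to after
#'   MTSEA modification (1 = locked fully open).
#' @param locked_popen Internal: non-NULL pins the open probability to this
#'   value regardless of agonist (set by [apply_mtsea()]).
#' @param label Optional free-text label.
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(k_on_glu, k_off_glu, beta, alpha, k_des, k_res,
                          k_block_mk = 0.012,
                          glycine_ec50 = 1.1, glycine_hill = 1.4,
                          proton_ic50_pH = 6.8, proton_hill = 1.37,
                          zinc_ic50 = 87, zinc_hill = 1, zinc_residual = 0.54,
                          mg_ic50_at_v = 31, mg_v_ref = -60, mg_v_slope = 17,
                          n_channels = 3300, gamma = 50, v_rev = 0,
                          gamma_mtsea_ratio = 0.70, popen_after_mtsea = 1,
                          locked_popen = NULL, label = "") {
  m <- list(k_on_glu = k_on_glu, k_off_glu = k_off_glu, beta = beta,
            alpha = alpha, k_des = k_des, k_res = k_res,
            k_block_mk = k_block_mk, glycine_ec50 = glycine_ec50,
            glycine_hill = glycine_hill, proton_ic50_pH = proton_ic50_pH,
            proton_hill = proton_hill, zinc_ic50 = zinc_ic50,
            zinc_hill = zinc_hill, zinc_residual = zinc_residual,
            mg_ic50_at_v = mg_ic50_at_v, mg_v_ref = mg_v_ref,
            mg_v_slope = mg_v_slope, n_channels = n_channels, gamma = gamma,
            v_rev = v_rev, gamma_mtsea_ratio = gamma_mtsea_ratio,
            popen_after_mtsea = popen_after_mtsea,
            locked_popen = locked_popen, label = label)
  if (any(unlist(m[RATE_FIELDS]) < 0)) stop("all rates must be >= 0")
  if (m$zinc_residual <= 0 || m$zinc_residual > 1)
    stop("zinc_residual must be in (0, 1]")
  if (m$gamma_mtsea_ratio <= 0 || m$gamma_mtsea_ratio > 1.5)
    stop("gamma_mtsea_ratio must be in (0, 1.5]")
  if (m$popen_after_mtsea <= 0 || m$popen_after_mtsea > 1)
    stop("popen_after_mtsea must be in (0, 1]")
  structure(m, class = "kinetic_model")
}

#' Load a kinetic model from a JSON fixture
#'
#' @param path Path to a JSON document whose fields match the
#'   [kinetic_model()] arguments. Extra fields named `calibration_notes` or
#'   `calibration_targets` (documentation of how the fixture was calibrated)
#'   are ignored.
#' @return A `kinetic_model`.
#' @export
read_kinetic_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$calibration_notes <- NULL
  j$calibration_targets <- NULL
  do.call(kinetic_model, j)
}

#' Path to one of the calibrated example models shipped with the package
#'
#' @param name Fixture name, e.g. `"wt2A"`, `"d731n"`, `"wt2A2A"`,
#'   `"d731n_2a"`, `"d731n_d731n"`.
#' @return File path of the installed JSON fixture.
#' @export
model_fixture <- function(name) {
  p <- system.file("extdata", paste0(name, ".json"), package = "nmdarfx")
  if (p == "") stop("no fixture named '", name, "'")
  p
}

## Multiplicative modulator factors on the macroscopic current.
## pH = NA means "no proton inhibition modelled" (factor 1); glycine = Inf
## means saturating co-agonist.
modulator_factor <- function(model, glycine = Inf, pH = NA, zinc = 0,
                             mg = 0, V = -40) {
  f_gly <- ifelse(is.infinite(glycine), 1,
                  ifelse(glycine <= 0, 0,
                         1 / (1 + (model$glycine_ec50 / glycine)^model$glycine_hill)))
  a50 <- 10^(-model$proton_ic50_pH)
  f_h <- ifelse(is.na(pH), 1,
                1 / (1 + (10^(-pH) / a50)^model$proton_hill))
  f_zn <- ifelse(zinc <= 0, 1,
                 model$zinc_residual + (1 - model$zinc_residual) /
                   (1 + (zinc / model$zinc_ic50)^model$zinc_hill))
  ic50_v <- model$mg_ic50_at_v * exp((V - model$mg_v_ref) / model$mg_v_slope)
  f_mg <- ifelse(mg <= 0, 1, 1 / (1 + mg / ic50_v))
  f_gly * f_h * f_zn * f_mg
}

## Gating-only equilibrium open probability at glutamate concentration c
## (uM), excluding the absorbing blocked state. Closed form from detailed
## balance on the tree-shaped scheme:
##   P_O = B / ((1 + K/c)^2 + B + Dr),  B = beta/alpha, Dr = k_des/k_res,
##   K = k_off/k_on.
popen_gating <- function(model, glutamate) {
  if (!is.null(model$locked_popen))
    return(rep(model$locked_popen, length(glutamate)))
  p <- numeric(length(glutamate))
  if (model$beta == 0) return(p)
  pos <- which(glutamate > 0)
  if (model$alpha == 0) { # open state absorbs all bound weight
    p[pos] <- 1
    return(p)
  }
  Dr <- if (model$k_res > 0) model$k_des / model$k_res else
    if (model$k_des > 0) Inf else 0
  if (is.infinite(Dr)) return(p)
  B <- model$beta / model$alpha
  K <- if (model$k_on_glu > 0) model$k_off_glu / model$k_on_glu else Inf
  p[pos] <- B / ((1 + K / glutamate[pos])^2 + B + Dr)
  p
}

#' Equilibrium open probability under stated conditions
#'
#' Closed-form stationary open probability of the gating scheme (blocked
#' state excluded), multiplied by the instantaneous modulator factors for
#' glycine, protons, zinc and magnesium.
#'
#' @param model A `kinetic_model`.
#' @param glutamate Glutamate (uM).
#' @param glycine Glycine (uM); `Inf` (default) = saturating.
#' @param pH Solution pH; `NA` (default) disables proton inhibition.
#' @param zinc Free zinc (nM).
#' @param mg Magnesium (uM).
#' @param V Membrane potential (mV), used for the voltage dependence of
#'   magnesium block.
#' @return Open probability in \[0, 1\] (vectorized over `glutamate`).
#' @export
equilibrium_open_prob <- function(model, glutamate, glycine = Inf, pH = NA,
                                  zinc = 0, mg = 0, V = -40) {
  popen_gating(model, glutamate) *
    modulator_factor(model, glycine, pH, zinc, mg, V)
}

#' Apparent agonist EC50 of a kinetic model
#'
#' Finds, by bisection on the closed-form equilibrium response, the agonist
#' concentration producing half the saturating response. For the glutamate
#' axis the response is the gating-only open probability; for the glycine
#' axis it is the response at saturating glutamate as glycine varies.
#'
#' @param model A `kinetic_model`.
#' @param axis `"glutamate"` or `"glycine"`.
#' @param rel_tol Relative tolerance of the bisection (default 1e-6).
#' @return EC50 (uM).
#' @export
apparent_ec50 <- function(model, axis = c("glutamate", "glycine"),
                          rel_tol = 1e-6) {
  axis <- match.arg(axis)
  resp <- switch(axis,
    glutamate = function(c) popen_gating(model, c),
    glycine = function(c) popen_gating(model, Inf) *
                          modulator_factor(model, glycine = c))
  sat <- resp(Inf)
  if (sat <= 0) stop("model has no response on this axis")
  probe <- resp(10^seq(-6, 8, length.out = 60))
  if (any(diff(probe) < -1e-9 * sat))
    stop("response curve is not monotone on this axis")
  f <- function(lc) resp(exp(lc)) - sat / 2
  lo <- log(1e-9); while (f(lo) > 0) lo <- lo - 5
  hi <- log(10); while (f(hi) < 0 && hi < log(1e18)) hi <- hi + 5
  exp(stats::uniroot(f, c(lo, hi), tol = rel_tol / 4)$root)
}

#' Apply MTSEA modification to a model
#'
#' MTSEA covalently modifies GluN1(A652C)-containing receptors, locking the
#' channel at open probability `popen_after_mtsea` (1 = fully locked open)
#' with conductance scaled by `gamma_mtsea_ratio`. By construction the
#' simulated potentiation (current after / current before) equals
#' `gamma_mtsea_ratio * popen_after_mtsea / P_open(before)`, so the
#' conductance-ratio inversion of potentiation recovers the pre-treatment
#' open probability exactly when `popen_after_mtsea = 1`.
#'
#' @param model A `kinetic_model`.
#' @return The modified `kinetic_model`.
#' @export
apply_mtsea <- function(model) {
  model$gamma <- model$gamma * model$gamma_mtsea_ratio
  model$locked_popen <- model$popen_after_mtsea
  model
}

#' Mixture of receptor populations in one cell
#'
#' Macroscopic current of a mixture is the fraction-weighted sum of the
#' component currents. An optional contaminant population (e.g. escape of
#' non-triheteromeric receptors from ER retention in tri-heteromeric
#' experiments) can be carried with its own small fraction.
#'
#' @param components List of `kinetic_model`s.
#' @param fractions Non-negative weights summing to 1.
#' @param contaminant Optional `kinetic_model` for the contaminating
#'   population.
#' @param contamination_fraction Fraction of total current carried by the
#'   contaminant; must be < 0.03.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(components, fractions, contaminant = NULL,
                          contamination_fraction = 0) {
  stopifnot(length(components) == length(fractions), all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (contamination_fraction < 0 || contamination_fraction >= 0.03)
    stop("contamination_fraction must be in [0, 0.03)")
  if (contamination_fraction > 0 && is.null(contaminant))
    stop("contamination_fraction > 0 requires a contaminant model")
  structure(list(components = components, fractions = fractions,
                 contaminant = contaminant,
                 contamination_fraction = contamination_fraction),
            class = "mixture_model")
}
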