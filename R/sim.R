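## ODE simulation of the 6-state scheme under a solution-exchange protocol.
##
## Nominal solution compositions are piecewise-constant per epoch; the
## concentration actually seen by the receptors relaxes first-order toward
## the nominal value with the protocol's exchange_tau (closed form within
## each epoch). Protons are exchanged on the hydrogen-ion-activity scale.
## Holding potential switches instantaneously at epoch boundaries.

EXCHANGED_FIELDS <- c("glutamate", "glycine", "mk801", "zinc", "magnesium",
                      "h_activity")

## Per-epoch filtered-concentration bookkeeping: for each exchanged field,
## the value at the start of each epoch (after filtering through all
## previous epochs). Returns a list with target and start matrices.
exchange_plan <- function(protocol) {
  ep <- protocol$epochs
  n <- nrow(ep)
  tgt <- cbind(glutamate = ep$glutamate, glycine = ep$glycine,
               mk801 = ep$mk801, zinc = ep$zinc, magnesium = ep$magnesium,
               h_activity = 10^(-ep$pH))
  start <- tgt
  if (n > 1 && protocol$exchange_tau > 0) {
    for (i in 2:n) {
      decay <- exp(-ep$duration[i - 1] / protocol$exchange_tau)
      start[i, ] <- tgt[i - 1, ] + (start[i - 1, ] - tgt[i - 1, ]) * decay
    }
  }
  list(target = tgt, start = start)
}

## Filtered concentration of one field at times t inside epoch i.
conc_in_epoch <- function(plan, protocol, i, field, t) {
  t0 <- protocol$epochs$start[i]
  tau <- protocol$exchange_tau
  tgt <- plan$target[i, field]
  st <- plan$start[i, field]
  if (tau <= 0) rep(tgt, length(t))
  else tgt + (st - tgt) * exp(-(t - t0) / tau)
}

deriv_6state <- function(t, y, parms) {
  c_glu <- parms$tgt_glu + parms$d_glu * exp(-(t - parms$t0) * parms$inv_tau)
  c_mk <- parms$tgt_mk + parms$d_mk * exp(-(t - parms$t0) * parms$inv_tau)
  m <- parms$m
  b1 <- 2 * m$k_on_glu * c_glu
  b2 <- m$k_on_glu * c_glu
  u1 <- m$k_off_glu
  u2 <- 2 * m$k_off_glu
  kb <- m$k_block_mk * c_mk
  R <- y[1]; RA <- y[2]; RA2 <- y[3]; O <- y[4]; D <- y[5]
  dR <- -b1 * R + u1 * RA
  dRA <- b1 * R - (u1 + b2) * RA + u2 * RA2
  dRA2 <- b2 * RA - (u2 + m$beta + m$k_des) * RA2 + m$alpha * O + m$k_res * D
  dO <- m$beta * RA2 - (m$alpha + kb) * O
  dD <- m$k_des * RA2 - m$k_res * D
  dB <- kb * O
  list(c(dR, dRA, dRA2, dO, dD, dB))
}

## Open-state occupancy over the trace time grid for one kinetic model.
## Integrates epoch by epoch so concentration-derivative discontinuities at
## epoch boundaries never cross a solver step.
solve_open_occupancy <- function(model, protocol, times, rtol = 1e-8) {
  if (!is.null(model$locked_popen))
    return(rep(model$locked_popen, length(times)))
  plan <- exchange_plan(protocol)
  ep <- protocol$epochs
  inv_tau <- if (protocol$exchange_tau > 0) 1 / protocol$exchange_tau else 0
  y <- c(1, 0, 0, 0, 0, 0)
  open_occ <- numeric(length(times))
  for (i in seq_len(nrow(ep))) {
    t0 <- ep$start[i]
    t1 <- t0 + ep$duration[i]
    last <- i == nrow(ep)
    idx <- which(times >= t0 - 1e-9 & (if (last) times <= t1 + 1e-9
                                       else times < t1 - 1e-9))
    tt <- unique(c(t0, times[idx], t1))
    parms <- list(m = model, t0 = t0, inv_tau = inv_tau,
                  tgt_glu = plan$target[i, "glutamate"],
                  d_glu = if (inv_tau > 0)
                    plan$start[i, "glutamate"] - plan$target[i, "glutamate"] else 0,
                  tgt_mk = plan$target[i, "mk801"],
                  d_mk = if (inv_tau > 0)
                    plan$start[i, "mk801"] - plan$target[i, "mk801"] else 0)
    sol <- deSolve::lsoda(y, tt, deriv_6state, parms, rtol = rtol, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0) stop("ODE solver failed in epoch ", i)
    tot <- rowSums(sol[, 2:7])
    if (any(abs(tot - 1) > 1e-6))
      stop("occupancy conservation violated beyond tolerance")
    if (length(idx) > 0)
      open_occ[idx] <- sol[match(times[idx], tt), 5]
    y <- pmax(sol[nrow(sol), 2:7], 0)
    y <- y / sum(y)
  }
  open_occ
}

## Modulator factor time course over the trace grid (filtered concentrations).
modulator_time_course <- function(model, protocol, times) {
  plan <- exchange_plan(protocol)
  ep <- protocol$epochs
  f <- numeric(length(times))
  V <- numeric(length(times))
  for (i in seq_len(nrow(ep))) {
    t0 <- ep$start[i]
    t1 <- t0 + ep$duration[i]
    last <- i == nrow(ep)
    idx <- which(times >= t0 - 1e-9 & (if (last) times <= t1 + 1e-9
                                       else times < t1 - 1e-9))
    if (length(idx) == 0) next
    tt <- times[idx]
    gly <- conc_in_epoch(plan, protocol, i, "glycine", tt)
    ha <- conc_in_epoch(plan, protocol, i, "h_activity", tt)
    zn <- conc_in_epoch(plan, protocol, i, "zinc", tt)
    mg <- conc_in_epoch(plan, protocol, i, "magnesium", tt)
    v <- ep$holding_potential[i]
    f[idx] <- modulator_factor(model, glycine = gly, pH = -log10(ha),
                               zinc = zn, mg = mg, V = v)
    V[idx] <- v
  }
  list(f = f, V = V)
}

#' Simulate a voltage-clamp current trace
#'
#' Deterministic macroscopic current from the 6-state gating scheme (or a
#' fraction-weighted mixture of schemes) under a solution-exchange protocol:
#' `I(t) = 1e-3 * n_channels * gamma * (V - v_rev) * P_O(t) * f_mod(t)`
#' in pA (inward negative at negative potentials), plus optional additive
#' Gaussian noise. The ODE is solved to relative tolerance 1e-8; with a
#' fixed seed the output is reproducible bit-for-bit.
#'
#' @param model A `kinetic_model` or `mixture_model`.
#' @param protocol An [protocol()] object.
#' @param meta A [cell_meta()] object.
#' @param noise_sd Gaussian noise SD (pA); 0 for noiseless traces.
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @param sample_interval Output sampling interval (ms).
#' @return An `nmda_trace` with `ground_truth` set to `model`.
#' @export
simulate_current <- function(model, protocol, meta, noise_sd = 0, seed = 1L,
                             sample_interval = 0.2) {
  t_lo <- protocol$epochs$start[1]
  t_hi <- protocol_end(protocol)
  times <- seq(t_lo, t_hi, by = sample_interval)
  comps <- if (inherits(model, "mixture_model")) {
    w <- model$fractions * (1 - model$contamination_fraction)
    mods <- model$components
    if (model$contamination_fraction > 0) {
      w <- c(w, model$contamination_fraction)
      mods <- c(mods, list(model$contaminant))
    }
    list(models = mods, weights = w)
  } else list(models = list(model), weights = 1)
  current <- numeric(length(times))
  for (k in seq_along(comps$models)) {
    m <- comps$models[[k]]
    occ <- solve_open_occupancy(m, protocol, times)
    mtc <- modulator_time_course(m, protocol, times)
    current <- current + comps$weights[k] * 1e-3 * m$n_channels * m$gamma *
      (mtc$V - m$v_rev) * occ * mtc$f
  }
  if (noise_sd > 0)
    current <- current +
      withr::with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  new_trace(times, current, protocol, meta, ground_truth = model)
}

#' Cohort simulation configuration
#'
#' Defines how a synthetic cohort of cells is drawn around a kinetic model.
#' Between-cell variability has three log-normal components, chosen to
#' emulate the variance structure of real recordings: a shared "tempo"
#' multiplier applied to every kinetic rate of a cell (which rescales time
#' constants but leaves equilibrium ratios such as EC50, open probability
#' and Iss/Ipeak unchanged), an independent per-rate jitter (which perturbs
#' those equilibrium quantities), and an expression multiplier on
#' `n_channels` (which only scales amplitude).
#'
#' @param model A `kinetic_model` or `mixture_model`.
#' @param protocols Named list of [protocol()] objects; every cell is
#'   simulated under each.
#' @param n_cells Number of cells (>= 1).
#' @param cv_between_cells CV of the independent per-rate jitter.
#' @param cv_tempo CV of the shared kinetic-tempo multiplier.
#' @param cv_channels CV of the expression (`n_channels`) multiplier.
#' @param noise_sd Additive recording noise SD (pA).
#' @param seed Integer seed; makes the whole cohort reproducible.
#' @param meta_template A [cell_meta()] whose fields (preparation,
#'   composition, capacitance, holding potential) are copied to each cell.
#' @param sample_interval Output sampling interval (ms).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(model, protocols, n_cells, cv_between_cells = 0.05,
                          cv_tempo = 0, cv_channels = NULL, noise_sd = 0,
                          seed = 1L, meta_template = NULL,
                          sample_interval = 0.2) {
  stopifnot(n_cells >= 1, cv_between_cells >= 0, cv_tempo >= 0, noise_sd >= 0)
  if (is.null(cv_channels)) cv_channels <- cv_between_cells
  if (is.null(meta_template))
    meta_template <- cell_meta("template", "oocyte")
  if (is.null(names(protocols)) || any(names(protocols) == ""))
    stop("protocols must be a named list")
  structure(list(model = model, protocols = protocols, n_cells = n_cells,
                 cv_between_cells = cv_between_cells, cv_tempo = cv_tempo,
                 cv_channels = cv_channels, noise_sd = noise_sd,
                 seed = as.integer(seed), meta_template = meta_template,
                 sample_interval = sample_interval),
            class = "cohort_config")
}

lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

perturb_model <- function(model, tempo, jitter, ch_mult) {
  for (i in seq_along(RATE_FIELDS))
    model[[RATE_FIELDS[i]]] <- model[[RATE_FIELDS[i]]] * tempo * jitter[i]
  model$n_channels <- model$n_channels * ch_mult
  model
}

#' Simulate a cohort of cells
#'
#' Draws per-cell parameter multipliers (see [cohort_config()]) and
#' simulates every protocol in the configuration for every cell. Fully
#' reproducible from `config$seed`; each trace records its own perturbed
#' generating model as `ground_truth`.
#'
#' @param config A [cohort_config()].
#' @return A list with one element per cell: `list(cell, model, traces)`
#'   where `traces` is a named list parallel to `config$protocols`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cells
  draws <- withr::with_seed(config$seed, list(
    tempo = lognorm_mult(n, config$cv_tempo),
    jitter = matrix(lognorm_mult(n * length(RATE_FIELDS),
                                 config$cv_between_cells),
                    nrow = n),
    channels = lognorm_mult(n, config$cv_channels),
    noise_seeds = sample.int(2^30, n)
  ))
  lapply(seq_len(n), function(i) {
    pm <- if (inherits(config$model, "mixture_model")) {
      mm <- config$model
      mm$components <- lapply(mm$components, perturb_model,
                              tempo = draws$tempo[i],
                              jitter = draws$jitter[i, ],
                              ch_mult = draws$channels[i])
      if (!is.null(mm$contaminant))
        mm$contaminant <- perturb_model(mm$contaminant, draws$tempo[i],
                                        draws$jitter[i, ], draws$channels[i])
      mm
    } else {
      perturb_model(config$model, draws$tempo[i], draws$jitter[i, ],
                    draws$channels[i])
    }
    meta <- config$meta_template
    meta$cell_id <- sprintf("%s_cell%02d", meta$cell_id, i)
    traces <- lapply(config$protocols, function(p)
      simulate_current(pm, p, meta, noise_sd = config$noise_sd,
                       seed = draws$noise_seeds[i],
                       sample_interval = config$sample_interval))
    list(cell = meta, model = pm, traces = traces)
  })
}
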