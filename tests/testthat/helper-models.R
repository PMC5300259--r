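# Shared builders for test models, protocols and synthetic series.

# Fast-relaxing model for ODE-vs-closed-form checks (all rates well above
# the protocol time scales).
quick_model <- function(...) {
  args <- utils::modifyList(
    list(k_on_glu = 0.01, k_off_glu = 0.05, beta = 0.3, alpha = 0.3,
         k_des = 0.01, k_res = 0.01, k_block_mk = 0.01,
         n_channels = 1000, gamma = 50),
    list(...))
  do.call(kinetic_model, args)
}

random_model <- function() {
  kinetic_model(
    k_on_glu = stats::runif(1, 0.001, 0.02),
    k_off_glu = stats::runif(1, 0.01, 0.1),
    beta = stats::runif(1, 0.05, 0.5),
    alpha = stats::runif(1, 0.05, 0.5),
    k_des = stats::runif(1, 0.001, 0.02),
    k_res = stats::runif(1, 0.002, 0.02),
    n_channels = 1000)
}

oocyte_meta <- function(composition = "WT2A", id = "oo1")
  cell_meta(id, "oocyte", composition)

hek_meta <- function(composition = "WT2A", id = "hk1", cap = 20)
  cell_meta(id, "HEK", composition, capacitance = cap,
            holding_potential_default = -60)

# Simple two-epoch protocol: baseline then one test epoch.
step_protocol <- function(glutamate = 1000, duration = 2000,
                          baseline = 500, exchange_tau = 0.5, ...)
  protocol(rbind(
    epoch(0, baseline, ...),
    epoch(baseline, duration, glutamate = glutamate, glycine = 100, ...)),
    exchange_tau = exchange_tau)

# Ideal square-pulse trace (no kinetics), for measurement-layer tests.
square_trace <- function(amp = -100, baseline = 500, duration = 2000,
                         si = 1, offset = 0) {
  p <- step_protocol(duration = duration, baseline = baseline,
                     exchange_tau = 0.1)
  tt <- seq(0, baseline + duration, by = si)
  cur <- ifelse(tt >= baseline, amp, 0) + offset
  new_trace(tt, cur, p, oocyte_meta())
}

# Exact Hill activation series (responses in pA, inward negative).
hill_series <- function(ec50, nh, conc, rmax_pA = -1000, noise_sd = 0,
                        cell_id = "syn") {
  y <- rmax_pA / (1 + (ec50 / conc)^nh)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  response_series(cell_id, "glutamate", conc, y)
}

inhib_series <- function(ic50, nh, minimum, conc, noise_sd = 0,
                         axis = "zinc", cell_id = "syn") {
  y <- (1 - minimum) / (1 + (conc / ic50)^nh) + minimum
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  response_series(cell_id, axis, conc, y)
}

# Pure bi-exponential decay trace over a pulse protocol (instant rise),
# for deactivation-fitter self-consistency tests.
biexp_trace <- function(a_f = -80, tau_f = 41, a_s = -20, tau_s = 384,
                        si = 0.5, post = 2500, noise_sd = 0) {
  p <- protocol(rbind(
    epoch(0, 100, glycine = 100, holding_potential = -60),
    epoch(100, 200, glutamate = 30000, glycine = 100,
          holding_potential = -60),
    epoch(300, post, glycine = 100, holding_potential = -60)),
    exchange_tau = 1e-6)
  tt <- seq(0, 300 + post, by = si)
  cur <- numeric(length(tt))
  on <- tt >= 100 & tt < 300
  cur[on] <- a_f + a_s
  dec <- tt >= 300
  td <- tt[dec] - 300
  cur[dec] <- a_f * exp(-td / tau_f) + a_s * exp(-td / tau_s)
  if (noise_sd > 0) cur <- cur + stats::rnorm(length(cur), 0, noise_sd)
  new_trace(tt, cur, p, hek_meta())
}

# Exponential-plus-plateau block trace at steady agonist.
block_trace <- function(tau_on = 3000, plateau = 0, amp = -500, mk = 0.2,
                        si = 20, block_dur = 15000, noise_sd = 0) {
  p <- protocol(rbind(
    epoch(0, 1000, holding_potential = -40),
    epoch(1000, 2000, glutamate = 10, glycine = 100,
          holding_potential = -40),
    epoch(3000, block_dur, glutamate = 10, glycine = 100, mk801 = mk,
          holding_potential = -40)),
    exchange_tau = 1e-6)
  tt <- seq(0, 3000 + block_dur, by = si)
  cur <- numeric(length(tt))
  cur[tt >= 1000] <- amp + plateau
  blk <- tt >= 3000
  cur[blk] <- plateau + amp * exp(-(tt[blk] - 3000) / tau_on)
  if (noise_sd > 0) cur <- cur + stats::rnorm(length(cur), 0, noise_sd)
  new_trace(tt, cur, p, oocyte_meta())
}
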