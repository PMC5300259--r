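# Independent brute-force oracles for the nonlinear fitters: dense grid
# search over the nonlinear parameters with exact linear least squares for
# the parameters the model is linear in. These share no code with the
# package fitters.

oracle_hill_sse <- function(conc, y, free_max = FALSE, n_grid = 140) {
  lec <- seq(log(min(conc)) - 3, log(max(conc)) + 3, length.out = n_grid)
  nh <- seq(0.3, 4, length.out = 75)
  best <- Inf
  for (le in lec) {
    g <- outer(conc, nh, function(cc, h) 1 / (1 + (exp(le) / cc)^h))
    if (free_max) {
      # rmax solved linearly per nh column
      num <- colSums(g * y); den <- colSums(g * g)
      rmax <- ifelse(den > 0, num / den, 0)
      sse <- colSums((y - sweep(g, 2, rmax, "*"))^2)
    } else {
      sse <- colSums((y - 100 * g)^2)
    }
    best <- min(best, min(sse))
  }
  best
}

oracle_inhib_sse <- function(conc, y, n_grid = 140) {
  lic <- seq(log(min(conc)) - 3, log(max(conc)) + 3, length.out = n_grid)
  nh <- seq(0.3, 4, length.out = 75)
  best <- Inf
  for (li in lic) {
    g <- outer(conc, nh, function(cc, h) 1 / (1 + (cc / exp(li))^h))
    # model: y = g + minimum * (1 - g); minimum linear, clipped to [0, 1)
    r <- y - g
    b <- 1 - g
    num <- colSums(r * b); den <- colSums(b * b)
    mn <- pmin(pmax(ifelse(den > 0, num / den, 0), 0), 0.999)
    sse <- colSums((r - sweep(b, 2, mn, "*"))^2)
    best <- min(best, min(sse))
  }
  best
}

oracle_biexp_sse <- function(t, y, n_grid = 70) {
  t0 <- t - min(t)
  span <- max(t0)
  taus <- 10^seq(log10(span / 1000), log10(span * 3), length.out = n_grid)
  E <- sapply(taus, function(tau) exp(-t0 / tau))
  best <- Inf
  for (i in seq_len(n_grid - 1)) for (j in (i + 1):n_grid) {
    X <- cbind(E[, i], E[, j])
    cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
    if (is.null(cf)) next
    sse <- sum((y - X %*% cf)^2)
    if (sse < best) best <- sse
  }
  best
}

oracle_exp_plateau_sse <- function(t, y, n_grid = 200) {
  t0 <- t - min(t)
  span <- max(t0)
  taus <- 10^seq(log10(span / 500), log10(span * 3), length.out = n_grid)
  best <- Inf
  for (tau in taus) {
    X <- cbind(1, exp(-t0 / tau))
    cf <- qr.solve(crossprod(X), crossprod(X, y))
    sse <- sum((y - X %*% cf)^2)
    if (sse < best) best <- sse
  }
  best
}

# Closed-form equilibrium quantities of the 6-state scheme, derived
# independently of the package internals.
scheme_popen_max <- function(m) {
  B <- m$beta / m$alpha
  Dr <- m$k_des / m$k_res
  B / (1 + B + Dr)
}
scheme_ec50 <- function(m) {
  B <- m$beta / m$alpha
  Dr <- m$k_des / m$k_res
  (m$k_off_glu / m$k_on_glu) / (sqrt(2 + B + Dr) - 1)
}
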