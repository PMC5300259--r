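---
title: "Methods: receptor model, estimators and synthetic-data design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor model, estimators and synthetic-data design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdarfx)
```

`nmdarfx` implements the functional-characterization workflow used to
assess disease-associated NMDA receptor variants from voltage-clamp
recordings: agonist concentration–response curves, negative-allosteric-
modulator sensitivity, synaptic-like response kinetics, and relative
channel open probability. Because raw recordings for such studies are
rarely deposited, the package also contains a mechanistic receptor
simulator that generates annotated current traces under arbitrary
solution-exchange protocols, so that every estimator can be validated
against known ground truth. This vignette documents the model, the
estimators, the numerical choices, and what the synthetic data do and do
not establish.

## The gating scheme

The simulator uses the minimal Markov scheme that supports every measured
phenomenon — two sequential glutamate binding steps, opening, macroscopic
desensitization, and irreversible open-channel block:

```
        2·k_on·[glu]     k_on·[glu]        beta         k_block·[MK801]
    R  ============  RA  ==========  RA2  ======  O  ------------------>  B
        k_off            2·k_off           alpha
                                     RA2  ======  D
                                          k_des / k_res
```

All rates are per millisecond (binding per µM per ms). Because the
unblocked scheme is a tree, detailed balance gives the stationary open
probability in closed form,

$$P_O(c) \;=\; \frac{B}{(1 + K/c)^2 + B + D_r},
\qquad B = \beta/\alpha,\; D_r = k_{des}/k_{res},\; K = k_{off}/k_{on},$$

from which the saturating open probability is $B/(1+B+D_r)$, the
equilibrium steady/peak ratio is $(1+B)/(1+B+D_r)$, and the half-maximal
concentration is $K/(\sqrt{2+B+D_r}-1)$. These closed forms are the
package's analytic oracles: the ODE solution is required to agree with
them to 1e-6 in the test suite.

Glycine co-agonism and inhibition by protons, zinc and magnesium are
modelled as instantaneous multiplicative Hill-form factors on the
macroscopic current rather than as explicit states, because only their
steady-state concentration–response relations are analyzed; explicit
modulator kinetics would be unidentifiable from such data. Magnesium
block carries a voltage dependence (e-fold per `mg_v_slope` mV relative
to a reference potential); zinc inhibition has a residual (uninhibited)
floor. MK-801 block is treated as irreversible on the experimental time
scale, the assumption under which its onset rate is proportional to open
probability.

Macroscopic current is
$I(t) = 10^{-3}\, n\, \gamma\, (V - V_{rev})\, P_O(t)\, f_{gly} f_H f_{Zn} f_{Mg}$
in pA — inward-negative at negative potentials. Traces store signed
current; summary tables report magnitudes, and densities are per pF of
cell capacitance (HEK cells only; oocyte currents are never normalized).

Nominal solution compositions are piecewise-constant per protocol epoch;
the concentration at the membrane relaxes first-order toward the nominal
value with the protocol's `exchange_tau` (0.5 ms default for theta-tube
rapid perfusion, ~2 s for oocyte bath exchange). Protons are exchanged on
the hydrogen-ion-activity scale. The ODE is integrated epoch-by-epoch
with `deSolve::lsoda` at relative tolerance 1e-8, so concentration-
derivative discontinuities never cross a solver step; occupancy
conservation is enforced to 1e-6.

## Estimators

**Concentration–response (activation).** Per-cell steady responses (mean
of the last 20% of each epoch) are normalized to the largest observed
response and fitted with the Hill equation by Levenberg–Marquardt least
squares in log-EC50 space. Initialization is a deterministic multi-start:
a 7-point EC50 grid across the observed concentration range crossed with
Hill slopes {0.8, 1.2, 1.6}; the start with the lowest sum of squares
wins, making fits exactly reproducible. Two maximum conventions are
provided: `fix_to_observed` pins the maximum at the largest observed
response (appropriate for saturable curves), while `free_predicted`
treats the maximum as a free "predicted" parameter — the convention
required for low-potency variants whose curves cannot be saturated
experimentally. A fit is refused when the series is not monotone
(Spearman rho < 0.8), and a `saturated` flag records whether the largest
observed response reached 95% of the fitted maximum.

Two biases of these conventions are documented and demonstrated in the
test suite rather than hidden. First, `fix_to_observed` on a truncated
curve systematically underestimates the EC50. Second, even
`free_predicted` is an *operational* estimate when the underlying
response is not exactly Hill-shaped: the two-sequential-binding curve of
the gating scheme approaches saturation more slowly than any Hill curve,
so on data truncated near 2× the EC50 the fitted predicted maximum is
low and the Hill EC50 lands roughly 20% below the mechanistic half-max
(10.9 mM versus 13.7 mM for the low-potency mutant fixture, noiselessly).
For this reason the recovery checks compare cohort estimates against the
same estimator applied to the same cells' noiseless curves — the
estimator must recover its own operational target; the offset between
the operational and mechanistic quantity is a property of the printed-
convention Hill fit, not noise.

**Concentration–response (inhibition).** Responses are normalized to the
annotated zero-inhibitor control epoch in the same cell (never inferred),
and fitted with a Hill inhibition curve with a residual `minimum`
constrained to [0, 1). Proton curves are fitted on the hydrogen-ion
activity axis ($a = 10^{-pH}$). Two scalar statistics mirror common
reporting conventions: the percentage of current remaining at pH 6.8
relative to pH 7.6, and the percent inhibition by 300 nM nominal free
zinc.

**Deactivation.** After rapid agonist removal the current is fitted with
a two-component exponential. Amplitudes are referenced to the removal
time; the fit window starts 3×`exchange_tau` later to exclude exchange
artifacts. Initialization solves the amplitudes linearly on a
decade-spaced grid of time-constant pairs (the model is linear in the
amplitudes), then refines by Levenberg–Marquardt; ties are resolved
deterministically. The weighted time constant uses amplitude-fraction
weights, `tau_w = %fast·tau_fast + %slow·tau_slow`. Degenerate fits
(time constants within 5%, or opposite-sign amplitudes) collapse to a
flagged single exponential with `amp_slow = 0`. The report also carries
the 10–90% rise time (linear interpolation between samples), Iss/Ipeak,
peak and steady-state densities, and the charge transfer as the product
`peak_density × tau_w` — the instant-rise/exponential-decay
approximation of the response integral — with a numerically integrated
decay as a cross-check column. Charge transfer is always computed per
cell and then averaged, since the product of group means differs from
the mean of per-cell products.

**MK-801 block onset.** The current decline under blocker co-application
is fitted with a single exponential plus an additive plateau. The printed
form of this fit has no plateau; the extra parameter is reported
separately (the fit reduces to the pure exponential when it is zero) and
makes the estimator robust to small residual currents. The microscopic
association rate is `k_on = 1/(tau_on·[MK801])`. Reported onset rates
use the s⁻¹ scale (a 0.2 µM block proceeds with a time constant of
seconds).

**Open probability.** Two routes: (i) relative MK-801 kinetics,
`P_open(test) = P_open(ref) · k_on(test)/k_on(ref)`, with reference
anchors 0.278 (di-heteromeric wild type) and 0.370 (tri-heteromeric
wild-type control) supplied as configuration inputs, SEs propagated by
the delta method, and refusal when blocker concentration or holding
potential differ between test and reference; (ii) MTSEA potentiation of
GluN1(A652C)-containing receptors, `P_open = γ-ratio / potentiation`,
with the conductance ratio defaulting to 0.70 — the value consistent
with a 0.278 open probability producing 252% potentiation. In the
simulator, MTSEA modification pins the channel at `popen_after_mtsea`
(default 1, fully locked open) with conductance scaled by the γ-ratio;
by construction the inversion is exact when the lock is complete, and
biased by exactly `1/popen_after_mtsea` otherwise. Because potentiation
is a within-cell current ratio, every multiplicative modulator factor
cancels, so the method recovers the gating-only open probability at the
test agonist concentration. Estimates above 1 are clipped and flagged.

**Statistics.** Group summaries are mean ± SEM with n = cells. Two-group
comparisons use the unequal-variance (Welch) two-tailed t test — the
variant is switchable to pooled-variance, since reports often leave it
unstated — and multi-group comparisons use one-way ANOVA with post hoc
Tukey HSD, α = 0.05, with no correction across distinct parameters.

## The synthetic cohorts: what they emulate

Between-cell variability uses three log-normal components, chosen to
reproduce the variance structure seen in real summary tables, where time
constants vary ~40% between cells while EC50s, Iss/Ipeak and open
probability vary only a few percent:

* a shared **tempo** multiplier applied to every kinetic rate of a cell
  (CV ~0.4): rescales all time constants but cancels exactly in every
  equilibrium ratio (EC50, open probability, Iss/Ipeak);
* an independent per-rate **jitter** (CV 0.05): perturbs the equilibrium
  quantities by a few percent;
* an expression multiplier on channel count (CV 0.6): scales amplitude
  only.

Additive Gaussian recording noise is set per preparation at roughly
0.5–1% of the maximal response. All draws derive from a single integer
seed, making entire cohorts bit-reproducible; mixtures (including a
<3% contaminant population representing escape from ER retention in
tri-heteromeric experiments) are simulated as fraction-weighted sums of
deterministic component currents.

Five calibrated models ship as JSON fixtures (`wt2A`, `d731n`, `wt2A2A`,
`d731n_2a`, `d731n_d731n`), each documenting its calibration targets in
the file. Calibration proceeds through the closed forms: Iss/Ipeak and
the saturating open probability fix $B$ and $D_r$; the EC50 fixes $K$;
the fast deactivation component fixes $k_{off}$ via
$\tau_{fast} \approx (1+B)/(2 k_{off})$; the slow component fixes
$k_{res}$; the 10–90% rise constrains $\beta + \alpha$ (wild type) or the
binding rate (low-potency mutant, where binding is rate-limiting at
30 mM); the block rate at the EC50 fixes `k_block_mk`; channel count is
set last so that simulated peak density at recording pH matches the
target (the mutant's proton IC50 at pH 7.3 makes proton inhibition at
recording pH 7.4 a ~45% effect, which the amplitude calibration must
absorb). The tri-heteromeric single-copy model is its own parameter set,
not derived from the homomeric models, since its intermediacy is an
empirical observation rather than a mechanistic constraint.

What passing tests on these data show: that the estimators recover the
quantities they define, at realistic noise and variability, under the
printed experimental designs (concentration series, pulse lengths,
blocker concentration, group sizes). What they do not show: anything
about real recordings — series-resistance and space-clamp errors,
capacitance transients, rundown, liquid-junction offsets, imperfect
solution exchange geometry, temperature drift and channelopathy-level
biological heterogeneity are all absent. The published biological values
serve only as calibration anchors for the fixtures; the pipeline is
validated against the simulator's ground truth, not against the paper's
cells.

## Numerical choices and problem sizes

* ODE: `lsoda`, rtol 1e-8, atol 1e-10, epoch-wise integration.
* All nonlinear fits: `minpack.lm::nlsLM`, deterministic multi-start
  (no stochastic restarts), log-parameterized positive parameters,
  tight then default convergence controls with fallback across the
  ordered start list (the looser retry guards against a brittle failure
  mode when rebuilding the model object at an already-converged
  optimum).
* Measurement windows: steady state = last 20% of an epoch; peak search
  and fit windows skip 3×`exchange_tau` after a solution switch; the
  baseline window must lie inside a zero-agonist epoch.
* Bisection for the apparent EC50 runs in log-concentration space to
  relative tolerance 1e-6 against the closed-form saturating response.
* Test-suite problem sizes are chosen to finish in minutes on one core:
  cohorts of 7–17 cells matching the published group sizes; oocyte
  protocols sampled at 25–170 ms, rapid-perfusion pulses at 0.2 ms;
  MK-801 grid checks use a deliberately slow block rate (~50× slower
  than the slowest gating relaxation) because proportionality of onset
  rate to open probability is exact only in that limit — at the
  fixtures' realistic block rates the measured onset deviates by a few
  percent, which is visible in the analysis outputs and is a property
  of the method itself.

## Known limitations

* The gating scheme is macroscopic and minimal: no single-channel
  stochasticity, no modal gating, no explicit modulator kinetics, no
  temperature dependence, no trafficking/expression mechanism (expression
  differences enter only through channel count).
* Eq-2 Hill fits of unsaturable two-site curves are operationally biased
  (documented above); consumers comparing absolute EC50s across studies
  should note the convention.
* The relative open-probability methods inherit their reference anchors;
  errors in the anchor propagate multiplicatively, and the shared
  reference cohort is the dominant variance source of a grid of
  estimates.
* Magnesium analysis is restricted to a single holding potential per
  series; no voltage-series (Woodhull-style) pore-block fitting is
  provided.
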