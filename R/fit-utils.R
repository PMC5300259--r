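## Shared Levenberg-Marquardt plumbing. nlsLM occasionally fails while
## rebuilding its nls model object at the converged optimum (a singular
## scaled gradient), which depends brittly on the start; retrying with the
## looser default control, or from the next-best deterministic start,
## resolves it without changing the fitted optimum materially.

lm_controls <- function() list(
  minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14),
  minpack.lm::nls.lm.control(maxiter = 500))

## call_fn: function(control) -> nls fit (may error). Returns fit or NULL.
robust_nlsLM <- function(call_fn) {
  for (ctrl in lm_controls()) {
    fit <- tryCatch(call_fn(ctrl), error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}
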