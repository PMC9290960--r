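# Shared fixtures: the reference scenario used across tests.
ref_ctx <- reference_context()
ref_methods <- reference_methodologies()
ref_config <- reference_program()

# Quadrature oracle for the population risk: integrate the lognormal
# dose-response CDF against the lognormal exposure density on the log10
# dose scale (a change of variables from the dose integral).
risk_by_quadrature <- function(mu_tox, sigma_tox, mu_exp, sigma_exp) {
  stats::integrate(
    function(t) {
      stats::pnorm((t - mu_tox) / sigma_tox) *
        stats::dnorm(t, mu_exp, sigma_exp)
    },
    lower = mu_exp - 12 * sigma_exp, upper = mu_exp + 12 * sigma_exp,
    rel.tol = 1e-12, abs.tol = 1e-12
  )$value
}

# Monte-Carlo oracle for the decision-making value: draw noisy potency
# estimates, classify truth and estimates into decision regions, count
# matches. Returns the match rate and its binomial standard error.
dmv_by_simulation <- function(mu_tox, sigma_mu_hat, context,
                              rule = c("simple", "complex"),
                              n_draws = 1e6, bias = 0) {
  rule <- match.arg(rule)
  est <- stats::rnorm(n_draws, mu_tox + bias, sigma_mu_hat)
  if (rule == "simple") {
    truth_side <- mu_tox > context$trl_mu_tox
    match <- (est > context$trl_mu_tox) == truth_side
  } else {
    cell <- function(m) colSums(outer(context$thresholds, m, ">"))
    match <- cell(est) == cell(mu_tox)
  }
  p <- mean(match)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}
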