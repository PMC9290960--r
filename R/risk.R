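#' Lognormal toxicity and exposure profiles
#'
#' A toxicity profile describes the distribution of individual threshold
#' doses in a population: doses at or above which an individual experiences
#' an adverse effect. An exposure profile describes the distribution of
#' doses actually received. Both are lognormal and parameterised on the
#' log10 scale: `mu` is the log10 of the geometric mean dose
#' (log10 mg/kg/day) and `sigma` is the log10 of the geometric standard
#' deviation (log10 units, unitless).
#'
#' All potency and exposure arithmetic in the package is carried out in
#' log10 space; doses are converted to mg/kg/day only for presentation.
#'
#' @param mu Numeric vector, log10 of the geometric mean dose.
#' @param sigma Numeric vector (recycled), log10 of the geometric standard
#'   deviation. Must be strictly positive.
#'
#' @return A list of class `"toxicity_profile"` or `"exposure_profile"`
#'   with elements `mu` and `sigma`.
#' @examples
#' tox <- toxicity_profile(-5, 1)
#' exp <- exposure_profile(-8, 0.5)
#' population_risk(tox, exp)
#' @export
toxicity_profile <- function(mu, sigma) {
  new_profile(mu, sigma, "toxicity_profile")
}

#' @rdname toxicity_profile
#' @export
exposure_profile <- function(mu, sigma) {
  new_profile(mu, sigma, "exposure_profile")
}

new_profile <- function(mu, sigma, class) {
  if (!is.numeric(mu) || !is.numeric(sigma)) {
    stop("`mu` and `sigma` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(mu))) {
    stop("`mu` must be finite", call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be finite and strictly positive", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma), class = c(class, "ln_profile"))
}

#' @export
print.ln_profile <- function(x, ...) {
  cat(sprintf(
    "<%s> mu = %s, sigma = %s (log10 mg/kg/day)\n",
    class(x)[1],
    paste(signif(x$mu, 6), collapse = ", "),
    paste(signif(x$sigma, 6), collapse = ", ")
  ))
  invisible(x)
}

as_profile <- function(x, class) {
  if (inherits(x, class)) return(x)
  if (is.list(x) && all(c("mu", "sigma") %in% names(x))) {
    return(new_profile(x$mu, x$sigma, class))
  }
  stop(sprintf("expected a %s (or a list with `mu` and `sigma`)", class),
       call. = FALSE)
}

#' Population risk under lognormal toxicity and exposure
#'
#' Computes the expected fraction of an exposed population experiencing an
#' adverse effect, assuming statistically independent lognormal
#' distributions of individual threshold doses (toxicity) and received
#' doses (exposure). The closed form is
#' \deqn{R = \Phi\!\left(\frac{\mu_{exp} - \mu_{tox}}
#'   {\sqrt{\sigma_{exp}^2 + \sigma_{tox}^2}}\right),}
#' the standard-normal probability that a random received dose exceeds a
#' random individual threshold dose on the log10 scale.
#'
#' @param tox A [toxicity_profile()].
#' @param exp An [exposure_profile()].
#' @return Numeric vector of population incidence fractions in \[0, 1\].
#'   Strictly decreasing in `tox$mu`, strictly increasing in `exp$mu`.
#' @seealso [mu_tox_at_risk()] for the inverse problem.
#' @examples
#' population_risk(toxicity_profile(-5, 1), exposure_profile(-8, 0.5))
#' @export
population_risk <- function(tox, exp) {
  tox <- as_profile(tox, "toxicity_profile")
  exp <- as_profile(exp, "exposure_profile")
  stats::pnorm((exp$mu - tox$mu) / sqrt(exp$sigma^2 + tox$sigma^2))
}

#' Potency at which a population attains a target risk
#'
#' Inverts the lognormal risk model: given a target incidence fraction, an
#' exposure profile and the toxicity geometric standard deviation, returns
#' the log10 potency (geometric-mean threshold dose) at which the
#' population risk equals the target,
#' \deqn{\mu_{tox} = \mu_{exp} - \Phi^{-1}(R^\ast)
#'   \sqrt{\sigma_{exp}^2 + \sigma_{tox}^2}.}
#' This is how a target risk level or a decision point in risk space is
#' mapped to a threshold in potency space.
#'
#' @param target_risk Fraction in (0, 1): the population incidence to attain.
#' @param exp An [exposure_profile()].
#' @param sigma_tox Positive scalar, log10 GSD of the toxicity distribution.
#' @return Log10 potency (log10 mg/kg/day). Round trip through
#'   [population_risk()] recovers `target_risk`.
#' @examples
#' mu <- mu_tox_at_risk(1e-6, exposure_profile(-8, 0.5), sigma_tox = 1)
#' population_risk(toxicity_profile(mu, 1), exposure_profile(-8, 0.5))
#' @export
mu_tox_at_risk <- function(target_risk, exp, sigma_tox) {
  if (any(!is.finite(target_risk)) ||
      any(target_risk <= 0) || any(target_risk >= 1)) {
    stop("`target_risk` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(sigma_tox)) || any(sigma_tox <= 0)) {
    stop("`sigma_tox` must be finite and strictly positive", call. = FALSE)
  }
  exp <- as_profile(exp, "exposure_profile")
  exp$mu - stats::qnorm(target_risk) * sqrt(exp$sigma^2 + sigma_tox^2)
}
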