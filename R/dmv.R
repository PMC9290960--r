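#' Describe a toxicity-testing methodology
#'
#' A methodology is characterised by how long testing takes, what testing
#' one chemical costs, and how uncertain the resulting potency estimate
#' is. The estimate of the log10 potency is modelled as normally
#' distributed about the true potency (plus any systematic bias) with
#' standard deviation `sigma_mu_hat`, all on the log10 scale.
#'
#' @param name Label for the methodology.
#' @param duration_years Positive integer, years of testing before results
#'   are usable.
#' @param cost_per_chemical Cost of testing one chemical, millions of
#'   dollars.
#' @param sigma_mu_hat Standard deviation of the potency-estimate
#'   uncertainty, log10 units; `0` means a perfect estimate.
#' @param bias Mean of (estimate - truth), log10 units; 0 by default.
#' @return A one-row tibble.
#' @examples
#' methodology("base case", 10, 5, 1)
#' @export
methodology <- function(name, duration_years, cost_per_chemical,
                        sigma_mu_hat, bias = 0) {
  stopifnot(
    duration_years >= 1, duration_years == as.integer(duration_years),
    cost_per_chemical > 0,
    sigma_mu_hat >= 0
  )
  tibble::tibble(
    name = as.character(name),
    duration_years = as.integer(duration_years),
    cost_per_chemical = as.numeric(cost_per_chemical),
    sigma_mu_hat = as.numeric(sigma_mu_hat),
    bias = as.numeric(bias)
  )
}

# Normal probability that the estimate falls in each decision region.
# Rows = chemicals, columns = regions (no action, action 1..K, beyond the
# choice set). Rows sum to 1 exactly up to floating point.
region_probabilities <- function(mu_tox, sigma_mu_hat, context, bias = 0) {
  b <- region_bounds(context$thresholds)
  centre <- mu_tox + bias
  if (sigma_mu_hat == 0) {
    # Degenerate point estimate: all mass in the cell holding the centre
    # (a centre exactly on a threshold sits in that threshold's region,
    # same tie-break as the truth).
    cells <- region_index(centre, context$thresholds)
    p <- matrix(0, length(mu_tox), length(b$upper))
    p[cbind(seq_along(mu_tox), cells)] <- 1
    return(p)
  }
  up <- outer(centre, b$upper, function(m, u) stats::pnorm((u - m) / sigma_mu_hat))
  lo <- outer(centre, b$lower, function(m, l) stats::pnorm((l - m) / sigma_mu_hat))
  up - lo
}

#' Decision-making value under the simple rule
#'
#' The probability that a methodology's noisy potency estimate leads to
#' the same accept/regulate decision as perfect knowledge of the true
#' potency. The estimate is Normal(`mu_tox + bias`, `sigma_mu_hat`) in
#' log10 space, and a correct decision is an estimate on the same side of
#' the TRL potency threshold as the truth (the threshold itself counts as
#' the acceptable side).
#'
#' @param mu_tox Numeric vector of true log10 potencies.
#' @param sigma_mu_hat SD of the potency-estimate uncertainty (log10
#'   units); a scalar, as uncertainty is a property of the methodology.
#' @param context A [decision_context()].
#' @param bias Mean of (estimate - truth), log10 units.
#' @return Probabilities in (0, 1\]. A chemical exactly at the threshold
#'   with an unbiased noisy estimate has value 0.5; a noiseless estimate
#'   always gives 1.
#' @examples
#' ctx <- reference_context()
#' dmv_simple(ctx$trl_mu_tox + 1, sigma_mu_hat = 1, ctx)
#' @export
dmv_simple <- function(mu_tox, sigma_mu_hat, context, bias = 0) {
  t0 <- context$trl_mu_tox
  centre <- mu_tox + bias
  if (sigma_mu_hat == 0) {
    # Point estimate: correct unless bias pushes it across the threshold.
    return(as.numeric((mu_tox > t0) == (centre > t0)))
  }
  z <- (t0 - centre) / sigma_mu_hat
  ifelse(mu_tox > t0, stats::pnorm(-z), stats::pnorm(z))
}

#' Decision-making value under the complex rule
#'
#' The probability that the noisy potency estimate falls in the same
#' decision region — delimited by the TRL potency threshold and the
#' per-action decision points — as the true potency, so that the same
#' regulatory action would be selected. Region probabilities are
#' differences of normal CDFs at consecutive thresholds; the most toxic
#' region is unbounded below.
#'
#' @inheritParams dmv_simple
#' @return Probabilities in (0, 1\].
#' @examples
#' ctx <- reference_context()
#' dmv_complex(-5, sigma_mu_hat = 1, ctx)
#' @export
dmv_complex <- function(mu_tox, sigma_mu_hat, context, bias = 0) {
  p <- region_probabilities(mu_tox, sigma_mu_hat, context, bias)
  cells <- region_index(mu_tox, context$thresholds)
  p[cbind(seq_along(mu_tox), cells)]
}

#' Tabulate decision-making values for chemicals under methodologies
#'
#' Crosses a population of chemicals with a set of methodologies and
#' computes both decision-making values analytically.
#'
#' @param chemicals A data frame with a `mu_tox` column (log10 mg/kg/day),
#'   e.g. from [sample_population()].
#' @param methods A data frame of methodologies, e.g.
#'   [reference_methodologies()]; one row per methodology with columns
#'   `name`, `duration_years`, `cost_per_chemical`, `sigma_mu_hat`, `bias`.
#' @param context A [decision_context()].
#' @return A tibble: the chemical columns, the methodology columns, and
#'   `dmv_simple`, `dmv_complex`.
#' @examples
#' pop <- sample_population(10, seed = 1)
#' compute_dmv(pop, reference_methodologies(), reference_context())
#' @export
compute_dmv <- function(chemicals, methods, context) {
  stopifnot("mu_tox" %in% names(chemicals))
  methods <- dplyr::mutate(methods, .method = dplyr::row_number())
  out <- tidyr::crossing(chemicals, methods)
  out <- dplyr::group_by(out, .data$.method)
  out <- dplyr::mutate(
    out,
    dmv_simple = dmv_simple(.data$mu_tox, .data$sigma_mu_hat[1], context,
                            .data$bias[1]),
    dmv_complex = dmv_complex(.data$mu_tox, .data$sigma_mu_hat[1], context,
                              .data$bias[1])
  )
  out <- dplyr::ungroup(out)
  dplyr::select(out, -".method")
}
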