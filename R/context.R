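#' Define a choice set of regulatory actions
#'
#' Each regulatory action replaces the baseline (uncontrolled) exposure
#' profile with a post-control profile; actions are ordered by increasing
#' stringency (each reduces risk further than the previous) and increasing
#' cost. Only the rank of the action costs enters the decision rule, never
#' the costs themselves.
#'
#' @param mu_exp Numeric vector, log10 GM of the post-control exposure
#'   distribution per action (log10 mg/kg/day).
#' @param sigma_exp Numeric vector (recycled), log10 GSD per action.
#' @param cost_rank Integer vector, 1 = cheapest; must be unique. Defaults
#'   to the order given.
#' @return A tibble with columns `id`, `mu_exp`, `sigma_exp`, `cost_rank`.
#' @examples
#' regulatory_actions(c(-8.5, -8.8, -14), c(0.4, 0.4, 0.1))
#' @export
regulatory_actions <- function(mu_exp, sigma_exp,
                               cost_rank = seq_along(mu_exp)) {
  sigma_exp <- rep_len(sigma_exp, length(mu_exp))
  if (anyDuplicated(cost_rank)) {
    stop("`cost_rank` values must be unique within a choice set",
         call. = FALSE)
  }
  new_profile(mu_exp, sigma_exp, "exposure_profile") # validates
  tibble::tibble(
    id = seq_along(mu_exp),
    mu_exp = as.numeric(mu_exp),
    sigma_exp = as.numeric(sigma_exp),
    cost_rank = as.integer(cost_rank)
  )
}

#' Build a decision context
#'
#' Combines a target risk level (TRL), the uncontrolled exposure profile,
#' a choice set of regulatory actions and the toxicity variability into the
#' object that both decision rules operate on. Two families of derived
#' thresholds partition potency space:
#'
#' * `trl_mu_tox` — the potency at which the uncontrolled risk equals the
#'   TRL; chemicals less potent than this need no action.
#' * `dp_mu_tox[k]` — the potency at which action k's post-control risk
#'   equals the TRL (the "decision point" in potency space); action k is
#'   the cheapest sufficient action exactly on
#'   `[dp_mu_tox[k], previous threshold)`.
#'
#' `dp_risk[k]` is the uncontrolled risk at `dp_mu_tox[k]`: the largest
#' no-action risk that action k can bring down to the TRL.
#'
#' @param trl Target risk level, a fraction in (0, 1).
#' @param baseline_exposure [exposure_profile()] for uncontrolled doses.
#' @param actions A tibble from [regulatory_actions()], ordered by
#'   increasing stringency.
#' @param sigma_tox Log10 GSD of the toxicity distribution.
#' @return An object of class `"decision_context"`.
#' @examples
#' ctx <- decision_context(
#'   trl = 1e-6,
#'   baseline_exposure = exposure_profile(-8, 0.5),
#'   actions = regulatory_actions(c(-8.5, -8.8, -14), c(0.4, 0.4, 0.1)),
#'   sigma_tox = 1
#' )
#' ctx
#' @export
decision_context <- function(trl, baseline_exposure, actions, sigma_tox) {
  if (!is.numeric(trl) || length(trl) != 1L || trl <= 0 || trl >= 1) {
    stop("`trl` must be a single fraction in (0, 1)", call. = FALSE)
  }
  baseline_exposure <- as_profile(baseline_exposure, "exposure_profile")
  stopifnot(is.data.frame(actions), nrow(actions) >= 1L)

  trl_mu_tox <- mu_tox_at_risk(trl, baseline_exposure, sigma_tox)
  dp_mu_tox <- mu_tox_at_risk(
    trl, exposure_profile(actions$mu_exp, actions$sigma_exp), sigma_tox
  )
  thresholds <- c(trl_mu_tox, dp_mu_tox)
  # Decision points must strictly decrease with stringency; an action no
  # more effective than no action (dp above the TRL threshold) is allowed
  # only in the degenerate equal-to-baseline case.
  if (any(diff(dp_mu_tox) >= 0) || dp_mu_tox[1] > trl_mu_tox) {
    stop(paste(
      "potency thresholds are not strictly decreasing;",
      "actions must be ordered by increasing stringency",
      "(decision regions would be ambiguous)"
    ), call. = FALSE)
  }
  dp_risk <- population_risk(
    toxicity_profile(dp_mu_tox, sigma_tox), baseline_exposure
  )

  structure(
    list(
      trl = trl,
      baseline_exposure = baseline_exposure,
      actions = actions,
      sigma_tox = sigma_tox,
      trl_mu_tox = trl_mu_tox,
      dp_mu_tox = dp_mu_tox,
      dp_risk = dp_risk,
      thresholds = thresholds
    ),
    class = "decision_context"
  )
}

#' @export
print.decision_context <- function(x, ...) {
  k <- nrow(x$actions)
  cat(sprintf("<decision_context> TRL = %g, K = %d actions\n", x$trl, k))
  cat(sprintf("  trl_mu_tox = %.4f log10 mg/kg/day (%.3g mg/kg/day)\n",
              x$trl_mu_tox, 10^x$trl_mu_tox))
  for (i in seq_len(k)) {
    cat(sprintf(
      "  action %d: dp_mu_tox = %.4f (%.3g mg/kg/day), dp_risk = %.3g\n",
      x$actions$id[i], x$dp_mu_tox[i], 10^x$dp_mu_tox[i], x$dp_risk[i]
    ))
  }
  invisible(x)
}

#' @describeIn decision_context One row per potency threshold: the TRL
#'   threshold (`action = 0`) and each action's decision point, in log10
#'   and natural dose units, with the decision-point risk.
#' @param x A `decision_context`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.decision_context <- function(x, ...) {
  tibble::tibble(
    action = c(0L, x$actions$id),
    threshold_mu_tox = x$thresholds,
    threshold_dose = 10^x$thresholds,
    risk_at_threshold = c(x$trl, x$dp_risk)
  )
}

#' Locate a potency in its decision region
#'
#' Maps true log10 potencies to the regulatory action that the complex
#' decision rule selects under perfect knowledge: 0 (no action) for
#' `mu_tox >= trl_mu_tox`, otherwise the cheapest sufficient action k on
#' `[dp_mu_tox[k], previous threshold)`. Regions are closed at the
#' more-toxic (lower) end. Potencies below the last decision point — where
#' even the most stringent action cannot attain the TRL — return `NA`.
#'
#' @param mu_tox Numeric vector of log10 potencies.
#' @param context A [decision_context()].
#' @return Integer vector of action ids (0 = no action), `NA` beyond the
#'   choice set.
#' @export
classify_potency <- function(mu_tox, context) {
  region <- region_index(mu_tox, context$thresholds)
  k <- length(context$thresholds)
  ifelse(region > k, NA_integer_, as.integer(region) - 1L)
}

# Cell index 1..K+2 over descending thresholds: cell 1 = [t1, Inf),
# cell j = [tj, t(j-1)) for j in 2..K+1, cell K+2 = (-Inf, t(K+1)).
# Boundaries belong to the lower (more-toxic) cell's upper edge, i.e. a
# potency equal to a threshold sits in the region where that threshold is
# the closed lower bound.
region_index <- function(mu_tox, thresholds) {
  counts <- vapply(
    mu_tox, function(m) sum(m < thresholds), numeric(1)
  )
  counts + 1
}

region_bounds <- function(thresholds) {
  list(upper = c(Inf, thresholds), lower = c(thresholds, -Inf))
}
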