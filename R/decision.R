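#' Simple decision rule
#'
#' Regulate (1) when the estimated uncontrolled population risk strictly
#' exceeds the target risk level; otherwise take no action (0). A risk
#' exactly at the TRL is acceptable.
#'
#' @param risk_estimate Numeric vector of risk estimates in \[0, 1\].
#' @param trl Target risk level.
#' @return Integer vector of 0/1 decisions.
#' @examples
#' decide_simple(c(2e-6, 1e-6, 0), trl = 1e-6)
#' @export
decide_simple <- function(risk_estimate, trl) {
  stopifnot(all(risk_estimate >= 0), all(risk_estimate <= 1))
  as.integer(risk_estimate > trl)
}

#' Complex decision rule
#'
#' Select no action (0) when the uncontrolled risk estimate is at or below
#' the TRL; otherwise select, among the actions whose post-control risk
#' estimate is at or below the TRL, the one with the lowest cost rank.
#' All risk estimates must derive from the same toxicity estimate.
#'
#' @param risk_no_action Numeric vector (length n) of uncontrolled risk
#'   estimates.
#' @param risk_actions Numeric vector (one chemical) or n-by-K matrix of
#'   post-control risk estimates, columns in the order of
#'   `context$actions`.
#' @param context A [decision_context()].
#' @return Integer vector of selected action ids (0 = no action).
#'   Errors if some chemical has risk above the TRL and no compliant
#'   action: the choice set is assumed to contain at least one action able
#'   to reach the TRL.
#' @examples
#' ctx <- reference_context()
#' tox <- toxicity_profile(-3.5, 1)
#' r0 <- population_risk(tox, ctx$baseline_exposure)
#' rk <- population_risk(tox, exposure_profile(ctx$actions$mu_exp,
#'                                             ctx$actions$sigma_exp))
#' decide_complex(r0, rk, ctx)
#' @export
decide_complex <- function(risk_no_action, risk_actions, context) {
  if (is.null(dim(risk_actions))) {
    risk_actions <- matrix(risk_actions, nrow = length(risk_no_action),
                           ncol = length(risk_actions), byrow = TRUE)
  }
  stopifnot(
    nrow(risk_actions) == length(risk_no_action),
    ncol(risk_actions) == nrow(context$actions)
  )
  rank <- context$actions$cost_rank
  ids <- context$actions$id
  vapply(seq_along(risk_no_action), function(i) {
    if (risk_no_action[i] <= context$trl) return(0L)
    ok <- which(risk_actions[i, ] <= context$trl)
    if (length(ok) == 0L) {
      stop("no compliant action: no regulatory action attains the TRL",
           call. = FALSE)
    }
    as.integer(ids[ok[which.min(rank[ok])]])
  }, integer(1))
}
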