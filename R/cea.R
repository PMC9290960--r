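#' Present-value discount factor
#'
#' Year 1 is undiscounted; year y is reduced by `(1 + rate)^-(y - 1)`.
#' The same convention applies to testing costs and to decision-making
#' value.
#'
#' @param year Integer vector of years, starting at 1.
#' @param rate Annual discount rate as a fraction (0.03 = 3%/year).
#' @return Numeric multipliers in (0, 1\].
#' @examples
#' discount_factor(c(1, 11), 0.03)
#' @export
discount_factor <- function(year, rate) {
  if (any(year < 1)) stop("`year` must be >= 1", call. = FALSE)
  if (rate < 0) stop("`rate` must be non-negative", call. = FALSE)
  (1 + rate)^-(year - 1)
}

#' Program configuration for a cohort-based testing program
#'
#' The program is funded at a constant annual budget; each year it starts
#' testing a new cohort of chemicals, as many as the year's budget funds
#' at the methodology's per-chemical cost (the whole cost of a cohort is
#' charged, discounted, in its start year). Leftover budget is discarded,
#' not banked.
#'
#' @param annual_budget Millions of dollars per year.
#' @param discount_rate Annual discount rate, fraction per year.
#' @param horizons Integer vector of time horizons (years) over which
#'   per-horizon program CERs are averaged; a single value for a fixed
#'   horizon.
#' @return A list of class `"program_config"`.
#' @examples
#' program_config()
#' @export
program_config <- function(annual_budget = 10, discount_rate = 0.03,
                           horizons = 11:20) {
  stopifnot(annual_budget > 0, discount_rate >= 0,
            all(horizons >= 1), all(horizons == as.integer(horizons)))
  structure(
    list(annual_budget = annual_budget, discount_rate = discount_rate,
         horizons = as.integer(horizons)),
    class = "program_config"
  )
}

#' @export
print.program_config <- function(x, ...) {
  cat(sprintf(
    "<program_config> budget $%gM/yr, discount %g%%/yr, horizons %s\n",
    x$annual_budget, 100 * x$discount_rate,
    if (length(x$horizons) > 1)
      sprintf("%d..%d", min(x$horizons), max(x$horizons))
    else as.character(x$horizons)
  ))
  invisible(x)
}

#' Single-chemical cost-effectiveness ratio
#'
#' Discounted testing cost divided by the discounted sum of annual
#' decision-making value over the years the data are usable. The full
#' testing cost is charged in year 1; the data support decisions in each
#' year from `duration_years + 1` through the horizon, contributing
#' `dmv * discount_factor(y)` per year.
#'
#' @param method One-row data frame from [methodology()] (columns
#'   `duration_years`, `cost_per_chemical` are used).
#' @param dmv Annual probability of a correct decision once data exist.
#' @param rate Annual discount rate.
#' @param horizon Time horizon in years; must exceed the test duration.
#' @return A one-row tibble with `cost_npv`, `outcome_npv` (discounted
#'   correct-decision-years) and `cer` (millions of dollars per
#'   discounted correct-decision-year).
#' @examples
#' single_chemical_cer(methodology("base case", 10, 5, 1), dmv = 0.9)
#' @export
single_chemical_cer <- function(method, dmv, rate = 0.03, horizon = 20) {
  duration <- method$duration_years[1]
  cost <- method$cost_per_chemical[1]
  if (horizon <= duration) {
    stop("no benefit years within horizon: `horizon` must exceed the test duration",
         call. = FALSE)
  }
  years <- seq(duration + 1, horizon)
  outcome_npv <- sum(dmv * discount_factor(years, rate))
  tibble::tibble(
    cost_npv = cost,
    outcome_npv = outcome_npv,
    cer = cost / outcome_npv
  )
}

#' Year-by-year single-chemical ledger
#'
#' Expands [single_chemical_cer()] into the year-by-year table of costs,
#' discounted costs, annual decision-making value and discounted
#' decision-making value, with net-present-value totals attached as
#' attributes `cost_npv`, `outcome_npv` and `cer`.
#'
#' @inheritParams single_chemical_cer
#' @return A tibble with one row per year of the horizon.
#' @examples
#' ledger <- cer_ledger()
#' attr(ledger, "cer")
#' @export
cer_ledger <- function(method = methodology("base case", 10, 5, 1),
                       dmv = 0.9, rate = 0.03, horizon = 20) {
  duration <- method$duration_years[1]
  cost <- method$cost_per_chemical[1]
  totals <- single_chemical_cer(method, dmv, rate, horizon)
  year <- seq_len(horizon)
  using <- year > duration
  out <- tibble::tibble(
    year = year,
    event = dplyr::case_when(
      year == 1 ~ "Performing the test",
      year == duration + 1 ~ "Using the data to assess risk",
      TRUE ~ ""
    ),
    cost = ifelse(year == 1, cost, 0),
    discounted_cost = ifelse(year == 1, cost, 0) *
      discount_factor(year, rate),
    dmv = ifelse(using, dmv, NA_real_),
    discounted_dmv = ifelse(using, dmv * discount_factor(year, rate),
                            NA_real_)
  )
  attr(out, "cost_npv") <- totals$cost_npv
  attr(out, "outcome_npv") <- totals$outcome_npv
  attr(out, "cer") <- totals$cer
  out
}

# Discounted bookkeeping shared by the program-level CER: cohorts start in
# every year 1..TH; a cohort started in year s finishes after `duration`
# years and supports decisions in years s + duration .. TH (none if it
# cannot finish inside the horizon). Summing the per-year discount factors
# over cohorts gives
#   outcome weight W = sum_{y = duration+1}^{TH} (y - duration) (1+r)^-(y-1)
# while each cohort's cost is charged, discounted, at its start year.
program_weights <- function(duration, horizon, rate) {
  if (horizon <= duration) {
    stop("no benefit years within horizon: every horizon must exceed the test duration",
         call. = FALSE)
  }
  years <- seq(duration + 1, horizon)
  list(
    cost = sum(discount_factor(seq_len(horizon), rate)),
    outcome = sum((years - duration) * discount_factor(years, rate))
  )
}

#' Program-level cost-effectiveness ratio per chemical
#'
#' Cost-effectiveness of an annually funded testing program: every year
#' through the horizon a new cohort of `floor(annual_budget /
#' cost_per_chemical)` chemicals starts testing and its full cost is
#' charged (discounted) at launch — including cohorts started too late to
#' finish, whose outcomes never accrue. A chemical started in year s
#' contributes `dmv * discount_factor(y)` in every year y from
#' `s + duration_years` through the horizon. The per-chemical CER is the
#' total discounted program cost divided by the total discounted outcome
#' for a program testing chemicals with the given `dmv`; cohort size
#' cancels, so under a fixed budget a k-fold cost reduction divides the
#' CER by exactly k.
#'
#' @param method One-row data frame from [methodology()].
#' @param dmv Numeric vector of per-chemical annual decision-making
#'   values.
#' @param config A [program_config()].
#' @param horizon Single time horizon (years); defaults to the first
#'   horizon of `config`.
#' @return Numeric vector of CERs (millions of dollars per discounted
#'   correct-decision-year), one per element of `dmv`.
#' @examples
#' program_cer(methodology("base case", 10, 5, 1), dmv = 1,
#'             program_config(), horizon = 20)
#' @export
program_cer <- function(method, dmv, config = program_config(),
                        horizon = config$horizons[1]) {
  cost <- method$cost_per_chemical[1]
  cohort_size <- floor(config$annual_budget / cost)
  if (cohort_size < 1) {
    stop("cohort size is zero: annual budget funds no chemical",
         call. = FALSE)
  }
  w <- program_weights(method$duration_years[1], horizon,
                       config$discount_rate)
  (cohort_size * cost * w$cost) / (cohort_size * dmv * w$outcome)
}

#' Horizon-averaged program cost-effectiveness ratio
#'
#' The choice of time horizon strongly affects how testing duration is
#' valued, and no single horizon is canonical; results are therefore
#' averaged over a range of horizons. Returns the arithmetic mean over
#' the integer horizons in `config$horizons` of the per-chemical
#' [program_cer()].
#'
#' @inheritParams program_cer
#' @return Numeric vector, one horizon-averaged CER per element of `dmv`.
#' @examples
#' horizon_averaged_cer(methodology("base case", 10, 5, 1), dmv = 1)
#' @export
horizon_averaged_cer <- function(method, dmv, config = program_config()) {
  per_th <- vapply(
    config$horizons,
    function(th) program_cer(method, 1, config, horizon = th),
    numeric(1)
  )
  mean(per_th) / dmv
}
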