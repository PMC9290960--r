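#' Reference scenario fixtures
#'
#' The package ships a reference scenario used throughout the examples and
#' tests: five hypothetical testing methodologies spanning fivefold
#' differences in cost, duration and uncertainty; a severe-effect target
#' risk level of 1e-6; an uncontrolled exposure of GM 1e-8 mg/kg/day
#' (log10 GSD 0.5); and a choice set of three increasingly stringent
#' regulatory actions. `reference_scenario()` bundles all of the pieces.
#'
#' @return `reference_methodologies()`: a five-row methodology tibble.
#'   `reference_context()`: a [decision_context()]. `reference_program()`:
#'   a [program_config()] ($10M/year, 3%/year, horizons 11..20).
#'   `reference_scenario()`: a list with elements `methods`, `context`,
#'   `config` and `population` (n and bounds for [sample_population()]).
#' @examples
#' reference_methodologies()
#' reference_context()
#' @export
reference_methodologies <- function() {
  dplyr::bind_rows(
    methodology("base case",           10, 5, 1),
    methodology("reduced cost",        10, 1, 1),
    methodology("reduced time",         2, 5, 1),
    methodology("reduced uncertainty", 10, 5, 0.2),
    methodology("all reduced",          2, 1, 0.2)
  )
}

#' @rdname reference_methodologies
#' @export
reference_context <- function() {
  decision_context(
    trl = 1e-6,
    baseline_exposure = exposure_profile(-8, 0.5),
    actions = regulatory_actions(
      mu_exp = c(-8.5, -8.8, -14),
      sigma_exp = c(0.4, 0.4, 0.1)
    ),
    sigma_tox = 1
  )
}

#' @rdname reference_methodologies
#' @export
reference_program <- function() {
  program_config(annual_budget = 10, discount_rate = 0.03,
                 horizons = 11:20)
}

#' @rdname reference_methodologies
#' @export
reference_scenario <- function() {
  list(
    methods = reference_methodologies(),
    context = reference_context(),
    config = reference_program(),
    population = list(n = 5000L, bounds = c(-5, 2))
  )
}

#' Read a scenario configuration file
#'
#' Scenarios mirror the reference fixtures field-for-field and may be
#' written as YAML or JSON (chosen by file extension). The schema, with
#' doses in log10 mg/kg/day, costs in millions of dollars, durations and
#' horizons in years:
#'
#' ```yaml
#' trl: 1.0e-6
#' sigma_tox: 1
#' baseline_exposure: {mu: -8, sigma: 0.5}
#' actions:
#'   - {mu: -8.5, sigma: 0.4, cost_rank: 1}
#'   - {mu: -8.8, sigma: 0.4, cost_rank: 2}
#'   - {mu: -14,  sigma: 0.1, cost_rank: 3}
#' methodologies:
#'   - {name: base case, duration_years: 10, cost_per_chemical: 5,
#'      sigma_mu_hat: 1, bias: 0}
#' program: {annual_budget: 10, discount_rate: 0.03, horizons: [11, 20]}
#' population: {n: 5000, bounds: [-5, 2]}
#' ```
#'
#' `program.horizons` is an inclusive integer range `[first, last]` (or a
#' single year). `bias` defaults to 0 and `population` to 5000 chemicals
#' on \[-5, 2\].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file. The
#'   installed example is
#'   `system.file("extdata", "reference_scenario.yaml", package = "toxcea")`.
#' @return A list with `methods`, `context`, `config`, `population`, as in
#'   [reference_scenario()].
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("scenario file must be .yaml, .yml or .json", call. = FALSE)
  }
  acts <- dplyr::bind_rows(lapply(raw$actions, tibble::as_tibble))
  context <- decision_context(
    trl = raw$trl,
    baseline_exposure = exposure_profile(raw$baseline_exposure$mu,
                                         raw$baseline_exposure$sigma),
    actions = regulatory_actions(
      acts$mu, acts$sigma,
      cost_rank = if ("cost_rank" %in% names(acts)) acts$cost_rank
                  else seq_len(nrow(acts))
    ),
    sigma_tox = raw$sigma_tox
  )
  methods <- dplyr::bind_rows(lapply(raw$methodologies, function(m) {
    methodology(m$name, m$duration_years, m$cost_per_chemical,
                m$sigma_mu_hat, bias = m$bias %||% 0)
  }))
  h <- raw$program$horizons
  horizons <- if (length(h) == 2) seq(h[[1]], h[[2]]) else h[[1]]
  config <- program_config(raw$program$annual_budget,
                           raw$program$discount_rate, horizons)
  pop <- raw$population %||% list()
  population <- list(
    n = as.integer(pop$n %||% 5000L),
    bounds = as.numeric(unlist(pop$bounds %||% c(-5, 2)))
  )
  list(methods = methods, context = context, config = config,
       population = population)
}
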