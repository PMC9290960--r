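#' Attach cost-effectiveness ratios to a decision-making-value table
#'
#' Adds horizon-averaged per-chemical program CERs for both decision rules
#' to the output of [compute_dmv()].
#'
#' @param dmv_tbl A tibble from [compute_dmv()] (columns `duration_years`,
#'   `cost_per_chemical`, `dmv_simple`, `dmv_complex`).
#' @param config A [program_config()].
#' @return The input tibble with `cer_simple` and `cer_complex` columns
#'   (millions of dollars per discounted correct-decision-year).
#' @examples
#' sample_population(10, seed = 1) |>
#'   compute_dmv(reference_methodologies(), reference_context()) |>
#'   compute_cer(reference_program())
#' @export
compute_cer <- function(dmv_tbl, config = reference_program()) {
  groups <- dplyr::group_by(dmv_tbl, .data$name, .data$duration_years,
                            .data$cost_per_chemical)
  out <- dplyr::mutate(
    groups,
    cer_simple = horizon_averaged_cer(
      dplyr::cur_group(), .data$dmv_simple, config
    ),
    cer_complex = horizon_averaged_cer(
      dplyr::cur_group(), .data$dmv_complex, config
    )
  )
  dplyr::ungroup(out)
}

#' Run a full cost-effectiveness comparison of testing methodologies
#'
#' For every chemical in the population and every methodology, computes
#' the decision-making value under the simple and complex rules and the
#' horizon-averaged program CER, then aggregates across the population
#' (mean and maximum per methodology and rule) and forms fold-reduction
#' ratios of each methodology against a base methodology.
#'
#' @param population Tibble with a `mu_tox` column, e.g. from
#'   [sample_population()].
#' @param methods Methodology tibble (default [reference_methodologies()]).
#' @param context A [decision_context()] (default [reference_context()]).
#' @param config A [program_config()] (default [reference_program()]).
#' @param base Row index of the base methodology for the reduction table.
#' @return An object of class `"cea_suite"`: a list with
#'   * `per_chemical` — one row per chemical x methodology with `dmv_*`
#'     and `cer_*` columns (sorted by `mu_tox` within methodology);
#'   * `summary` — mean and max CER per methodology and rule;
#'   * `reductions` — fold reductions base/other; the `mean` column is the
#'     ratio of population means, the `max` column the largest
#'     per-chemical ratio (the chemical most affected by the difference);
#'   * the `methods`, `context` and `config` used.
#' @examples
#' suite <- sample_population(500, seed = 1) |> run_cea_suite()
#' suite$summary
#' @export
run_cea_suite <- function(population,
                          methods = reference_methodologies(),
                          context = reference_context(),
                          config = reference_program(),
                          base = 1L) {
  per_chemical <- compute_cer(
    compute_dmv(population, methods, context), config
  )
  per_chemical <- dplyr::arrange(
    per_chemical, match(.data$name, methods$name), .data$mu_tox
  )

  long <- tidyr::pivot_longer(
    per_chemical, c("cer_simple", "cer_complex"),
    names_to = "rule", names_prefix = "cer_", values_to = "cer"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$name, .data$rule),
    mean_cer = mean(.data$cer),
    max_cer = max(.data$cer),
    .groups = "drop"
  )
  summary <- dplyr::arrange(summary, match(.data$name, methods$name),
                            dplyr::desc(.data$rule))

  base_name <- methods$name[base]
  base_tbl <- dplyr::filter(long, .data$name == base_name)
  ratios <- dplyr::inner_join(
    dplyr::select(base_tbl, "chemical", "rule", base_cer = "cer"),
    dplyr::filter(long, .data$name != base_name),
    by = c("chemical", "rule")
  )
  reductions <- dplyr::summarise(
    dplyr::group_by(ratios, .data$name, .data$rule),
    mean_reduction = mean(.data$base_cer) / mean(.data$cer),
    max_reduction = max(.data$base_cer / .data$cer),
    .groups = "drop"
  )
  reductions <- dplyr::arrange(
    reductions, match(.data$name, methods$name), dplyr::desc(.data$rule)
  )
  reductions <- dplyr::mutate(
    reductions, comparison = paste(base_name, "/", .data$name),
    .before = 1
  )

  structure(
    list(per_chemical = per_chemical, summary = summary,
         reductions = reductions, methods = methods, context = context,
         config = config, base = base_name),
    class = "cea_suite"
  )
}

#' @export
print.cea_suite <- function(x, ...) {
  cat(sprintf(
    "<cea_suite> %d chemicals x %d methodologies\n",
    length(unique(x$per_chemical$chemical)), nrow(x$methods)
  ))
  cat("\nMean and maximum CER ($M per discounted correct-decision-year):\n")
  print(x$summary, n = Inf)
  cat(sprintf("\nFold reductions relative to '%s':\n", x$base))
  print(x$reductions, n = Inf)
  invisible(x)
}

#' @describeIn run_cea_suite Per-chemical results as a tibble.
#' @param x,object A `cea_suite`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cea_suite <- function(x, ...) {
  x$per_chemical
}

#' @describeIn run_cea_suite Population aggregates, one row per
#'   methodology with mean/max CER for each rule.
#' @exportS3Method generics::glance
glance.cea_suite <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary, names_from = "rule",
    values_from = c("mean_cer", "max_cer")
  )
}

#' Plot cost-effectiveness against chemical potency
#'
#' Draws the per-chemical CER-versus-potency curves for each methodology.
#' Under the complex rule the curves peak (or step) at the potencies
#' matching the TRL threshold and the decision points, where a given
#' estimate uncertainty most easily flips the selected action; threshold
#' potencies are marked with dashed lines.
#'
#' @param object A `cea_suite` from [run_cea_suite()].
#' @param rule `"simple"`, `"complex"` or `"both"` (facetted).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' suite <- sample_population(500, seed = 1) |> run_cea_suite()
#' autoplot(suite, rule = "complex")
#' @exportS3Method ggplot2::autoplot
autoplot.cea_suite <- function(object, rule = c("both", "simple", "complex"),
                               ...) {
  rule <- match.arg(rule)
  long <- tidyr::pivot_longer(
    object$per_chemical, c("cer_simple", "cer_complex"),
    names_to = "rule", names_prefix = "cer_", values_to = "cer"
  )
  if (rule != "both") long <- dplyr::filter(long, .data$rule == .env$rule)
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$mu_tox, y = .data$cer, colour = .data$name)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$context$thresholds,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(mu[tox] ~ (log[10] ~ "mg/kg/day")),
      y = "CER ($M per discounted correct-decision-year)",
      colour = "Methodology"
    )
  if (rule == "both") {
    p <- p + ggplot2::facet_wrap(~rule)
  }
  p
}

#' @rdname autoplot.cea_suite
#' @export
plot_cer_curve <- function(object, rule = c("both", "simple", "complex"),
                           ...) {
  autoplot.cea_suite(object, rule = rule, ...)
}
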