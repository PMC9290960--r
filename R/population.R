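#' Sample a chemical population with log-uniform potencies
#'
#' Draws true log10 potencies (geometric-mean threshold doses) uniformly
#' on a log10 interval — a log-uniform distribution of potency in natural
#' dose units. The default bounds of -5 to 2 log10 mg/kg/day (0.00001 to
#' 100 mg/kg/day) deliberately span a wider range than most real chemical
#' inventories, so that the relationship between cost-effectiveness and
#' potency is visible across all decision regions.
#'
#' @param n Number of chemicals (default 5000).
#' @param bounds Length-2 numeric, lower and upper log10 potency bounds.
#' @param seed Optional integer; when supplied, sampling is reproducible
#'   and leaves the global RNG state untouched.
#' @return A tibble with columns `chemical` (id) and `mu_tox`
#'   (log10 mg/kg/day).
#' @examples
#' sample_population(5, seed = 1)
#' @export
sample_population <- function(n = 5000, bounds = c(-5, 2), seed = NULL) {
  stopifnot(n >= 1, length(bounds) == 2)
  if (bounds[1] > bounds[2]) {
    stop("`bounds` must be ordered (lower, upper)", call. = FALSE)
  }
  draw <- function() stats::runif(n, bounds[1], bounds[2])
  mu_tox <- if (is.null(seed)) {
    draw()
  } else {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    )
    set.seed(seed)
    draw()
  }
  tibble::tibble(chemical = seq_len(n), mu_tox = mu_tox)
}
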