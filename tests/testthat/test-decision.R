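test_that("decision context derives the potency thresholds of the fixtures", {
  expect_equal(round(ref_ctx$trl_mu_tox, 4), -2.6855)
  expect_equal(round(ref_ctx$dp_mu_tox[1], 4), -3.3804)
  expect_equal(round(ref_ctx$dp_mu_tox[2], 4), -3.6804)
  # Printed dose bands: no-action boundary 0.002, action bands
  # 0.0004-0.002 and 0.0002-0.0004 mg/kg/day.
  expect_equal(signif(10^ref_ctx$trl_mu_tox, 1), 0.002)
  expect_equal(signif(10^ref_ctx$dp_mu_tox[1:2], 1), c(4e-4, 2e-4))
  # dp_risk is the no-action risk at each decision point and exceeds the
  # TRL for every (stringent) action.
  expect_true(all(ref_ctx$dp_risk > ref_ctx$trl))
  # Post-control risk at the decision point equals the TRL by construction.
  for (k in 1:3) {
    rk <- population_risk(
      toxicity_profile(ref_ctx$dp_mu_tox[k], ref_ctx$sigma_tox),
      exposure_profile(ref_ctx$actions$mu_exp[k],
                       ref_ctx$actions$sigma_exp[k])
    )
    expect_equal(rk, ref_ctx$trl, tolerance = 1e-12)
  }
})

test_that("an action with baseline exposure shares the TRL threshold", {
  ctx <- decision_context(
    trl = 1e-6,
    baseline_exposure = exposure_profile(-8, 0.5),
    actions = regulatory_actions(c(-8), c(0.5)),
    sigma_tox = 1
  )
  expect_equal(ctx$dp_mu_tox, ctx$trl_mu_tox)
})

test_that("non-decreasing thresholds are rejected as ambiguous", {
  expect_error(
    decision_context(
      trl = 1e-6, baseline_exposure = exposure_profile(-8, 0.5),
      actions = regulatory_actions(c(-8.8, -8.5), c(0.4, 0.4)),
      sigma_tox = 1
    ),
    "not strictly decreasing"
  )
  expect_error(regulatory_actions(c(-8.5, -8.8), c(0.4, 0.4),
                                  cost_rank = c(1, 1)),
               "unique")
})

test_that("simple rule regulates strictly above the TRL only", {
  expect_identical(decide_simple(2e-6, 1e-6), 1L)
  expect_identical(decide_simple(1e-6, 1e-6), 0L) # boundary acceptable
  expect_identical(decide_simple(0, 1e-6), 0L)
  expect_identical(decide_simple(c(0, 1e-6, 2e-6), 1e-6), c(0L, 0L, 1L))
})

complex_from_truth <- function(mu_tox, ctx) {
  r0 <- population_risk(toxicity_profile(mu_tox, ctx$sigma_tox),
                        ctx$baseline_exposure)
  rk <- sapply(seq_len(nrow(ctx$actions)), function(k) {
    population_risk(toxicity_profile(mu_tox, ctx$sigma_tox),
                    exposure_profile(ctx$actions$mu_exp[k],
                                     ctx$actions$sigma_exp[k]))
  })
  if (is.null(dim(rk))) rk <- matrix(rk, nrow = 1)
  decide_complex(r0, rk, ctx)
}

test_that("complex rule picks the cheapest sufficient action", {
  # Low-toxicity chemical: no action needed.
  expect_identical(complex_from_truth(0, ref_ctx), 0L)
  # Highly toxic chemical: only the most stringent action suffices.
  expect_identical(complex_from_truth(-5, ref_ctx), 3L)
  # Mid-band chemical between the two decision points: action 2.
  expect_identical(complex_from_truth(-3.5, ref_ctx), 2L)
  # Inside the action-1 band.
  expect_identical(complex_from_truth(-3, ref_ctx), 1L)
  # Beyond the choice set: nothing attains the TRL.
  expect_error(complex_from_truth(-12, ref_ctx), "no compliant action")
})

test_that("risk-based complex decisions agree with potency-region lookup", {
  set.seed(3)
  mu <- runif(1000, -5, 2)
  from_risk <- complex_from_truth(mu, ref_ctx)
  from_region <- classify_potency(mu, ref_ctx)
  expect_identical(from_risk, from_region)
  # Region lookup covers the line: every potency above the last decision
  # point maps to exactly one of 0..K, and more toxic potencies never get
  # a less stringent action.
  ordered <- sort(mu, decreasing = TRUE)
  expect_true(all(diff(classify_potency(ordered, ref_ctx)) >= 0))
})

test_that("region boundaries are closed at the more-toxic end", {
  t <- ref_ctx$thresholds
  expect_identical(classify_potency(t[1], ref_ctx), 0L) # at TRL: no action
  expect_identical(classify_potency(t[2], ref_ctx), 1L)
  expect_identical(classify_potency(t[3], ref_ctx), 2L)
  expect_true(is.na(classify_potency(t[4] - 1e-9, ref_ctx)))
})
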