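test_that("simple-rule DMV has its closed-form values", {
  t0 <- ref_ctx$trl_mu_tox
  # A chemical exactly at the threshold straddles it symmetrically.
  expect_equal(dmv_simple(t0, 1, ref_ctx), 0.5)
  expect_equal(dmv_simple(t0, 0.2, ref_ctx), 0.5)
  # One uncertainty-SD above the threshold.
  expect_equal(dmv_simple(t0 + 1, 1, ref_ctx), pnorm(1))
  expect_equal(round(dmv_simple(t0 + 1, 1, ref_ctx), 4), 0.8413)
  # Perfect estimates decide perfectly off-threshold, and the degenerate
  # on-threshold point estimate matches the truth's tie-break.
  expect_equal(dmv_simple(c(t0 - 2, t0, t0 + 2), 0, ref_ctx), c(1, 1, 1))
})

test_that("complex-rule DMV matches region probabilities of the fixtures", {
  # Truth in the most-toxic region: probability of the estimate landing
  # below the action-2 decision point.
  expect_equal(round(dmv_complex(-5, 1, ref_ctx), 4), 0.9065)
  expect_equal(
    dmv_complex(-5, 1, ref_ctx),
    pnorm((ref_ctx$dp_mu_tox[2] + 5) / 1) - pnorm((ref_ctx$dp_mu_tox[3] + 5) / 1)
  )
  # Midpoint of the narrow action-2 band: the band is only 0.3 log10
  # units wide, so a unit-SD estimate rarely stays inside it.
  mid <- mean(ref_ctx$dp_mu_tox[1:2])
  expect_equal(dmv_complex(mid, 1, ref_ctx), pnorm(0.15) - pnorm(-0.15))
  expect_equal(round(dmv_complex(mid, 1, ref_ctx), 4), 0.1192)
  # Perfect estimate in any region interior.
  expect_equal(dmv_complex(c(-5, -3.5, -3, 0), 0, ref_ctx), rep(1, 4))
})

test_that("region probabilities sum to one for any chemical", {
  set.seed(5)
  mu <- runif(200, -12, 3)
  for (s in c(0.2, 1, 3)) {
    p <- toxcea:::region_probabilities(mu, s, ref_ctx)
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    expect_true(all(p >= 0))
  }
})

test_that("complex DMV never exceeds simple DMV under the fixtures", {
  # Every complex-rule region on one side of the TRL threshold is a
  # subset of that side, so region membership implies side membership.
  mu <- seq(-6, 3, by = 0.05)
  for (s in c(0.2, 1)) {
    expect_true(all(dmv_complex(mu, s, ref_ctx) <=
                      dmv_simple(mu, s, ref_ctx) + 1e-12))
  }
})

test_that("DMV approaches one far from every threshold", {
  far <- c(ref_ctx$trl_mu_tox + 10, ref_ctx$dp_mu_tox[3] - 10)
  expect_true(all(dmv_simple(far, 1, ref_ctx) > 1 - 1e-9))
  expect_true(all(dmv_complex(far, 1, ref_ctx) > 1 - 1e-9))
})

test_that("bias shifts the estimate distribution, not the truth", {
  t0 <- ref_ctx$trl_mu_tox
  # Truth one unit below the threshold, bias pushing the estimate back up
  # to it: half the estimates cross over.
  expect_equal(dmv_simple(t0 - 1, 1, ref_ctx, bias = 1), 0.5)
  expect_equal(dmv_simple(t0 - 1, 1, ref_ctx, bias = 0), pnorm(1))
})

test_that("analytic DMV agrees with the Monte-Carlo oracle", {
  grid <- seq(-4.5, -1.5, length.out = 12)
  set.seed(99)
  for (m in grid) {
    for (rule in c("simple", "complex")) {
      analytic <- if (rule == "simple") dmv_simple(m, 1, ref_ctx)
                  else dmv_complex(m, 1, ref_ctx)
      sim <- dmv_by_simulation(m, 1, ref_ctx, rule, n_draws = 2e5)
      expect_lt(abs(analytic - sim$p), 3 * sim$se + 1e-12)
    }
  }
})

test_that("methodology profiles validate their invariants", {
  expect_error(methodology("m", 0, 5, 1))
  expect_error(methodology("m", 10, 0, 1))
  expect_error(methodology("m", 10, 5, -1))
  m <- reference_methodologies()
  expect_equal(m$duration_years, c(10L, 10L, 2L, 10L, 2L))
  expect_equal(m$cost_per_chemical, c(5, 1, 5, 5, 1))
  expect_equal(m$sigma_mu_hat, c(1, 1, 1, 0.2, 0.2))
  expect_equal(m$bias, rep(0, 5))
})

test_that("compute_dmv crosses chemicals with methodologies", {
  pop <- sample_population(20, seed = 4)
  tbl <- compute_dmv(pop, ref_methods, ref_ctx)
  expect_equal(nrow(tbl), 20 * 5)
  expect_true(all(tbl$dmv_simple > 0 & tbl$dmv_simple <= 1))
  expect_true(all(tbl$dmv_complex > 0 & tbl$dmv_complex <= 1))
  # Per-methodology columns agree with direct vectorised calls.
  base <- dplyr::filter(tbl, name == "base case")
  expect_equal(base$dmv_simple, dmv_simple(base$mu_tox, 1, ref_ctx))
  expect_equal(base$dmv_complex, dmv_complex(base$mu_tox, 1, ref_ctx))
})
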