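# Reference scenario: five hypothetical toxicity-testing methodologies,
# a severe-effect target risk level, and a three-action choice set.
# Doses in log10 mg/kg/day, costs in millions of dollars, years integer.
trl: 1.0e-6
sigma_tox: 1
baseline_exposure: {mu: -8, sigma: 0.5}
actions:
  - {mu: -8.5, sigma: 0.4, cost_rank: 1}
  - {mu: -8.8, sigma: 0.4, cost_rank: 2}
  - {mu: -14.0, sigma: 0.1, cost_rank: 3}
methodologies:
  - {name: base case, duration_years: 10, cost_per_chemical: 5, sigma_mu_hat: 1, bias: 0}
  - {name: reduced cost, duration_years: 10, cost_per_chemical: 1, sigma_mu_hat: 1, bias: 0}
  - {name: reduced time, duration_years: 2, cost_per_chemical: 5, sigma_mu_hat: 1, bias: 0}
  - {name: reduced uncertainty, duration_years: 10, cost_per_chemical: 5, sigma_mu_hat: 0.2, bias: 0}
  - {name: all reduced, duration_years: 2, cost_per_chemical: 1, sigma_mu_hat: 0.2, bias: 0}
program: {annual_budget: 10, discount_rate: 0.03, horizons: [11, 20]}
population: {n: 5000, bounds: [-5, 2]}
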