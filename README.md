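# valba — discounted value accumulation in intertemporal choice

`valba` models choices between a fixed immediate reward ($10 now) and a
larger delayed one ($R in D days) as *discounted value accumulation*: a
race between two linear ballistic accumulators (LBA), one per option,
whose mean evidence-accumulation rates (drift rates) encode discounted
subjective value. It is written for decision scientists who want to fit
response-time-aware models of delay discounting, compare constraint
variants, and test whether independently estimated drift rates really
track subjective value.

## The models

**Value and choice.** Subjective value of a delayed reward follows one of
three discounting functions — hyperbolic `V = R / (1 + kD)`, exponential
`V = R exp(-kD)`, or quasi-hyperbolic `V = R·β·δ^D` — and choices follow a
softmax rule `P(delayed) = 1 / (1 + exp(-m (V_D - V_I)))` with sensitivity
`m` per dollar.

**Response times.** Each option accumulates evidence from a uniform start
point on `[0, A]` at a normally distributed rate (mean ν, sd s) until a
threshold `b`; observed RT adds a non-decision time `t0`. Drift means sum
to one across the two options, so only the delayed drift `nu_d` is
estimated, per value condition. The (choice, RT) likelihood is the
defective density: the winner's finishing density times the probability
the loser has not finished.

**Estimation.** A hierarchical Bayesian sampler combines
differential-evolution MCMC at the subject level with conjugate Gibbs
updates of group-level normal means and inverse-gamma variances
(transformed scales: log for positive parameters, logit for drifts). The
default configuration — 24 chains, 5,000 burn-in + 5,000 kept, thinned by
4 — retains 30,000 draws. Model variants M1–M8 (which parameters vary
across the five value conditions) are compared by the Bayesian predictive
information criterion, reported as the across-chain mean with its
across-chain sd.

## Worked example

```r
library(valba)

# synthetic two-session cohort with known ground truth
coh <- generate_cohort(cohort_config(n_subjects = 8, seed = 1))
flt <- filter_trials(coh$trials[coh$trials$session == 2, ])

# hierarchical fit of the drift + non-decision-time variant (desk scale)
fit <- fit_hlba(flt$kept, variant = "M2",
                control = hlba_control(n_chains = 12, burn_in = 1500,
                                       keep = 1500, thin = 4, seed = 2))
print(fit)
#> Hierarchical LBA fit, variant M2 (13 subject parameters)
#>   8 subjects, 1397 trials
#>   12 chains x (1500 burn-in + 1500 kept)/thin 4 -> 4500 retained draws
#>   mean acceptance rate 0.22; elapsed 116.5s

recovery_report(coh$truth, fit)[5, c("parameter", "coverage95", "cor_map")]
#>   parameter coverage95   cor_map
#> 5      nu_d      0.925 0.9457117
```

The last two columns say that 37 of the 40 true per-condition drift rates
fall inside their 95% credible intervals and that MAP drift estimates
correlate at r = 0.95 with the generating truth. Downstream,
`bpic()`/`model_search()` compare variants,
`consistency_rt_test()` checks that value-inconsistent choices are slower
(the slow-error signature of an elevated accumulation bound), and
`identity_tests_all_models()` tests the linkage identity
`m (V_D - 10) = β0 + β1 ν_d` — slope near 1 means drift rates are an
affine readout of discounted value whichever value function is assumed.

A command-line driver wrapping the same functions lives at
`inst/cli/valba.R` (`simulate` / `fit` / `compare` / `analyze`
subcommands, YAML configs, JSON run manifests).

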