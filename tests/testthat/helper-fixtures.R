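# shared fixtures built in code

# small, well-behaved LBA parameter set in the elevated-bound regime
fix_params <- function(nu = c(0.25, 0.4, 0.5, 0.6, 0.75)) {
  lba_params(A = 0.45, chi = 0.5, s = 0.3, t0 = 0.3, nu_d = nu)
}

# random valid parameter draws for property-style loops
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lba_params(A = runif(1, 0.2, 1), chi = runif(1, 0.2, 1.2),
               s = runif(1, 0.15, 0.5), t0 = runif(1, 0.1, 0.5),
               nu_d = runif(5, 0.15, 0.85))
  })
}

# simulated discounting choice set from a known subject
sim_choice_trials <- function(fit, n_per = 60, seed = 1) {
  set.seed(seed)
  off <- offers_for_targets(fit, counts = n_per)
  p <- softmax_prob_delayed(
    subjective_value(off$delayed_amount, off$delay_days, fit), 10, fit$m)
  data.frame(delayed_amount = off$delayed_amount,
             delay_days = off$delay_days,
             target_p = off$target_p,
             choice = rbinom(nrow(off), 1, p))
}

# tiny cohort + fast sampler settings for integration-style tests
quick_control <- function(seed = 1, n_chains = 8, burn_in = 250, keep = 250,
                          thin = 2) {
  hlba_control(n_chains = n_chains, burn_in = burn_in, keep = keep,
               thin = thin, seed = seed)
}

quiet_cohort <- function(...) suppressWarnings(generate_cohort(cohort_config(...)))
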