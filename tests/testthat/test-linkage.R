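test_that("trial filtering applies the 200 ms and decision-window rules", {
  tr <- data.frame(subject_id = "s1", session = 2,
                   condition_target_p = 0.5, delay_days = 30,
                   delayed_amount = 12, choice = 1,
                   rt_seconds = c(0.199, 0.2, 1.0, 4.0, 4.001, NA))
  flt <- filter_trials(tr)
  expect_equal(nrow(flt$kept), 3)
  expect_equal(flt$dropped$reason, c("too_fast", "outside_window",
                                     "missing_rt"))
  # idempotent
  again <- filter_trials(flt$kept)
  expect_equal(nrow(again$dropped), 0)
  expect_equal(again$kept, flt$kept)
})

test_that("condition summaries define consistency by modelled value", {
  tr <- data.frame(subject = rep("a", 6), condition = rep(c(5, 1), each = 3),
                   target_p = rep(c(0.9, 0.1), each = 3),
                   choice = c(1, 1, 0, 0, 0, 1),
                   rt = c(1, 1.2, 2.5, 0.9, 1.1, 2.2))
  tr$condition_target_p <- tr$target_p
  tr$subject_id <- tr$subject; tr$rt_seconds <- tr$rt
  sm <- condition_summary(tr)
  # p = 0.9: consistent = delayed; p = 0.1: consistent = immediate
  expect_equal(sm$median_rt_consistent[sm$target_p == 0.9], 1.1)
  expect_equal(sm$median_rt_inconsistent[sm$target_p == 0.9], 2.5)
  expect_equal(sm$median_rt_consistent[sm$target_p == 0.1], 1.0)
  expect_equal(sm$median_rt_inconsistent[sm$target_p == 0.1], 2.2)
  expect_equal(sm$min_rt, c(0.9, 1))
  expect_true(all(sm$median_rt >= sm$min_rt))
})

test_that("consistency rank test rejects degenerate inputs", {
  coh <- quiet_cohort(n_subjects = 2, seed = 31)
  flt <- filter_trials(coh$trials[coh$trials$session == 2, ])
  sm <- condition_summary(flt$kept)
  expect_error(consistency_rt_test(sm[sm$subject == sm$subject[1], ]),
               "too few")
})

test_that("quadratic value regressor takes the documented values", {
  expect_equal((c(0.1, 0.3, 0.5, 0.7, 0.9) - 0.5)^2,
               c(0.16, 0.04, 0, 0.04, 0.16))
})

test_that("t0 regressions recover a planted quadratic and detect nulls", {
  set.seed(32)
  targets <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  n_sub <- 15
  q_true <- 0.4
  df <- do.call(rbind, lapply(1:n_sub, function(s) {
    data.frame(subject = paste0("s", s), condition = 1:5,
               target_p = targets,
               t0 = 0.3 + rnorm(1, 0, 0.03) + q_true * (targets - 0.5)^2 +
                 rnorm(5, 0, 0.01))
  }))
  st <- t0_value_regression(df)
  expect_lt(abs(st$estimate - q_true), 2 * st$se)
  expect_lt(st$p_value, 0.01)
  # constant t0: slope indistinguishable from zero
  df0 <- df; df0$t0 <- 0.3 + rep(rnorm(n_sub, 0, 0.02), each = 5) +
    rnorm(nrow(df0), 0, 0.01)
  st0 <- t0_value_regression(df0)
  expect_gt(st0$p_value, 0.05)
})

test_that("t0-RT regressions recover exact and null relationships", {
  set.seed(33)
  targets <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  df <- do.call(rbind, lapply(1:12, function(s) {
    data.frame(subject = paste0("s", s), condition = 1:5,
               target_p = targets,
               min_rt = runif(5, 0.4, 0.9), median_rt = runif(5, 1, 2))
  }))
  df$t0 <- df$min_rt  # identity with min RT
  sm <- df[, c("subject", "condition", "min_rt", "median_rt")]
  res <- t0_rt_regressions(df, sm)
  expect_equal(res$min_rt$estimate, 1, tolerance = 1e-8)
  expect_gt(res$median_rt$p_value, 0.01)  # unrelated regressor
})

test_that("per-condition t0 analyses refuse variants without free t0", {
  coh <- quiet_cohort(n_subjects = 3, seed = 34)
  flt <- filter_trials(coh$trials[coh$trials$session == 2, ])
  fit <- fit_hlba(flt$kept, "M1",
                  control = hlba_control(n_chains = 6, burn_in = 40,
                                         keep = 40, thin = 2, seed = 1))
  expect_error(t0_value_regression(fit), "M2-family")
})

test_that("drift-value logistic recovers a planted sigmoidal linkage", {
  set.seed(35)
  targets <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  beta1 <- 10
  n_per <- 60
  rows <- list(); maps <- list()
  for (s in 1:12) {
    nu <- 0.5 + (targets - 0.5) * 0.45 + rnorm(5, 0, 0.02)
    b0 <- -beta1 * 0.5 + rnorm(1, 0, 0.3)
    p <- plogis(b0 + beta1 * nu)
    for (j in 1:5) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = paste0("s", s), condition = j, target_p = targets[j],
        choice = rbinom(n_per, 1, p[j]), rt = 1)
    }
    maps[[s]] <- data.frame(subject = paste0("s", s), condition = 1:5,
                            nu_d = nu)
  }
  tr <- do.call(rbind, rows)
  tr$subject_id <- tr$subject; tr$rt_seconds <- tr$rt
  tr$condition_target_p <- tr$target_p
  lk <- drift_value_logistic(tr, do.call(rbind, maps))
  expect_lt(abs(lk$group$mean_beta1 - beta1), 2.5 * lk$group$se)
  expect_lt(lk$group$p_value, 1e-4)
  # constant drift across conditions is flagged, not fitted
  maps_const <- lapply(maps, function(m) { m$nu_d <- 0.5; m })
  lk0 <- drift_value_logistic(tr, do.call(rbind, maps_const))
  expect_true(all(lk0$subjects$flag == "constant_drift"))
})

test_that("identity regression finds slope one when the linkage is exact", {
  # build a cohort where drifts are an exact affine readout of the
  # softmax linear predictor, so m (V_D - 10) = beta0 + beta1 nu_d holds
  set.seed(36)
  targets <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  rows <- list(); maps <- list(); fits <- list()
  for (s in 1:15) {
    m_s <- exp(rnorm(1, log(2), 0.2)); k_s <- exp(rnorm(1, log(0.01), 0.3))
    dfit <- discount_fit("hyperbolic", k = k_s, m = m_s)
    off <- offers_for_targets(dfit, targets, counts = 40)
    nu <- 0.5 + 0.2 * qlogis(targets) / m_s  # affine in m (V_D - 10)
    for (j in 1:5) {
      oj <- off[off$target_p == targets[j], ]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = paste0("s", s), condition_target_p = targets[j],
        delay_days = oj$delay_days, delayed_amount = oj$delayed_amount,
        choice = rbinom(nrow(oj), 1, targets[j]), rt_seconds = 1)
    }
    maps[[s]] <- data.frame(subject = paste0("s", s), condition = 1:5,
                            nu_d = nu)
    fits[[paste0("s", s)]] <- dfit
  }
  tr <- do.call(rbind, rows)
  map_df <- do.call(rbind, maps)
  lk <- drift_value_logistic(tr, map_df)
  st <- identity_test(lk, fits, tr, map_df)
  expect_lt(abs(st$estimate - 1), 0.1)
  expect_lt(st$p_value, 1e-6)
  # shuffling drifts across conditions severs the drift-choice linkage:
  # the per-subject logistic slopes lose their group-level signal
  set.seed(37)
  map_shuf <- do.call(rbind, lapply(split(map_df, map_df$subject),
                                    function(m) { m$nu_d <- sample(m$nu_d); m }))
  lk_s <- drift_value_logistic(tr, map_shuf)
  expect_gt(lk_s$group$p_value, 0.05)
})
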