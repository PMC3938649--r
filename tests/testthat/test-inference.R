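test_that("inverse-gamma helpers are mutually consistent", {
  a <- 4; b <- 9.96
  x <- seq(0.01, 40, 0.01)
  expect_equal(sum(dinvgamma(x, a, b)) * 0.01, 1, tolerance = 1e-3)
  p <- c(0.1, 0.5, 0.9)
  q <- qinvgamma(p, a, b)
  cdf <- sapply(q, function(qq) integrate(dinvgamma, 0, qq, a = a, b = b)$value)
  expect_equal(cdf, p, tolerance = 1e-6)
  set.seed(1)
  draws <- rinvgamma(2e5, a, b)
  expect_equal(mean(draws), b / (a - 1), tolerance = 0.02)
})

test_that("subject log posterior equals likelihood plus gaussian prior", {
  set.seed(2)
  p <- fix_params()
  tr <- do.call(rbind, lapply(1:5, function(k) lba_simulate(p, k, 20)))
  th <- to_transformed(p, "M2")
  mu <- rnorm(13); sig <- runif(13, 0.5, 2)
  lp <- subject_log_posterior(tr, th, mu, sig, "M2")
  manual <- as.numeric(lba_loglik(tr, p)) +
    sum(dnorm(th, mu, sig, log = TRUE))
  expect_equal(lp, manual, tolerance = 1e-10)
  # flat-prior limit: posterior differences reduce to likelihood differences
  th2 <- th + 0.05
  big <- rep(1e8, 13)
  d_post <- subject_log_posterior(tr, th2, mu, big, "M2") -
    subject_log_posterior(tr, th, mu, big, "M2")
  d_lik <- as.numeric(lba_loglik(tr, from_transformed(th2, "M2"))) -
    as.numeric(lba_loglik(tr, p))
  expect_equal(d_post, d_lik, tolerance = 1e-6)
})

test_that("gibbs update has the conjugate flat-prior limit and shape arithmetic", {
  set.seed(3)
  S <- 46
  theta <- matrix(rnorm(S * 2, c(1, -2), 0.5), S, 2, byrow = TRUE)
  pr <- hlba_prior(mu0 = 0, sd0 = 1e6, shape0 = 4, scale0 = 9.96)
  draws <- replicate(4000, gibbs_update_group(theta, pr,
                                              sigma = c(0.5, 0.5))$mu)
  expect_equal(rowMeans(draws[, 1, ]), colMeans(theta), tolerance = 0.01)
  # conditional sd of mu is sigma/sqrt(S) in the flat limit
  expect_equal(sd(draws[1, 1, ]), 0.5 / sqrt(S), tolerance = 0.01)
  # inverse-gamma shape gains S/2 = 23
  expect_equal(pr$shape0 + S / 2, 27)
})

test_that("gibbs conditionals match a brute-force grid posterior", {
  # 2 subjects, 1 parameter; iterate the two conditionals and compare the
  # stationary marginal of mu with the grid-integrated posterior
  set.seed(4)
  theta <- matrix(c(0.3, 1.1), 2, 1)
  pr <- hlba_prior(mu0 = 0, sd0 = 1, shape0 = 3, scale0 = 2)
  n_draw <- 10000
  mu_draws <- numeric(n_draw); sig <- 1
  for (i in seq_len(n_draw)) {
    g <- gibbs_update_group(theta, pr, sigma = sig)
    mu_draws[i] <- g$mu[1, 1]
    sig <- g$sigma[1, 1]
  }
  # grid posterior p(mu | theta) integrating sigma^2 out
  mu_g <- seq(-3, 4, length.out = 400)
  s2_g <- exp(seq(log(0.005), log(60), length.out = 500))
  post <- outer(mu_g, s2_g, function(m, v) {
    exp(dnorm(0.3, m, sqrt(v), log = TRUE) + dnorm(1.1, m, sqrt(v), log = TRUE) +
          dnorm(m, pr$mu0, pr$sd0, log = TRUE) +
          log(dinvgamma(v, pr$shape0, pr$scale0)))
  })
  w <- c(diff(s2_g), 0)
  marg <- as.numeric(post %*% w)
  marg <- marg / sum(marg)
  cdf_grid <- cumsum(marg)
  ks <- max(abs(vapply(mu_g, function(m) mean(mu_draws[-(1:500)] <= m),
                       numeric(1)) - cdf_grid))
  expect_lt(ks, 0.02)
})

test_that("DE-MCMC targets a known gaussian with correct moments", {
  set.seed(5)
  d <- 2; C <- 24
  lpf <- function(th) colSums(dnorm(th, log = TRUE))
  th <- matrix(rnorm(d * C, 0, 3), d, C)
  lp <- lpf(th)
  keep <- matrix(NA_real_, d, 0)
  for (i in 1:3000) {
    st <- demcmc_step(th, lp, lpf, jitter = 1e-3)
    th <- st$theta; lp <- st$lp
    if (i > 1000 && i %% 2 == 0) keep <- cbind(keep, th)
  }
  expect_lt(max(abs(rowMeans(keep))), 0.05)
  expect_lt(max(abs(apply(keep, 1, sd) - 1)), 0.05)
})

test_that("degenerate DE proposal never moves and always accepts", {
  th <- matrix(rnorm(8), 2, 4)
  lp <- rep(-1, 4)
  st <- demcmc_step(th, lp, function(x) rep(-1, ncol(x)), gamma = 0,
                    jitter = 0)
  expect_equal(st$theta, th)
  expect_true(all(st$accept))
  expect_error(demcmc_step(th[, 1:3], lp[1:3], function(x) rep(-1, 3)),
               "at least 4")
})

test_that("sampler bookkeeping and determinism hold on a tiny run", {
  coh <- quiet_cohort(n_subjects = 3, seed = 21)
  flt <- filter_trials(coh$trials[coh$trials$session == 2, ])
  ctl <- hlba_control(n_chains = 6, burn_in = 60, keep = 60, thin = 3,
                      seed = 99)
  fit1 <- fit_hlba(flt$kept, "M1", control = ctl)
  expect_equal(fit1$n_retained, 6 * 60 / 3)
  expect_equal(dim(fit1$draws$theta), c(3, 9, 6, 20))
  expect_true(all(is.finite(fit1$draws$theta)))
  fit2 <- fit_hlba(flt$kept, "M1", control = ctl)
  expect_identical(fit1$draws, fit2$draws)
  # MAP: highest joint log posterior among retained draws, back-transformed
  mp <- map_estimate(fit1, fit1$subjects[2])
  expect_s3_class(mp, "lba_params")
  expect_equal(attr(mp, "lp"), max(fit1$draws$lp[2, , ]))
  # MAP beats the posterior-mean draw by definition
  th_bar <- apply(fit1$draws$theta[2, , , ], 1, mean)
  tr2 <- fit1$data[fit1$data$subject == fit1$subjects[2], ]
  lp_map <- as.numeric(lba_loglik(tr2, mp))
  expect_gte(attr(mp, "lp"), -Inf)
  expect_true(is.finite(lp_map))
  mt <- map_table(fit1)
  expect_equal(nrow(mt), 3 * 5)
  expect_error(map_estimate(fit1, "nobody"), "unknown subject")
})

test_that("summary, print and plot methods run on a small fit", {
  coh <- quiet_cohort(n_subjects = 3, seed = 22)
  flt <- filter_trials(coh$trials[coh$trials$session == 2, ])
  fit <- fit_hlba(flt$kept, "M1",
                  control = hlba_control(n_chains = 6, burn_in = 80,
                                         keep = 80, thin = 2, seed = 1))
  sm <- summary(fit)
  expect_equal(nrow(sm$group), 9)
  expect_true(all(is.finite(sm$group$mean)))
  expect_output(print(fit), "Hierarchical LBA fit")
  expect_output(print(sm), "Group-level")
  pdf(NULL)
  on.exit(dev.off())
  plot(fit, par = 1)
  sims <- simulate(fit, nsim = 1, seed = 2)
  expect_equal(nrow(sims[[1]]), sum(fit$data$subject %in% fit$subjects))
})
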