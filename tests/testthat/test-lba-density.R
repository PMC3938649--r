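test_that("node CDF has the right limits and is monotone", {
  # limit mass: probability the drift is positive
  expect_equal(lba_node_cdf(1e6, A = 1, b = 2, nu = 0.7, s = 0.3),
               pnorm(0.7 / 0.3), tolerance = 1e-6)
  expect_equal(lba_node_cdf(1e-9, A = 1, b = 2, nu = 0.7, s = 0.3), 0,
               tolerance = 1e-8)
  expect_equal(lba_node_cdf(0, A = 1, b = 2, nu = 0.7, s = 0.3), 0)
  set.seed(1)
  for (i in 1:10) {
    A <- runif(1, 0.2, 1); b <- A + runif(1, 0.1, 1.5)
    nu <- runif(1, 0.1, 0.9); s <- runif(1, 0.15, 0.5)
    grid <- seq(1e-3, 20, length.out = 1000)
    F <- lba_node_cdf(grid, A, b, nu, s)
    expect_true(all(diff(F) >= -1e-12))
    expect_true(all(F >= 0 & F <= 1))
  }
})

test_that("node PDF differentiates the CDF and integrates to the finishing mass", {
  set.seed(2)
  for (i in 1:100) {
    A <- runif(1, 0.2, 1); b <- A + runif(1, 0.1, 1.5)
    nu <- runif(1, 0.1, 0.9); s <- runif(1, 0.15, 0.5)
    t <- runif(1, 0.2, 6)
    h <- 1e-5
    fd <- (lba_node_cdf(t + h, A, b, nu, s) -
             lba_node_cdf(t - h, A, b, nu, s)) / (2 * h)
    expect_equal(lba_node_pdf(t, A, b, nu, s), fd, tolerance = 1e-5)
  }
  q <- integrate(lba_node_pdf, 0, Inf, A = 0.5, b = 1.2, nu = 0.6, s = 0.3,
                 rel.tol = 1e-10)
  expect_equal(q$value, pnorm(0.6 / 0.3), tolerance = 1e-6)
  expect_equal(lba_node_pdf(-1, 0.5, 1.2, 0.6, 0.3), 0)
})

test_that("R and C++ defective-density paths agree", {
  set.seed(3)
  p <- fix_params()
  rt <- runif(200, 0.35, 3.5)
  cond <- sample(1:5, 200, replace = TRUE)
  ch <- sample(0:1, 200, replace = TRUE)
  tr <- data.frame(rt = rt, choice = ch, condition = cond)
  ll_c <- as.numeric(lba_loglik(tr, p))
  g_r <- numeric(200)
  for (i in 1:200) g_r[i] <- lba_defective_pdf(rt[i], ch[i], p, cond[i])
  expect_equal(ll_c, sum(pmax(log(g_r), -700)), tolerance = 1e-10)
})

test_that("defective density is symmetric at nu = 0.5 and zero below t0", {
  p <- fix_params(nu = rep(0.5, 5))
  t <- seq(0.4, 3, 0.1)
  expect_equal(lba_defective_pdf(t, "delayed", p, 3),
               lba_defective_pdf(t, "immediate", p, 3))
  expect_equal(lba_defective_pdf(p$t0[1], 1, p, 1), 0)
  expect_error(lba_defective_pdf(1, 1, p, 7), "condition")
})

test_that("defective densities conserve total response mass", {
  for (p in random_params(10, seed = 4)) {
    cond <- sample(1:5, 1)
    tot <- integrate(function(u) lba_defective_pdf(u, 1, p, cond) +
                       lba_defective_pdf(u, 0, p, cond),
                     p$t0[cond], Inf, rel.tol = 1e-9)$value
    expect_equal(tot, lba_total_mass(p, cond), tolerance = 1e-5)
  }
})

test_that("choice probability is coherent and matches simulation", {
  p <- fix_params(nu = rep(0.5, 5))
  expect_equal(lba_choice_prob(p, 1, "delayed"), 0.5, tolerance = 1e-8)
  p2 <- fix_params(nu = rep(0.98, 5))
  expect_gt(lba_choice_prob(p2, 1, "delayed"), 0.95)
  p3 <- fix_params()
  for (cond in c(1, 4)) {
    pd <- lba_choice_prob(p3, cond, "delayed")
    pa <- lba_choice_prob(p3, cond, "immediate")
    expect_equal(pd + pa, 1, tolerance = 1e-8)
    sim <- lba_simulate(p3, cond, 2e4, seed = cond)
    expect_lt(abs(mean(sim$choice) - pd), 3 * sqrt(pd * (1 - pd) / 2e4) + 0.002)
  }
})

test_that("simulator respects construction invariants", {
  p <- fix_params()
  sim <- lba_simulate(p, 2, 500, seed = 9)
  expect_true(all(sim$rt > p$t0[2]))
  expect_identical(sim, lba_simulate(p, 2, 500, seed = 9))
  expect_true(all(sim$choice %in% 0:1))
})

test_that("elevated bound produces slow errors (inconsistent slower)", {
  p <- fix_params()
  sim <- lba_simulate(p, 5, 2e4, seed = 10)  # delayed-favoured condition
  expect_gt(median(sim$rt[sim$choice == 0]), median(sim$rt[sim$choice == 1]))
  sim <- lba_simulate(p, 1, 2e4, seed = 11)  # immediate-favoured
  expect_gt(median(sim$rt[sim$choice == 1]), median(sim$rt[sim$choice == 0]))
})

test_that("log-likelihood is additive and floors impossible trials", {
  p <- fix_params()
  tr1 <- data.frame(rt = 1.2, choice = 1L, condition = 3L)
  ll1 <- as.numeric(lba_loglik(tr1, p))
  expect_equal(ll1, log(lba_defective_pdf(1.2, 1, p, 3)))
  tr2 <- rbind(tr1, tr1)
  expect_equal(as.numeric(lba_loglik(tr2, p)), 2 * ll1)
  tr_bad <- data.frame(rt = 0.05, choice = 1L, condition = 3L)  # below t0
  ll_bad <- lba_loglik(tr_bad, p)
  expect_equal(as.numeric(ll_bad), -700)
  expect_equal(attr(ll_bad, "n_floored"), 1L)
  expect_error(lba_loglik(tr1[0, ], p), "empty")
})

test_that("likelihood peaks near the generating parameters", {
  p <- fix_params()
  set.seed(12)
  wins <- 0
  for (r in 1:20) {
    tr <- do.call(rbind, lapply(1:5, function(k) lba_simulate(p, k, 100)))
    ll_true <- as.numeric(lba_loglik(tr, p))
    p_pert <- p
    p_pert$nu_d <- pmin(pmax(p$nu_d + runif(5, -0.15, 0.15), 0.05), 0.95)
    p_pert$t0 <- p$t0 * runif(1, 0.7, 1.3)
    wins <- wins + (ll_true >= as.numeric(lba_loglik(tr, p_pert)))
  }
  expect_gte(wins, 15)
})

test_that("parameter constructor validates its domain", {
  expect_error(lba_params(A = -1, chi = 1, s = 0.3, t0 = 0.3, nu_d = 0.5), "A")
  expect_error(lba_params(A = 1, b = 0.5, s = 0.3, t0 = 0.3, nu_d = 0.5),
               "threshold")
  expect_error(lba_params(A = 1, chi = 1, s = 0.3, t0 = 0.3, nu_d = 1.2),
               "nu_d")
  p <- lba_params(A = 1, b = 2, s = 0.3, t0 = 0.3, nu_d = 0.5)
  expect_equal(p$chi, rep(1, 5))
})
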