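#' Sampler configuration for the hierarchical fit
#'
#' Defaults mirror the estimation protocol: 24 chains, 5,000 burn-in and
#' 5,000 kept iterations per chain, thinned by 4, giving 30,000 retained
#' posterior draws in total.
#'
#' @param n_chains number of DE-MCMC chains (>= 4).
#' @param burn_in discarded iterations per chain.
#' @param keep post-burn-in iterations per chain.
#' @param thin retain every `thin`-th kept iteration.
#' @param gamma DE proposal scale; default `2.38/sqrt(2 d)` with `d` the
#'   per-subject parameter count.
#' @param jitter uniform proposal noise half-width.
#' @param seed RNG seed; the entire fit is reproducible from it.
#' @param retry_cap maximum re-initialisation attempts per chain.
#' @param progress print progress messages.
#' @return list of class `hlba_control`.
#' @export
hlba_control <- function(n_chains = 24, burn_in = 5000, keep = 5000,
                         thin = 4, gamma = NULL, jitter = 1e-3, seed = 1,
                         retry_cap = 100, progress = FALSE) {
  stopifnot(n_chains >= 4, burn_in >= 0, keep >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in), keep = as.integer(keep),
                 thin = as.integer(thin), gamma = gamma, jitter = jitter,
                 seed = as.integer(seed), retry_cap = retry_cap,
                 progress = progress),
            class = "hlba_control")
}

#' Retained draw count implied by a sampler configuration
#'
#' `n_chains * floor(keep / thin)`: every chain contributes its kept
#' iterations after thinning. The default configuration retains
#' `24 * 5000 / 4 = 30000` draws.
#'
#' @param control an [hlba_control].
#' @return integer total retained draws.
#' @export
n_retained <- function(control) {
  control$n_chains * (control$keep %/% control$thin)
}

#' Subject-level log posterior on the transformed scale
#'
#' Data log-likelihood of the back-transformed parameters plus the
#' normal group prior evaluated parameter-wise:
#' `lba_loglik(trials, from_transformed(theta)) +
#'  sum(dnorm(theta, group_mu, group_sigma, log = TRUE))`.
#'
#' @param trials one subject's trials (`rt`, `choice`, `condition`).
#' @param theta transformed parameter vector.
#' @param group_mu,group_sigma group-level means and sds per parameter.
#' @param variant variant name or [variant_spec].
#' @return scalar log posterior (up to the group-level normalising terms).
#' @export
subject_log_posterior <- function(trials, theta, group_mu, group_sigma,
                                  variant = "M2") {
  spec <- as_variant(variant)
  stopifnot(all(is.finite(theta)))
  ll <- lba_loglik(trials, from_transformed(theta, spec))
  as.numeric(ll) + sum(dnorm(theta, group_mu, group_sigma, log = TRUE))
}

normalize_trials <- function(trials) {
  nm <- names(trials)
  subj <- if ("subject_id" %in% nm) trials$subject_id else trials$subject
  rt <- if ("rt_seconds" %in% nm) trials$rt_seconds else trials$rt
  if (is.null(subj) || is.null(rt) || is.null(trials$choice)) {
    stop("trials need subject, choice and rt columns")
  }
  if ("condition" %in% nm) {
    cond <- as.integer(trials$condition)
    tp <- if ("condition_target_p" %in% nm) trials$condition_target_p else NA
  } else if ("condition_target_p" %in% nm) {
    lev <- sort(unique(trials$condition_target_p))
    cond <- match(trials$condition_target_p, lev)
    tp <- trials$condition_target_p
  } else stop("trials need a condition or condition_target_p column")
  out <- data.frame(subject = subj, condition = cond, target_p = tp,
                    choice = as.integer(trials$choice), rt = as.numeric(rt))
  if (any(!out$choice %in% 0:1)) stop("choice must be 0/1")
  if (any(is.na(out$rt) | out$rt <= 0)) {
    stop("all rts must be positive; run filter_trials() first")
  }
  out
}

#' Fit the hierarchical Bayesian LBA model
#'
#' Estimates subject-level LBA parameters and group-level means and
#' dispersions jointly. Each iteration runs one differential-evolution
#' MCMC sweep per subject (all chains updated against the current
#' group-level parameters) followed by a conjugate Gibbs update of the
#' group-level normal means and inverse-gamma dispersions; every chain
#' carries its own group-level state, updated from that chain's subject
#' draws. Burn-in draws are discarded and the remainder thinned.
#'
#' @param trials trial table covering all subjects; columns `subject_id`
#'   (or `subject`), `condition_target_p` (or `condition`), `choice`
#'   (1 = delayed), `rt_seconds` (or `rt`). Apply [filter_trials()] first.
#' @param variant model variant name (see [variant_spec()]).
#' @param prior an [hlba_prior].
#' @param control an [hlba_control].
#' @return an object of class `hlba_fit` containing the retained draws
#'   (`$draws`: subject parameters `theta` `[S, d, C, K]` on the
#'   transformed scale, group `mu`/`sigma` `[d, C, K]`, per-subject data
#'   log-likelihoods `loglik` and joint log posteriors `lp` `[S, C, K]`),
#'   acceptance rates, the configuration echo and the data.
#' @export
fit_hlba <- function(trials, variant = "M2", prior = hlba_prior(),
                     control = hlba_control()) {
  spec <- as_variant(variant)
  dat <- normalize_trials(trials)
  subjects <- unique(dat$subject)
  S <- length(subjects)
  if (S < 2) stop("hierarchical fit needs at least 2 subjects")
  nc <- sort(unique(dat$condition))
  if (!identical(nc, 1:5)) stop("expected conditions 1..5 in the data")
  by_s <- lapply(subjects, function(id) {
    d <- dat[dat$subject == id, ]
    if (length(unique(d$condition)) != 5) {
      stop("subject ", id, " is missing value conditions")
    }
    list(rt = d$rt, choice = d$choice, cond = d$condition)
  })

  C <- control$n_chains
  d <- spec$n_params
  # block-wise DE updates: structural parameters (A, chi, s, t0) and
  # drift rates get separate proposals with dimension-scaled DE factors
  blocks <- list(list(name = "struct", idx = seq_len(d - 5L)),
                 list(name = "nu", idx = (d - 4L):d))
  gammas <- lapply(setNames(blocks, vapply(blocks, `[[`, "", "name")),
                   function(bl) {
                     if (is.null(control$gamma)) 2.38 / sqrt(2 * length(bl$idx))
                     else control$gamma
                   })
  names(gammas) <- vapply(blocks, `[[`, "", "name")
  jitter <- control$jitter
  set.seed(control$seed)

  ll_fn <- function(s, th) {
    dec <- decode_chains(th, spec)
    lba_loglik_chains_cpp(by_s[[s]]$rt, by_s[[s]]$choice, by_s[[s]]$cond,
                          dec$A, dec$b, dec$s, dec$t0, dec$nu, -700)
  }

  # initialisation: a cheap per-subject penalised maximum-likelihood point
  # (weak pre-coupling normal prior as regulariser), found from heuristic
  # starts anchored at data moments; chains start jittered around it.
  # Re-drawn from the pre-coupling prior on failure (floored likelihood).
  start_point <- function(s) {
    minrt <- min(by_s[[s]]$rt)
    p_hat <- vapply(1:5, function(k) {
      ch <- by_s[[s]]$choice[by_s[[s]]$cond == k]
      min(max(mean(ch), 0.05), 0.95)
    }, numeric(1))
    nu0 <- qlogis(pmin(pmax(0.5 + qnorm(p_hat) * 0.3 / sqrt(2), 0.1), 0.9))
    x0 <- numeric(d)
    x0[spec$idx$A] <- log(0.75); x0[spec$idx$chi] <- log(0.9)
    x0[spec$idx$s] <- log(0.3); x0[spec$idx$t0] <- log(0.5 * minrt)
    x0[spec$idx$nu] <- nu0
    obj <- function(x) {
      -(ll_fn(s, matrix(x, d, 1))[1] +
          sum(dnorm(x, prior$init_mean, prior$init_sd, log = TRUE)))
    }
    opt <- tryCatch(nlminb(x0, obj, control = list(iter.max = 200)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) x0 else opt$par
  }
  init_one <- function(s) {
    th <- start_point(s) + matrix(rnorm(d * C, 0, 0.25), d, C)
    ll <- ll_fn(s, th)
    bad <- which(ll <= -600 * length(by_s[[s]]$rt))
    tries <- 0
    while (length(bad) && tries < control$retry_cap) {
      th[, bad] <- rnorm(d * length(bad), prior$init_mean, prior$init_sd)
      ll[bad] <- ll_fn(s, th[, bad, drop = FALSE])
      bad <- which(ll <= -600 * length(by_s[[s]]$rt))
      tries <- tries + 1
    }
    if (length(bad)) stop("could not initialise finite log posterior for subject ",
                          subjects[s], " within the retry cap")
    list(theta = th, ll = ll)
  }

  theta <- vector("list", S); ll <- vector("list", S)
  for (s in seq_len(S)) {
    ini <- init_one(s)
    theta[[s]] <- ini$theta
    ll[[s]] <- ini$ll
  }
  mu <- matrix(rowMeans(do.call(cbind, lapply(theta, rowMeans))), d, C)
  sigma <- matrix(1, d, C)
  lpr <- lapply(theta, function(th) colSums(dnorm(th, mu, sigma, log = TRUE)))

  burn <- control$burn_in; keep <- control$keep; thin <- control$thin
  K <- keep %/% thin
  theta_draws <- array(NA_real_, c(S, d, C, K))
  mu_draws <- array(NA_real_, c(d, C, K))
  sigma_draws <- array(NA_real_, c(d, C, K))
  ll_draws <- array(NA_real_, c(S, C, K))
  lp_draws <- array(NA_real_, c(S, C, K))
  accept_n <- matrix(0, S, C)

  n_iter <- burn + keep
  theta_arr <- array(NA_real_, c(S, d, C))
  k <- 0L
  t_start <- proc.time()[3]
  for (it in seq_len(n_iter)) {
    for (s in seq_len(S)) {
      for (bl in blocks) {
        th <- theta[[s]]
        pairs <- vapply(seq_len(C),
                        function(i) sample(seq_len(C)[-i], 2L), integer(2))
        # randomised DE scale with occasional near-unit mode-jumping
        # moves keeps small chain populations dispersed
        g_it <- if (runif(1) < 0.1) 0.98
                else runif(1, 0.5, 1) * gammas[[bl$name]]
        prop <- th
        prop[bl$idx, ] <- th[bl$idx, , drop = FALSE] +
          g_it * (th[bl$idx, pairs[1, ], drop = FALSE] -
                    th[bl$idx, pairs[2, ], drop = FALSE]) +
          matrix(runif(length(bl$idx) * C, -jitter, jitter),
                 length(bl$idx), C)
        ll_prop <- ll_fn(s, prop)
        lpr_prop <- colSums(dnorm(prop, mu, sigma, log = TRUE))
        acc <- log(runif(C)) < (ll_prop + lpr_prop) - (ll[[s]] + lpr[[s]])
        if (any(acc)) {
          theta[[s]][, acc] <- prop[, acc]
          ll[[s]][acc] <- ll_prop[acc]
          lpr[[s]][acc] <- lpr_prop[acc]
          if (it > burn) accept_n[s, acc] <- accept_n[s, acc] + 1
        }
      }
    }
    for (s in seq_len(S)) theta_arr[s, , ] <- theta[[s]]
    g <- gibbs_update_group(theta_arr, prior, sigma)
    mu <- g$mu; sigma <- g$sigma
    for (s in seq_len(S)) {
      lpr[[s]] <- colSums(dnorm(theta[[s]], mu, sigma, log = TRUE))
    }
    if (it > burn && (it - burn) %% thin == 0L) {
      k <- k + 1L
      theta_draws[, , , k] <- theta_arr
      mu_draws[, , k] <- mu
      sigma_draws[, , k] <- sigma
      for (s in seq_len(S)) {
        ll_draws[s, , k] <- ll[[s]]
        lp_draws[s, , k] <- ll[[s]] + lpr[[s]]
      }
    }
    if (control$progress && it %% max(1, n_iter %/% 10) == 0) {
      message(sprintf("  iteration %d/%d (%.0fs)", it, n_iter,
                      proc.time()[3] - t_start))
    }
  }

  target_map <- unique(dat[, c("condition", "target_p")])
  target_map <- target_map[order(target_map$condition), ]
  structure(list(
    draws = list(theta = theta_draws, mu = mu_draws, sigma = sigma_draws,
                 loglik = ll_draws, lp = lp_draws),
    variant = spec,
    prior = prior,
    control = control,
    gamma = unlist(gammas),
    subjects = subjects,
    target_p = target_map$target_p,
    data = dat,
    accept_rate = accept_n / (keep * length(blocks)),
    n_retained = C * K,
    elapsed = proc.time()[3] - t_start
  ), class = "hlba_fit")
}

#' Maximum a posteriori estimate for one subject
#'
#' Returns the retained draw with the highest joint log posterior for the
#' subject, back-transformed to the natural scale.
#'
#' @param fit an [fit_hlba()] result.
#' @param subject subject id (or index into `fit$subjects`).
#' @return an [lba_params] with attribute `lp` (the achieved log
#'   posterior).
#' @export
map_estimate <- function(fit, subject) {
  s <- match_subject(fit, subject)
  lp <- fit$draws$lp[s, , , drop = FALSE][1, , ]
  lp <- matrix(lp, dim(fit$draws$lp)[2], dim(fit$draws$lp)[3])
  idx <- arrayInd(which.max(lp), dim(lp))
  th <- fit$draws$theta[s, , idx[1], idx[2]]
  out <- from_transformed(th, fit$variant)
  attr(out, "lp") <- max(lp)
  out
}

match_subject <- function(fit, subject) {
  s <- if (is.numeric(subject) && !subject %in% fit$subjects) subject
       else match(subject, fit$subjects)
  if (is.na(s) || s < 1 || s > length(fit$subjects)) {
    stop("unknown subject: ", subject)
  }
  as.integer(s)
}

#' MAP parameter table across subjects and conditions
#'
#' @param fit an `hlba_fit`.
#' @return data frame with one row per subject x condition holding the MAP
#'   `A`, `b`, `s`, `t0`, `nu_d` and the condition's target probability.
#' @export
map_table <- function(fit) {
  do.call(rbind, lapply(seq_along(fit$subjects), function(s) {
    p <- map_estimate(fit, fit$subjects[s])
    data.frame(subject = fit$subjects[s], condition = 1:5,
               target_p = fit$target_p, A = p$A, b = p$b, s = p$s,
               t0 = p$t0, nu_d = p$nu_d)
  }))
}

#' @export
coef.hlba_fit <- function(object, ...) map_table(object)

#' @export
print.hlba_fit <- function(x, ...) {
  ctl <- x$control
  cat(sprintf("Hierarchical LBA fit, variant %s (%d subject parameters)\n",
              x$variant$name, x$variant$n_params))
  cat(sprintf("  %d subjects, %d trials\n", length(x$subjects), nrow(x$data)))
  cat(sprintf("  %d chains x (%d burn-in + %d kept)/thin %d -> %d retained draws\n",
              ctl$n_chains, ctl$burn_in, ctl$keep, ctl$thin, x$n_retained))
  cat(sprintf("  mean acceptance rate %.2f; elapsed %.1fs\n",
              mean(x$accept_rate), x$elapsed))
  invisible(x)
}

#' @export
summary.hlba_fit <- function(object, ...) {
  d <- dim(object$draws$mu)[1]
  tab <- data.frame(parameter = object$variant$par_names,
                    mean = NA_real_, sd = NA_real_, q2.5 = NA_real_,
                    q97.5 = NA_real_, rhat = NA_real_, ess = NA_real_)
  for (p in seq_len(d)) {
    x <- object$draws$mu[p, , ]
    tab$mean[p] <- mean(x); tab$sd[p] <- sd(x)
    tab$q2.5[p] <- quantile(x, 0.025); tab$q97.5[p] <- quantile(x, 0.975)
    tab$rhat[p] <- split_rhat(x)
    tab$ess[p] <- ess_basic(x)
  }
  structure(list(group = tab, fit = object), class = "summary.hlba_fit")
}

#' @export
print.summary.hlba_fit <- function(x, ...) {
  print(x$fit)
  cat("\nGroup-level posterior means (transformed scale):\n")
  tab <- x$group
  tab[, -1] <- round(tab[, -1], 3)
  print(tab, row.names = FALSE)
  if (any(x$group$rhat > 1.1, na.rm = TRUE)) {
    cat("\nNote: some split-Rhat values exceed 1.1; consider longer runs.\n")
  }
  invisible(x)
}

#' @export
plot.hlba_fit <- function(x, par = 1, what = c("trace", "density"), ...) {
  what <- match.arg(what)
  draws <- x$draws$mu[par, , , drop = FALSE]
  C <- dim(draws)[2]; K <- dim(draws)[3]
  m <- t(matrix(draws, C, K))
  nm <- x$variant$par_names[par]
  if (what == "trace") {
    graphics::matplot(m, type = "l", lty = 1, xlab = "retained iteration",
                      ylab = paste("group mean", nm),
                      main = paste("Trace:", nm), ...)
  } else {
    graphics::plot(stats::density(as.numeric(m)), main = paste("Posterior:", nm),
                   xlab = nm, ...)
  }
  invisible(x)
}

#' Posterior predictive simulation
#'
#' Simulates new trials for each subject from randomly selected retained
#' posterior draws, mirroring each subject's observed per-condition trial
#' counts.
#'
#' @param object an `hlba_fit`.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `nsim` trial data frames.
#' @export
simulate.hlba_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(object$draws$theta)
  C <- dims[3]; K <- dims[4]
  counts <- table(object$data$subject, object$data$condition)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    sim <- list()
    for (s in seq_along(object$subjects)) {
      ci <- sample.int(C, 1); ki <- sample.int(K, 1)
      p <- from_transformed(object$draws$theta[s, , ci, ki], object$variant)
      id <- object$subjects[s]
      for (cond in 1:5) {
        n <- counts[as.character(id), as.character(cond)]
        if (n > 0) {
          tr <- lba_simulate(p, cond, n)
          tr$subject <- id
          sim[[length(sim) + 1]] <- tr
        }
      }
    }
    out[[r]] <- do.call(rbind, sim)
  }
  out
}

split_rhat <- function(x) {
  # x: chains x draws matrix
  x <- as.matrix(x)
  K <- ncol(x)
  if (K < 4) return(NA_real_)
  half <- K %/% 2
  sub <- rbind(x[, seq_len(half)], x[, (K - half + 1):K])
  m <- nrow(sub); n <- ncol(sub)
  means <- rowMeans(sub)
  B <- n * stats::var(means)
  W <- mean(apply(sub, 1, stats::var))
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x) {
  # crude multi-chain ESS from pooled lag-1 autocorrelation
  x <- as.matrix(x)
  rho <- mean(apply(x, 1, function(v) {
    if (stats::sd(v) == 0) return(1)
    stats::cor(v[-1], v[-length(v)])
  }), na.rm = TRUE)
  rho <- min(max(rho, 0), 0.999)
  length(x) * (1 - rho) / (1 + rho)
}
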