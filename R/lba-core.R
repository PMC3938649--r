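#' Linear ballistic accumulator subject parameters
#'
#' Container for one subject's LBA parameters across the five value
#' conditions. The threshold is parameterised as `b = A + chi` with
#' `chi > 0`, which guarantees the threshold exceeds the start-point range.
#' The delayed and immediate accumulators' mean drifts are constrained to
#' sum to one, so only the delayed drift `nu_d` is stored.
#'
#' @param A start-point range (evidence units, > 0); scalar or length 5.
#' @param b response threshold (> A); scalar or length 5. Give either `b`
#'   or `chi`.
#' @param chi threshold gap `b - A` (> 0); scalar or length 5.
#' @param s drift-rate standard deviation (evidence/second, > 0); scalar or
#'   length 5.
#' @param t0 non-decision time in seconds (>= 0); scalar or length 5.
#' @param nu_d mean drift of the delayed accumulator, in (0, 1); scalar or
#'   length 5 (one per value condition).
#' @return an object of class `lba_params` whose fields are all length-5
#'   vectors (scalars are recycled across conditions).
#' @export
lba_params <- function(A, b = NULL, chi = NULL, s, t0, nu_d) {
  if (is.null(chi)) {
    if (is.null(b)) stop("supply either b or chi")
    chi <- b - A
  }
  A <- rep_len(A, 5); chi <- rep_len(chi, 5); s <- rep_len(s, 5)
  t0 <- rep_len(t0, 5); nu_d <- rep_len(nu_d, 5)
  if (any(A <= 0)) stop("A must be positive")
  if (any(chi <= 0)) stop("threshold must exceed the start-point range (chi > 0)")
  if (any(s <= 0)) stop("s must be positive")
  if (any(t0 < 0)) stop("t0 must be non-negative")
  if (any(nu_d <= 0 | nu_d >= 1)) stop("nu_d must lie strictly in (0, 1)")
  structure(list(A = A, chi = chi, b = A + chi, s = s, t0 = t0, nu_d = nu_d),
            class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA subject parameters (5 value conditions)\n")
  m <- rbind(A = x$A, b = x$b, s = x$s, t0 = x$t0, nu_d = x$nu_d)
  colnames(m) <- paste0("c", 1:5)
  print(round(m, 4))
  invisible(x)
}

#' Single-accumulator finishing-time distribution
#'
#' Closed-form CDF and PDF of the time at which one linear ballistic
#' accumulator (start point uniform on `[0, A]`, drift normal with mean
#' `nu` and sd `s`, threshold `b`) reaches threshold. The distribution is
#' defective: its total mass is \eqn{\Phi(\nu/s)}, the probability the
#' drift is positive. Times at or below zero have zero density/mass.
#'
#' @param t decision time in seconds (vectorised).
#' @param A start-point range (> 0).
#' @param b threshold (>= A).
#' @param nu mean drift rate.
#' @param s drift standard deviation (> 0).
#' @return `lba_node_cdf`: finishing probability by time `t`;
#'   `lba_node_pdf`: finishing-time density (1/seconds).
#' @export
lba_node_cdf <- function(t, A, b, nu, s) {
  stopifnot(A > 0, s > 0, b >= A)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    tt <- t[pos]; ts <- tt * s
    u1 <- b - A - tt * nu; u2 <- b - tt * nu
    F <- 1 + (u1 / A) * pnorm(u1 / ts) - (u2 / A) * pnorm(u2 / ts) +
      (ts / A) * dnorm(u1 / ts) - (ts / A) * dnorm(u2 / ts)
    out[pos] <- pmin(pmax(F, 0), 1)
  }
  out
}

#' @rdname lba_node_cdf
#' @export
lba_node_pdf <- function(t, A, b, nu, s) {
  stopifnot(A > 0, s > 0, b >= A)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    tt <- t[pos]; ts <- tt * s
    z1 <- (b - A - tt * nu) / ts; z2 <- (b - tt * nu) / ts
    f <- (-nu * pnorm(z1) + s * dnorm(z1) + nu * pnorm(z2) - s * dnorm(z2)) / A
    out[pos] <- pmax(f, 0)
  }
  out
}

#' Defective response-time density of the two-accumulator race
#'
#' Density of responding with `choice` at time `rt` (measured from decision
#' onset): the chosen accumulator finishes at `rt - t0` while the other has
#' not yet finished. Integrating over all times gives that option's choice
#' probability; the two integrals sum to the probability that at least one
#' drift is positive (the density is left un-renormalised, the standard
#' LBA convention).
#'
#' @param rt response time in seconds (vectorised).
#' @param choice `"delayed"` / 1 or `"immediate"` / 0.
#' @param params an [lba_params] object.
#' @param condition value-condition index in 1..5.
#' @return density values (0 for `rt <= t0`).
#' @export
lba_defective_pdf <- function(rt, choice, params, condition) {
  condition <- as.integer(condition)
  if (length(condition) != 1 || is.na(condition) || condition < 1 || condition > 5) {
    stop("condition must be a single index in 1..5")
  }
  ch <- normalize_choice(choice)
  nu_w <- if (ch == 1L) params$nu_d[condition] else 1 - params$nu_d[condition]
  A <- params$A[condition]; b <- params$b[condition]
  s <- params$s[condition]; t0 <- params$t0[condition]
  t <- rt - t0
  lba_node_pdf(t, A, b, nu_w, s) * (1 - lba_node_cdf(t, A, b, 1 - nu_w, s))
}

normalize_choice <- function(choice) {
  if (is.character(choice)) {
    match.arg(choice, c("immediate", "delayed"))
    return(if (choice == "delayed") 1L else 0L)
  }
  ch <- as.integer(choice)
  if (!all(ch %in% c(0L, 1L))) stop("choice must be 0/1 or immediate/delayed")
  ch
}

#' Model-implied choice probability
#'
#' Integrates the defective response-time density over all times and
#' normalises by the total response probability, so that the delayed and
#' immediate probabilities sum to one.
#'
#' @inheritParams lba_defective_pdf
#' @param rel.tol quadrature relative tolerance.
#' @return probability of the requested choice.
#' @export
lba_choice_prob <- function(params, condition, choice = "delayed",
                            rel.tol = 1e-9) {
  ch <- normalize_choice(choice)
  t0 <- params$t0[condition]
  mass <- function(chv) {
    q <- integrate(function(u) lba_defective_pdf(u + t0, chv, params, condition),
                   0, Inf, rel.tol = rel.tol, abs.tol = 1e-12,
                   stop.on.error = FALSE)
    if (q$message != "OK" && q$abs.error > 1e-5) {
      stop("quadrature did not converge: ", q$message,
           " (abs.error ", signif(q$abs.error, 3), ")")
    }
    q$value
  }
  pd <- mass(1L)
  pa <- mass(0L)
  if (ch == 1L) pd / (pd + pa) else pa / (pd + pa)
}

#' Solve for the delayed drift attaining a target choice probability
#'
#' Finds `nu_d` in (0, 1) such that the model-implied probability of the
#' delayed choice equals `target`, holding `A`, `b`, `s` fixed. Used by the
#' synthetic-cohort generator's exact drift-value linkage mode.
#'
#' @param target desired delayed-choice probability.
#' @param params an [lba_params] object supplying `A`, `b`, `s` (its
#'   `nu_d` entry for `condition` is ignored).
#' @param condition condition index in 1..5.
#' @param interval search interval for `nu_d`.
#' @return the solving `nu_d`.
#' @export
lba_solve_drift <- function(target, params, condition,
                            interval = c(0.02, 0.98)) {
  f <- function(nu) {
    p <- params; p$nu_d[condition] <- nu
    lba_choice_prob(p, condition, "delayed", rel.tol = 1e-8) - target
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo > 0 || hi < 0) {
    stop(sprintf(
      "target p = %.3f unreachable for A=%.3f b=%.3f s=%.3f (range %.4f..%.4f)",
      target, params$A[condition], params$b[condition], params$s[condition],
      lo + target, hi + target))
  }
  uniroot(f, interval, tol = 1e-9)$root
}

#' Simulate LBA trials
#'
#' Draws trials from the two-accumulator race: start points uniform on
#' `[0, A]` and drifts normal `(nu, s)` independently per accumulator;
#' the response is the accumulator reaching threshold first and the RT is
#' `t0` plus its finishing time. Trials on which both drifts are
#' non-positive are redrawn (their count is returned as an attribute).
#' Exact finishing-time ties are broken toward the delayed accumulator.
#'
#' @param params an [lba_params] object.
#' @param condition condition index in 1..5.
#' @param n number of trials.
#' @param seed optional RNG seed.
#' @return data frame with columns `condition`, `choice` (1 = delayed),
#'   `rt` (seconds); attribute `n_redrawn` counts redraws.
#' @export
lba_simulate <- function(params, condition, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  A <- params$A[condition]; b <- params$b[condition]
  s <- params$s[condition]; t0 <- params$t0[condition]
  nu_d <- params$nu_d[condition]; nu_a <- 1 - nu_d
  td <- ta <- numeric(n)
  todo <- seq_len(n)
  n_redrawn <- 0L
  while (length(todo)) {
    m <- length(todo)
    pd <- runif(m, 0, A); pa <- runif(m, 0, A)
    vd <- rnorm(m, nu_d, s); va <- rnorm(m, nu_a, s)
    bad <- vd <= 0 & va <= 0
    ok <- !bad
    idx <- todo[ok]
    td[idx] <- ifelse(vd[ok] > 0, (b - pd[ok]) / vd[ok], Inf)
    ta[idx] <- ifelse(va[ok] > 0, (b - pa[ok]) / va[ok], Inf)
    n_redrawn <- n_redrawn + sum(bad)
    todo <- todo[bad]
  }
  delayed_wins <- td <= ta
  rt <- t0 + pmin(td, ta)
  structure(data.frame(condition = condition,
                       choice = as.integer(delayed_wins),
                       rt = rt),
            n_redrawn = n_redrawn)
}

#' LBA data log-likelihood for one subject
#'
#' Sum over trials of the log defective density at the observed
#' (choice, RT) pairs. Trials with zero density (e.g. `rt <= t0`) and log
#' densities below the floor are clamped at `floor_lp` per trial for
#' sampler robustness; the number of floored trials is returned as an
#' attribute.
#'
#' @param trials data frame with columns `rt` (seconds), `choice` (0/1)
#'   and `condition` (1..5).
#' @param params an [lba_params] object.
#' @param floor_lp per-trial lower bound on the log density.
#' @return scalar log-likelihood with attribute `n_floored`.
#' @export
lba_loglik <- function(trials, params, floor_lp = -700) {
  if (nrow(trials) == 0) stop("empty trial set")
  theta5 <- function(x) matrix(x, 5, 1)
  ll <- lba_loglik_chains_cpp(as.numeric(trials$rt),
                              as.integer(trials$choice),
                              as.integer(trials$condition),
                              theta5(params$A), theta5(params$b),
                              theta5(params$s), theta5(params$t0),
                              theta5(params$nu_d), floor_lp)
  g <- lba_defective_pdf_rows(trials, params)
  structure(ll[1], n_floored = sum(g <= exp(floor_lp)))
}

# per-row defective density via the R reference path (used for flooring
# diagnostics and density cross-checks)
lba_defective_pdf_rows <- function(trials, params) {
  g <- numeric(nrow(trials))
  for (k in unique(trials$condition)) {
    for (ch in c(0L, 1L)) {
      i <- trials$condition == k & trials$choice == ch
      if (any(i)) g[i] <- lba_defective_pdf(trials$rt[i], ch, params, k)
    }
  }
  g
}

#' Total response mass of the defective densities
#'
#' Closed-form total probability that at least one accumulator finishes:
#' \eqn{1 - \Phi(-\nu_a/s)\Phi(-\nu_d/s)}. The defective delayed and
#' immediate densities integrate to this value jointly.
#'
#' @inheritParams lba_defective_pdf
#' @return total response probability.
#' @export
lba_total_mass <- function(params, condition) {
  nu_d <- params$nu_d[condition]; s <- params$s[condition]
  1 - pnorm(-(1 - nu_d) / s) * pnorm(-nu_d / s)
}
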