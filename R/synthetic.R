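#' Configuration for a synthetic two-session cohort
#'
#' Describes the ground-truth population a simulated cohort is drawn from
#' and the task-design arm it completes. The design constants mirror the
#' task: five value conditions at target delayed-choice probabilities
#' 0.1/0.3/0.5/0.7/0.9, delays uniform on 30–45 days, a fixed $10
#' immediate option, 30 (60 at 0.5) trials per condition in the EEG-like
#' arm or 40 (80 at 0.5) in the fMRI-like arm, a 4-second decision window,
#' and a 60-trial session-1 staircase.
#'
#' Group-level truth distributions are lognormal on the natural scale
#' (means chosen as typical human values: discount rate around 0.01/day,
#' softmax sensitivity around 2.5 per dollar, LBA start range 0.45,
#' threshold gap 0.5 — an elevated bound relative to start-point noise,
#' the slow-error regime — drift sd 0.3, non-decision time around 0.30 s).
#' Under the M2 generating variant, non-decision time follows a positive
#' quadratic profile in the target probability,
#' `t0 = t0_base + t0_quad * (p - 0.5)^2`.
#'
#' @param n_subjects cohort size.
#' @param arm `"eeg"` (30/60 per condition) or `"fmri"` (40/80).
#' @param variant generating variant: `"M1"` (constant t0) or `"M2"`
#'   (quadratic t0 profile).
#' @param linkage `"exact"` (per-condition delayed drift solved so the
#'   model-implied choice probability equals the target exactly) or
#'   `"noisy"` (Gaussian perturbation of the exact drift on the logit
#'   scale).
#' @param k_meanlog,k_sdlog lognormal truth for the discount rate (per day).
#' @param m_meanlog,m_sdlog lognormal truth for softmax sensitivity.
#' @param A_meanlog,A_sdlog,chi_meanlog,chi_sdlog,s_meanlog,s_sdlog,t0_meanlog,t0_sdlog
#'   lognormal truths for the LBA parameters.
#' @param t0_quad quadratic t0 coefficient (seconds per unit of
#'   `(p-0.5)^2`); used when `variant = "M2"`.
#' @param linkage_sd logit-scale sd of the drift perturbation in noisy
#'   mode.
#' @param decision_window decision period length in seconds.
#' @param staircase_trials session-1 staircase length.
#' @param seed RNG seed for the whole cohort.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8, arm = c("eeg", "fmri"),
                          variant = c("M2", "M1"),
                          linkage = c("exact", "noisy"),
                          k_meanlog = log(0.01), k_sdlog = 0.5,
                          m_meanlog = log(2.5), m_sdlog = 0.3,
                          A_meanlog = log(0.45), A_sdlog = 0.15,
                          chi_meanlog = log(0.5), chi_sdlog = 0.15,
                          s_meanlog = log(0.3), s_sdlog = 0.1,
                          t0_meanlog = log(0.3), t0_sdlog = 0.15,
                          t0_quad = 0.5, linkage_sd = 0.15,
                          decision_window = 4, staircase_trials = 60,
                          seed = 1) {
  arm <- match.arg(arm)
  structure(list(n_subjects = as.integer(n_subjects), arm = arm,
                 variant = match.arg(variant), linkage = match.arg(linkage),
                 k_meanlog = k_meanlog, k_sdlog = k_sdlog,
                 m_meanlog = m_meanlog, m_sdlog = m_sdlog,
                 A_meanlog = A_meanlog, A_sdlog = A_sdlog,
                 chi_meanlog = chi_meanlog, chi_sdlog = chi_sdlog,
                 s_meanlog = s_meanlog, s_sdlog = s_sdlog,
                 t0_meanlog = t0_meanlog, t0_sdlog = t0_sdlog,
                 t0_quad = t0_quad, linkage_sd = linkage_sd,
                 decision_window = decision_window,
                 staircase_trials = as.integer(staircase_trials),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

arm_counts <- function(arm, targets = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  base <- if (arm == "eeg") 30L else 40L
  counts <- rep(base, length(targets))
  counts[targets == 0.5] <- 2L * base
  counts
}

#' Generate a synthetic two-session cohort with known ground truth
#'
#' Per subject: draws true discounting and LBA parameters from the
#' configured group distributions; simulates the 60-trial session-1
#' staircase; constructs session-2 offers at the five target
#' probabilities with the arm's trial counts; sets the per-condition
#' delayed drift by solving the LBA choice probability for the target
#' (exact mode) or perturbing that solution (noisy mode); and simulates
#' session-2 choices and RTs from the LBA race. Responses slower than the
#' decision window are emitted with their true RT so that
#' [filter_trials()] exercises the discard rule downstream.
#'
#' @param config a [cohort_config].
#' @return list of class `synthetic_cohort`: `trials` (both sessions, in
#'   the trial-table format), `truth` (long table: subject, parameter,
#'   condition, value), and the `config` echo.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  targets <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  counts <- arm_counts(config$arm, targets)
  trial_rows <- list(); truth_rows <- list()
  for (si in seq_len(config$n_subjects)) {
    id <- sprintf("s%02d", si)
    k <- stats::rlnorm(1, config$k_meanlog, config$k_sdlog)
    m <- stats::rlnorm(1, config$m_meanlog, config$m_sdlog)
    dfit <- discount_fit("hyperbolic", k = k, m = m)
    A <- stats::rlnorm(1, config$A_meanlog, config$A_sdlog)
    chi <- stats::rlnorm(1, config$chi_meanlog, config$chi_sdlog)
    s <- stats::rlnorm(1, config$s_meanlog, config$s_sdlog)
    t0_base <- stats::rlnorm(1, config$t0_meanlog, config$t0_sdlog)
    t0 <- if (config$variant == "M2") {
      t0_base + config$t0_quad * (targets - 0.5)^2
    } else rep(t0_base, 5)

    # session 1: staircase (no RTs modelled; choices only)
    st <- run_staircase(dfit, n_trials = config$staircase_trials)
    trial_rows[[length(trial_rows) + 1]] <- data.frame(
      subject_id = id, session = 1L, condition_target_p = NA_real_,
      delay_days = st$history$delay_days,
      delayed_amount = st$history$delayed_amount,
      choice = st$history$choice, rt_seconds = NA_real_)

    # session 2: offers at target probabilities, LBA-generated behaviour
    offers <- offers_for_targets(dfit, targets, counts)
    params <- lba_params(A = A, chi = chi, s = s, t0 = t0, nu_d = 0.5)
    nu <- numeric(5)
    for (j in seq_along(targets)) {
      nu[j] <- tryCatch(
        lba_solve_drift(targets[j], params, j),
        error = function(e) stop("subject ", id, ", condition p=",
                                 targets[j], ": ", conditionMessage(e)))
    }
    if (config$linkage == "noisy") {
      nu <- plogis(qlogis(nu) + rnorm(5, 0, config$linkage_sd))
    }
    params$nu_d <- nu
    sess2 <- lapply(seq_along(targets), function(j) {
      n_j <- sum(offers$target_p == targets[j])
      sim <- lba_simulate(params, j, n_j)
      off <- offers[offers$target_p == targets[j], ]
      data.frame(subject_id = id, session = 2L,
                 condition_target_p = targets[j],
                 delay_days = off$delay_days,
                 delayed_amount = off$delayed_amount,
                 choice = sim$choice, rt_seconds = sim$rt)
    })
    trial_rows[[length(trial_rows) + 1]] <- do.call(rbind, sess2)

    truth_rows[[length(truth_rows) + 1]] <- rbind(
      data.frame(subject = id, parameter = c("k", "m", "A", "chi", "s"),
                 condition = NA_integer_, value = c(k, m, A, chi, s)),
      data.frame(subject = id, parameter = "t0", condition = 1:5, value = t0),
      data.frame(subject = id, parameter = "nu_d", condition = 1:5, value = nu))
  }
  structure(list(trials = do.call(rbind, trial_rows),
                 truth = do.call(rbind, truth_rows),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %s arm, variant %s, %s linkage\n",
              x$config$n_subjects, x$config$arm, x$config$variant,
              x$config$linkage))
  cat(sprintf("  %d trial rows (%d session-2)\n", nrow(x$trials),
              sum(x$trials$session == 2)))
  invisible(x)
}

#' Parameter-recovery report against known ground truth
#'
#' Compares a hierarchical fit with the generating truth: per parameter,
#' the bias and RMSE of the MAP estimates, the coverage of equal-tailed
#' 95% credible intervals, and the truth-MAP correlation (across
#' subject-conditions for condition-varying parameters).
#'
#' @param truth truth table from [generate_cohort()].
#' @param fit an [fit_hlba()] result on the same subjects.
#' @return data frame per parameter: `n`, `bias`, `rmse`, `coverage95`,
#'   `cor_map`.
#' @export
recovery_report <- function(truth, fit) {
  if (!all(fit$subjects %in% unique(truth$subject))) {
    stop("truth and fit subject ids do not match")
  }
  draws <- fit$draws$theta
  dims <- dim(draws)
  spec <- fit$variant
  # natural-scale draw extraction per subject/parameter/condition
  nat_draws <- function(s, parameter, cond) {
    idx <- switch(parameter, nu_d = spec$idx$nu, t0 = spec$idx$t0,
                  A = spec$idx$A, chi = spec$idx$chi, s = spec$idx$s)
    row <- if (length(idx) == 5) idx[cond] else idx[1]
    x <- as.numeric(draws[s, row, , ])
    if (parameter == "nu_d") plogis(x) else exp(x)
  }
  map_par <- function(s, parameter, cond) {
    p <- map_estimate(fit, fit$subjects[s])
    v <- switch(parameter, nu_d = p$nu_d, t0 = p$t0, A = p$A,
                chi = p$chi, s = p$s)
    v[if (is.na(cond)) 1 else cond]
  }
  rows <- list()
  for (parameter in unique(truth$parameter)) {
    if (parameter %in% c("k", "m")) next  # discounting truth, not LBA fit
    tt <- truth[truth$parameter == parameter, ]
    est <- numeric(0); tru <- numeric(0); cover <- logical(0)
    for (i in seq_len(nrow(tt))) {
      s <- match(tt$subject[i], fit$subjects)
      cond <- tt$condition[i]
      if (is.na(s)) next
      if (!is.na(cond) && parameter == "t0" && !"t0" %in% spec$free) cond <- 1L
      dr <- nat_draws(s, parameter, if (is.na(cond)) 1L else cond)
      ci <- quantile(dr, c(0.025, 0.975))
      tru_i <- tt$value[i]
      est <- c(est, map_par(s, parameter, cond))
      tru <- c(tru, tru_i)
      cover <- c(cover, tru_i >= ci[1] && tru_i <= ci[2])
    }
    if (!length(est)) next
    rows[[parameter]] <- data.frame(
      parameter = parameter, n = length(est), bias = mean(est - tru),
      rmse = sqrt(mean((est - tru)^2)), coverage95 = mean(cover),
      cor_map = if (stats::sd(tru) > 0 && stats::sd(est) > 0)
        cor(est, tru) else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
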