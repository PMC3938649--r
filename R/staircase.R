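#' Adaptive staircase estimation of the indifference discount rate
#'
#' Simulates the stair-stepping procedure used to approximate a subject's
#' hyperbolic discount rate. Each trial offers a delayed reward of
#' \eqn{R = 10 (1 + \hat k D)} dollars at a delay \eqn{D} against a fixed
#' $10 immediate option, so indifference implies a discount rate of exactly
#' \eqn{\hat k}. If the delayed offer is chosen, \eqn{\hat k} decreases by
#' the current step size for the next trial; otherwise it increases by the
#' same amount. At every second choice reversal occurring within
#' `reversal_window` consecutive trials the step size is reduced by 5%.
#'
#' @param true_subject a [discount_fit] object describing the simulated
#'   subject's true preferences (any of the three value models); choices
#'   are generated by the softmax rule with the subject's sensitivity `m`.
#' @param n_trials number of staircase trials (the task used 60).
#' @param k0 initial equivalence rate per day.
#' @param step0 initial step size per day.
#' @param delay_range integer day range delays are drawn from uniformly.
#' @param reversal_window number of consecutive trials within which the
#'   second reversal must fall for the step reduction to apply.
#' @param k_floor smallest admissible \eqn{\hat k}; values driven to or
#'   below zero are clamped here with a warning.
#' @param seed optional RNG seed for reproducibility.
#' @return an object of class `staircase` with elements `k_hat` (final
#'   estimate), `step` (final step size), `reversal_count`, and `history`,
#'   a data frame with one row per trial (delay, offered amount, choice,
#'   and the post-update `k_hat`).
#' @export
run_staircase <- function(true_subject, n_trials = 60, k0 = 0.01,
                          step0 = 0.005, delay_range = c(30, 45),
                          reversal_window = 5, k_floor = 1e-6, seed = NULL) {
  stopifnot(n_trials >= 1, k0 > 0, step0 > 0)
  if (!is.null(seed)) set.seed(seed)
  k_hat <- k0
  step <- step0
  reversals <- 0L
  last_rev_trial <- -Inf
  prev_choice <- NA_integer_
  clamped <- FALSE
  hist <- data.frame(trial = seq_len(n_trials), delay_days = NA_real_,
                     delayed_amount = NA_real_, choice = NA_integer_,
                     k_hat = NA_real_, step = NA_real_)
  delays <- sample(seq(delay_range[1], delay_range[2]), n_trials,
                   replace = TRUE)
  for (i in seq_len(n_trials)) {
    D <- delays[i]
    R <- 10 * (1 + k_hat * D)
    v <- subjective_value(R, D, true_subject)
    p <- softmax_prob_delayed(v, 10, true_subject$m)
    ch <- rbinom(1, 1, p)
    if (!is.na(prev_choice) && ch != prev_choice) {
      reversals <- reversals + 1L
      if (reversals %% 2L == 0L && (i - last_rev_trial) < reversal_window) {
        step <- step * 0.95
      }
      last_rev_trial <- i
    }
    k_hat <- if (ch == 1L) k_hat - step else k_hat + step
    if (k_hat <= k_floor) {
      k_hat <- k_floor
      clamped <- TRUE
    }
    hist$delay_days[i] <- D
    hist$delayed_amount[i] <- R
    hist$choice[i] <- ch
    hist$k_hat[i] <- k_hat
    hist$step[i] <- step
    prev_choice <- ch
  }
  if (clamped) warning("staircase k_hat hit the positive floor ", k_floor)
  structure(list(k_hat = k_hat, step = step, reversal_count = reversals,
                 trial_index = n_trials, history = hist),
            class = "staircase")
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf("Staircase: %d trials, %d reversals, final k_hat = %.5f/day (step %.5f)\n",
              x$trial_index, x$reversal_count, x$k_hat, x$step))
  invisible(x)
}
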