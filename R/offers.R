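#' Construct delayed offers at target choice probabilities
#'
#' Given a fitted discounting model and softmax sensitivity for a subject,
#' builds offers whose model-implied probability of choosing the delayed
#' reward equals each target exactly. The required subjective value is
#' \eqn{V_D = 10 + \mathrm{logit}(p) / m}, and the offered amount is the
#' inverse of the value function at the drawn delay (hyperbolic:
#' \eqn{R = V_D (1 + kD)}; exponential: \eqn{R = V_D e^{kD}};
#' quasi-hyperbolic: \eqn{R = V_D / (\beta \delta^D)}).
#'
#' @param fit a [discount_fit] with `m > 0`.
#' @param targets target delayed-choice probabilities in (0, 1).
#' @param counts number of offers per target (recycled); the EEG-like arm
#'   used 30 per level with 60 at 0.5, the fMRI-like arm 40 and 80.
#' @param delay_range integer day range delays are drawn from uniformly.
#' @param seed optional RNG seed.
#' @return data frame of offers with columns `target_p`, `delay_days`,
#'   `delayed_amount`, `immediate_amount` (fixed at 10).
#' @export
offers_for_targets <- function(fit, targets = c(0.1, 0.3, 0.5, 0.7, 0.9),
                               counts = 1, delay_range = c(30, 45),
                               seed = NULL) {
  stopifnot(all(targets > 0 & targets < 1))
  if (is.null(fit$m) || fit$m <= 0) stop("fit must carry a positive sensitivity m")
  if (!is.null(seed)) set.seed(seed)
  counts <- rep_len(counts, length(targets))
  tp <- rep(targets, counts)
  n <- length(tp)
  D <- sample(seq(delay_range[1], delay_range[2]), n, replace = TRUE)
  v_d <- 10 + qlogis(tp) / fit$m
  if (any(v_d <= 0)) {
    stop("target probability ", min(tp), " implies a non-positive subjective ",
         "value at m = ", fit$m, "; offer amount would not be positive")
  }
  R <- switch(fit$model,
    hyperbolic = v_d * (1 + fit$k * D),
    exponential = v_d * exp(fit$k * D),
    quasi_hyperbolic = v_d / (fit$beta * fit$delta^D))
  data.frame(target_p = tp, delay_days = D, delayed_amount = R,
             immediate_amount = 10)
}
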