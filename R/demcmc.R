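#' One differential-evolution MCMC sweep over chains
#'
#' For every chain `i`, proposes
#' \eqn{\theta^* = \theta_i + \gamma(\theta_m - \theta_n) + U(-j, j)} with
#' `m != n != i` drawn without replacement from the other chains'
#' current states, and accepts with Metropolis probability
#' `min(1, exp(lp* - lp))`. With `gamma = 0` and `jitter = 0` the proposal
#' equals the current state and every move is accepted.
#'
#' @param theta `d x C` matrix of chain states.
#' @param lp length-`C` vector of current log posteriors.
#' @param log_post_fn function mapping a `d x C` matrix to a length-`C`
#'   vector of log posteriors.
#' @param gamma DE scale factor; default `2.38 / sqrt(2 d)`.
#' @param jitter half-width of the uniform proposal noise.
#' @return list with updated `theta`, `lp`, and logical `accept` per chain.
#' @export
demcmc_step <- function(theta, lp, log_post_fn, gamma = NULL, jitter = 1e-3) {
  d <- nrow(theta); C <- ncol(theta)
  if (C < 4) stop("DE-MCMC needs at least 4 chains")
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  pairs <- vapply(seq_len(C),
                  function(i) sample(seq_len(C)[-i], 2L), integer(2))
  prop <- theta + gamma * (theta[, pairs[1, ], drop = FALSE] -
                             theta[, pairs[2, ], drop = FALSE]) +
    matrix(runif(d * C, -jitter, jitter), d, C)
  lp_prop <- log_post_fn(prop)
  accept <- log(runif(C)) < lp_prop - lp
  accept[!is.finite(lp_prop)] <- FALSE
  theta[, accept] <- prop[, accept]
  lp[accept] <- lp_prop[accept]
  list(theta = theta, lp = lp, accept = accept)
}
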