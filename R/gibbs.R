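#' Conjugate Gibbs update of the group-level parameters
#'
#' One draw from the exact conditional posteriors of the group mean and
#' variance of each transformed subject parameter, given the current
#' subject-level draws. With `S` subjects and prior `mu ~ N(m0, v0^2)`,
#' `sigma^2 ~ IG(a0, b0)`:
#' \deqn{\mu \mid \sigma^2, \theta \sim N\!\left(\frac{m_0/v_0^2 + \sum_s
#'   \theta_s/\sigma^2}{1/v_0^2 + S/\sigma^2},\;
#'   \left(1/v_0^2 + S/\sigma^2\right)^{-1}\right)}
#' \deqn{\sigma^2 \mid \mu, \theta \sim IG\!\left(a_0 + S/2,\;
#'   b_0 + \sum_s (\theta_s - \mu)^2 / 2\right)}
#'
#' @param theta subject draws: an `S x d` matrix (one chain) or an
#'   `S x d x C` array (one per chain).
#' @param prior an [hlba_prior].
#' @param sigma current group sds (`d` vector or `d x C` matrix) used in
#'   the mean update; defaults to the sample sd across subjects.
#' @return list with `mu` and `sigma` (`d x C` matrices; single-chain input
#'   yields one column).
#' @export
gibbs_update_group <- function(theta, prior, sigma = NULL) {
  if (length(dim(theta)) == 2) theta <- array(theta, c(dim(theta), 1L))
  S <- dim(theta)[1]; d <- dim(theta)[2]; C <- dim(theta)[3]
  if (S < 2) stop("group update needs at least 2 subjects")
  sums <- apply(theta, c(2, 3), sum)              # d x C
  if (is.null(sigma)) sigma <- apply(theta, c(2, 3), sd)
  sig2 <- matrix(sigma, d, C)^2
  m0 <- rep_len(prior$mu0, d); v0sq <- rep_len(prior$sd0, d)^2
  prec <- 1 / v0sq + S / sig2
  mu <- matrix(rnorm(d * C, (m0 / v0sq + sums / sig2) / prec,
                     1 / sqrt(prec)), d, C)
  ssq <- matrix(0, d, C)
  for (c in seq_len(C)) {
    thc <- matrix(theta[, , c], S, d)
    ssq[, c] <- colSums((thc - matrix(mu[, c], S, d, byrow = TRUE))^2)
  }
  shape <- prior$shape0 + S / 2
  scale <- rep_len(prior$scale0, d) + ssq / 2
  sig2_new <- matrix(1 / rgamma(d * C, shape = shape, rate = scale), d, C)
  list(mu = mu, sigma = sqrt(sig2_new))
}
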