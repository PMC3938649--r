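#' Discounted subjective value of a delayed reward
#'
#' Computes the present subjective value of a reward of `amount` dollars
#' delivered after `delay` days under one of three standard delay-discounting
#' models:
#' \describe{
#'   \item{hyperbolic}{\eqn{V = R / (1 + kD)}}
#'   \item{exponential}{\eqn{V = R \exp(-kD)}}
#'   \item{quasi_hyperbolic}{\eqn{V = R \beta \delta^D} for \eqn{D > 0},
#'     \eqn{V = R} at \eqn{D = 0} (beta-delta model)}
#' }
#'
#' @param amount delayed reward magnitude in dollars (> 0); vectorised.
#' @param delay delay in days (>= 0); vectorised.
#' @param fit a [discount_fit] object, or a named list with elements
#'   `model` and the model's parameters (`k`, or `beta` and `delta`).
#' @return subjective value in dollars, in `(0, amount]`.
#' @seealso [fit_discounting()], [softmax_prob_delayed()]
#' @export
subjective_value <- function(amount, delay, fit) {
  stopifnot(is.numeric(amount), is.numeric(delay))
  if (any(amount <= 0)) stop("delayed amount must be positive")
  if (any(delay < 0)) stop("delay must be non-negative")
  model <- match.arg(fit$model, c("hyperbolic", "exponential", "quasi_hyperbolic"))
  switch(model,
    hyperbolic = {
      if (fit$k < 0) stop("k must be non-negative")
      amount / (1 + fit$k * delay)
    },
    exponential = {
      if (fit$k < 0) stop("k must be non-negative")
      amount * exp(-fit$k * delay)
    },
    quasi_hyperbolic = {
      if (fit$beta <= 0 || fit$beta > 1) stop("beta must lie in (0, 1]")
      if (fit$delta <= 0 || fit$delta >= 1) stop("delta must lie in (0, 1)")
      ifelse(delay > 0, amount * fit$beta * fit$delta^delay, amount)
    })
}

#' Softmax probability of choosing the delayed reward
#'
#' Logistic choice rule on the difference of subjective values:
#' \eqn{P(\mathrm{delayed}) = 1 / (1 + \exp(-m (V_D - V_I)))}, where `m` is
#' the subject's sensitivity (per dollar) to value differences.
#'
#' @param v_delayed subjective value of the delayed option (dollars).
#' @param v_immediate subjective value of the immediate option (dollars).
#' @param m sensitivity (> 0, per dollar).
#' @return probability of choosing the delayed reward.
#' @export
softmax_prob_delayed <- function(v_delayed, v_immediate, m) {
  if (any(m <= 0)) stop("sensitivity m must be positive")
  plogis(m * (v_delayed - v_immediate))
}

#' Construct a discounting model parameter set
#'
#' Builds the parameter object used by [subjective_value()] and the
#' synthetic-cohort generator without fitting, e.g. to specify a known
#' ground-truth subject.
#'
#' @param model one of `"hyperbolic"`, `"exponential"`, `"quasi_hyperbolic"`.
#' @param k per-day discount rate (hyperbolic/exponential).
#' @param beta,delta quasi-hyperbolic parameters (`beta` in (0,1], `delta`
#'   in (0,1), per-day base).
#' @param m softmax sensitivity (> 0, per dollar).
#' @return an object of class `discount_fit` (with `loglik = NA`).
#' @export
discount_fit <- function(model = c("hyperbolic", "exponential", "quasi_hyperbolic"),
                         k = NULL, beta = NULL, delta = NULL, m = 1) {
  model <- match.arg(model)
  if (m <= 0) stop("m must be positive")
  out <- list(model = model, m = m, loglik = NA_real_, n = 0L,
              identifiable = NA)
  if (model %in% c("hyperbolic", "exponential")) {
    if (is.null(k) || k < 0) stop("k must be supplied and non-negative")
    out$k <- k
  } else {
    if (is.null(beta) || is.null(delta)) stop("beta and delta must be supplied")
    if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
    if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
    out$beta <- beta; out$delta <- delta
  }
  class(out) <- "discount_fit"
  out
}

#' Fit a delay-discounting model with a softmax choice rule
#'
#' Maximises the Bernoulli log-likelihood of observed choices under the
#' softmax rule applied to model-implied subjective values. The immediate
#' option is valued at its face amount (default $10).
#'
#' @param trials data frame with columns `delayed_amount`, `delay_days`,
#'   `choice` (1 = delayed, 0 = immediate) and optionally
#'   `immediate_amount` (default 10).
#' @param model discounting model; see [subjective_value()].
#' @param immediate_amount value of the immediate option if not a column.
#' @return a `discount_fit` object with fitted parameters, `m`, `loglik`,
#'   `n` and an `identifiable` flag. When all observed choices are
#'   identical the fit is not identifiable: a boundary fit is returned with
#'   a warning and `identifiable = FALSE`.
#' @export
fit_discounting <- function(trials,
                            model = c("hyperbolic", "exponential", "quasi_hyperbolic"),
                            immediate_amount = 10) {
  model <- match.arg(model)
  need <- c("delayed_amount", "delay_days", "choice")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns ", paste(need, collapse = ", "))
  }
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  n <- nrow(trials)
  if (n < 2) stop("non-identifiable: need at least 2 trials")
  vi <- if ("immediate_amount" %in% names(trials)) trials$immediate_amount else immediate_amount
  ch <- as.integer(trials$choice)
  if (!all(ch %in% c(0L, 1L))) stop("choice must be 0 (immediate) or 1 (delayed)")

  nll_for <- function(fit) {
    v <- subjective_value(trials$delayed_amount, trials$delay_days, fit)
    p <- softmax_prob_delayed(v, vi, fit$m)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(ch == 1L, log(p), log1p(-p)))
  }

  if (length(unique(ch)) == 1L) {
    warning("all choices identical: discounting fit is not identifiable; ",
            "returning boundary fit")
    # push value towards the observed side at the parameter boundary
    fit <- if (model == "quasi_hyperbolic") {
      discount_fit(model, beta = if (ch[1] == 1) 1 else 1e-3, delta = 0.999,
                   m = 1)
    } else {
      discount_fit(model, k = if (ch[1] == 1) 1e-6 else 10, m = 1)
    }
    fit$loglik <- -nll_for(fit); fit$n <- n; fit$identifiable <- FALSE
    fit$trials <- trials
    return(fit)
  }

  unpack <- function(par) {
    if (model == "quasi_hyperbolic") {
      discount_fit(model, beta = plogis(par[1]), delta = plogis(par[2]),
                   m = exp(par[3]))
    } else {
      discount_fit(model, k = exp(par[1]), m = exp(par[2]))
    }
  }
  obj <- function(par) nll_for(unpack(par))
  start <- if (model == "quasi_hyperbolic") c(qlogis(0.8), qlogis(0.995), 0)
           else c(log(0.01), 0)
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  fit <- unpack(opt$par)
  fit$loglik <- -opt$value
  fit$n <- n
  fit$identifiable <- TRUE
  fit$convergence <- opt$convergence
  fit$trials <- trials
  fit
}

#' @export
print.discount_fit <- function(x, ...) {
  cat("Delay-discounting fit (", x$model, ")\n", sep = "")
  if (x$model == "quasi_hyperbolic") {
    cat(sprintf("  beta = %.4f, delta = %.5f (per day)\n", x$beta, x$delta))
  } else {
    cat(sprintf("  k = %.5f per day\n", x$k))
  }
  cat(sprintf("  softmax sensitivity m = %.3f per dollar\n", x$m))
  if (!is.na(x$loglik)) {
    cat(sprintf("  log-likelihood %.2f on %d trials\n", x$loglik, x$n))
  }
  if (isFALSE(x$identifiable)) cat("  [not identifiable: boundary fit]\n")
  invisible(x)
}

#' @export
coef.discount_fit <- function(object, ...) {
  if (object$model == "quasi_hyperbolic") {
    c(beta = object$beta, delta = object$delta, m = object$m)
  } else {
    c(k = object$k, m = object$m)
  }
}

#' @export
logLik.discount_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- if (object$model == "quasi_hyperbolic") 3 else 2
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' @export
predict.discount_fit <- function(object, newdata = NULL, immediate_amount = 10, ...) {
  if (is.null(newdata)) newdata <- object$trials
  vi <- if ("immediate_amount" %in% names(newdata)) newdata$immediate_amount
        else immediate_amount
  v <- subjective_value(newdata$delayed_amount, newdata$delay_days, object)
  softmax_prob_delayed(v, vi, object$m)
}

#' @export
simulate.discount_fit <- function(object, nsim = 1, seed = NULL,
                                  newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  replicate(nsim, rbinom(length(p), 1, p), simplify = FALSE)
}
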