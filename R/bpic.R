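#' Bayesian predictive information criterion
#'
#' Computes BPIC from the retained draws of a hierarchical fit. With the
#' deviance \eqn{D(\theta) = -2 \sum_s \log L(y_s \mid \theta_s)}, the
#' effective parameter count is \eqn{p_D = \bar D - D(\bar\theta)} (the
#' posterior-mean deviance minus the deviance at the posterior mean, taken
#' on the transformed scale where posteriors are closer to Gaussian), and
#' \deqn{\mathrm{BPIC} = \bar D + 2 p_D.} The criterion is computed
#' independently within each chain and reported as the across-chain mean
#' with its standard deviation — the form in which fit tables report it.
#' Per-chain plug-in points also keep \eqn{D(\bar\theta)} on the
#' likelihood ridge when weakly identified parameters leave the pooled
#' posterior mean off it (the pooled-plug-in effective parameter count is
#' returned as a diagnostic).
#'
#' @param fit an [fit_hlba()] result.
#' @param min_draws refuse computation below this many retained draws.
#' @return object of class `bpic`: list with `variant`, `mean_deviance`,
#'   `p_d` and `bpic` (across-chain means), `per_chain` (vector of
#'   per-chain BPICs), `sd_chain`, and the pooled-plug-in `p_d_pooled`
#'   diagnostic.
#' @export
bpic <- function(fit, min_draws = 50) {
  dr <- fit$draws
  dims <- dim(dr$theta)  # S, d, C, K
  S <- dims[1]; C <- dims[3]; K <- dims[4]
  if (C * K < min_draws) {
    stop("only ", C * K, " retained draws; need at least ", min_draws)
  }
  dev_draws <- -2 * apply(dr$loglik, c(2, 3), sum)          # C x K
  dev_draws <- matrix(dev_draws, C, K)
  mean_dev <- mean(dev_draws)

  dev_at <- function(theta_bar) {  # theta_bar: S x d
    tot <- 0
    for (s in seq_len(S)) {
      tr <- fit$data[fit$data$subject == fit$subjects[s], ]
      dec <- decode_chains(matrix(theta_bar[s, ], ncol = 1), fit$variant)
      tot <- tot + lba_loglik_chains_cpp(tr$rt, tr$choice, tr$condition,
                                         dec$A, dec$b, dec$s, dec$t0,
                                         dec$nu, -700)[1]
    }
    -2 * tot
  }

  # per-chain criterion: each chain's plug-in point is its own posterior
  # mean, which stays on the likelihood ridge even when chains occupy
  # different parts of it; the reported BPIC is the across-chain mean,
  # with the across-chain sd as the stability diagnostic
  per_chain <- t(vapply(seq_len(C), function(ci) {
    md <- mean(dev_draws[ci, ])
    tb <- apply(dr$theta[, , ci, , drop = FALSE], c(1, 2), mean)
    pd <- md - dev_at(matrix(tb, S, dims[2]))
    c(mean_dev = md, p_d = pd, bpic = md + 2 * pd)
  }, numeric(3)))

  # pooled plug-in (grand posterior mean) kept as a diagnostic; with
  # ridge-shaped posteriors it can fall off the ridge and go negative
  theta_bar <- apply(dr$theta, c(1, 2), mean)
  p_d_pooled <- mean_dev - dev_at(matrix(theta_bar, S, dims[2]))

  structure(list(variant = fit$variant$name, mean_deviance = mean_dev,
                 p_d = mean(per_chain[, "p_d"]),
                 bpic = mean(per_chain[, "bpic"]),
                 per_chain = per_chain[, "bpic"],
                 sd_chain = sd(per_chain[, "bpic"]),
                 p_d_pooled = p_d_pooled),
            class = "bpic")
}

#' @export
print.bpic <- function(x, ...) {
  cat(sprintf("%s: BPIC = %.2f (sd across chains %.2f), mean deviance %.2f, p_D %.2f\n",
              x$variant, x$bpic, x$sd_chain, x$mean_deviance, x$p_d))
  invisible(x)
}

#' Deviance information criterion (internal cross-check)
#'
#' DIC from the same draws: `mean_deviance + p_D`. BPIC applies twice the
#' DIC penalty on identical posteriors.
#'
#' @inheritParams bpic
#' @return numeric DIC.
#' @export
dic <- function(fit, min_draws = 50) {
  b <- bpic(fit, min_draws)
  b$mean_deviance + b$p_d
}

#' Forward model-building search over the variant lattice
#'
#' Fits the simplest variant (M1, drift rates only), then the four
#' single-extension variants (M2–M5). If the best of those improves on M1,
#' its three two-extension completions (the M6–M8 pattern) are fitted as
#' well; parameters are added only when they improve BPIC. At most eight
#' variants are fitted.
#'
#' @param trials trial table (see [fit_hlba()]).
#' @param prior an [hlba_prior].
#' @param control an [hlba_control]; the same configuration is used for
#'   every variant.
#' @return object of class `model_search`: a results table (`$table`,
#'   ordered as fitted, with the winner flagged) plus the per-variant
#'   [bpic] objects and fits.
#' @export
model_search <- function(trials, prior = hlba_prior(),
                         control = hlba_control()) {
  fit_one <- function(v) {
    tryCatch({
      f <- fit_hlba(trials, v, prior, control)
      list(variant = v, bpic = bpic(f), fit = f, error = NULL)
    }, error = function(e) {
      warning("variant ", v, " failed: ", conditionMessage(e))
      list(variant = v, bpic = NULL, fit = NULL,
           error = conditionMessage(e))
    })
  }
  results <- list(fit_one("M1"))
  for (v in c("M2", "M3", "M4", "M5")) results[[length(results) + 1]] <- fit_one(v)
  ok <- !vapply(results, function(r) is.null(r$bpic), logical(1))
  vals <- vapply(results[ok], function(r) r$bpic$bpic, numeric(1))
  names(vals) <- vapply(results[ok], `[[`, "", "variant")
  best1 <- names(vals)[which.min(vals)]
  if (best1 != "M1") {
    ext <- switch(best1,
                  M2 = c("M6", "M7", "M8"),
                  M3 = "M6", M4 = "M7", M5 = "M8")
    # extensions pairing the winner's freed parameter with t0 (and, for
    # an M2 winner, each of A/b/s)
    for (v in ext) results[[length(results) + 1]] <- fit_one(v)
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(variant = r$variant,
               n_params = variant_spec(r$variant)$n_params,
               free = paste(c("nu_d", variant_spec(r$variant)$free),
                            collapse = ","),
               bpic = if (is.null(r$bpic)) NA_real_ else r$bpic$bpic,
               sd_chain = if (is.null(r$bpic)) NA_real_ else r$bpic$sd_chain,
               p_d = if (is.null(r$bpic)) NA_real_ else r$bpic$p_d,
               failed = !is.null(r$error))
  }))
  tab$winner <- FALSE
  if (any(!is.na(tab$bpic))) tab$winner[which.min(tab$bpic)] <- TRUE
  structure(list(table = tab, results = results,
                 winner = tab$variant[tab$winner][1]),
            class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat("BPIC model-building search (winner:", x$winner, ")\n")
  tab <- x$table
  tab$bpic <- round(tab$bpic, 2); tab$sd_chain <- round(tab$sd_chain, 2)
  tab$p_d <- round(tab$p_d, 1)
  print(tab[, c("variant", "bpic", "sd_chain", "free", "winner")],
        row.names = FALSE)
  invisible(x)
}
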