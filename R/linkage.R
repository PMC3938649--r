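#' Filter trials by response-time validity
#'
#' Discards trials answered in under 200 ms or outside the 4000 ms
#' decision period (RTs are measured from decision-period onset). Rows
#' with missing RT (e.g. session-1 staircase trials) are also dropped with
#' their own reason code. The operation is idempotent.
#'
#' @param trials data frame with an `rt_seconds` (or `rt`) column.
#' @param min_rt,max_rt inclusive validity bounds in seconds.
#' @return list with `kept` (valid rows) and `dropped` (invalid rows plus
#'   a `reason` column: `too_fast`, `outside_window`, `missing_rt`).
#' @export
filter_trials <- function(trials, min_rt = 0.2, max_rt = 4.0) {
  rt <- if ("rt_seconds" %in% names(trials)) trials$rt_seconds else trials$rt
  if (is.null(rt)) stop("trials need an rt_seconds or rt column")
  reason <- rep(NA_character_, nrow(trials))
  reason[is.na(rt)] <- "missing_rt"
  reason[!is.na(rt) & rt < min_rt] <- "too_fast"
  reason[!is.na(rt) & rt > max_rt] <- "outside_window"
  drop <- !is.na(reason)
  dropped <- trials[drop, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[drop]
  else dropped$reason <- character(0)
  list(kept = trials[!drop, , drop = FALSE], dropped = dropped)
}

#' Per-subject, per-condition behavioural summaries
#'
#' Observed delayed-choice fraction, trial counts, minimum RT, and median
#' RTs split by value-consistency. A choice is consistent when it matches
#' the side with the higher modelled subjective value: delayed in
#' conditions with target probability above 0.5, immediate below 0.5
#' (undefined at 0.5).
#'
#' @param trials filtered trial table with `subject_id`/`subject`,
#'   `condition_target_p` (or `condition` + `target_p`), `choice`, and
#'   `rt_seconds`/`rt`.
#' @return data frame, one row per subject x condition: `p_hat`, `n`,
#'   `min_rt`, `median_rt`, `median_rt_consistent`,
#'   `median_rt_inconsistent` (NA where a side has no trials).
#' @export
condition_summary <- function(trials) {
  dat <- normalize_trials(trials)
  split_by <- interaction(dat$subject, dat$condition, drop = TRUE)
  rows <- lapply(split(dat, split_by), function(d) {
    tp <- d$target_p[1]
    cons <- if (!is.na(tp) && tp != 0.5) as.integer(d$choice == (tp > 0.5)) else NA
    data.frame(subject = d$subject[1], condition = d$condition[1],
               target_p = tp, n = nrow(d), p_hat = mean(d$choice),
               min_rt = min(d$rt), median_rt = median(d$rt),
               median_rt_consistent =
                 if (all(is.na(cons)) || !any(cons == 1)) NA_real_
                 else median(d$rt[cons == 1]),
               median_rt_inconsistent =
                 if (all(is.na(cons)) || !any(cons == 0)) NA_real_
                 else median(d$rt[cons == 0]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Rank test of consistent versus inconsistent response times
#'
#' For each value condition with target probability different from 0.5,
#' performs a paired Wilcoxon signed-rank test across subjects of the
#' median RT for value-inconsistent choices against the median RT for
#' value-consistent choices. Subjects without trials of both kinds in a
#' condition are excluded from that condition's test (counts reported).
#'
#' @param summaries output of [condition_summary()].
#' @return data frame per tested condition: `target_p`, `n_subjects`,
#'   `n_excluded`, `median_diff` (inconsistent minus consistent), `V`,
#'   `p_value`.
#' @export
consistency_rt_test <- function(summaries) {
  conds <- sort(unique(summaries$target_p[!is.na(summaries$target_p) &
                                            summaries$target_p != 0.5]))
  if (!length(conds)) stop("no conditions with target p != 0.5")
  out <- lapply(conds, function(tp) {
    d <- summaries[!is.na(summaries$target_p) & summaries$target_p == tp, ]
    ok <- !is.na(d$median_rt_consistent) & !is.na(d$median_rt_inconsistent)
    n <- sum(ok)
    if (n < 3) {
      stop("condition p = ", tp, ": only ", n,
           " subjects with both choice types; too few for a rank test")
    }
    diff <- d$median_rt_inconsistent[ok] - d$median_rt_consistent[ok]
    wt <- suppressWarnings(wilcox.test(diff, mu = 0, exact = FALSE))
    data.frame(target_p = tp, n_subjects = n, n_excluded = nrow(d) - n,
               median_diff = median(diff), V = unname(wt$statistic),
               p_value = wt$p.value)
  })
  do.call(rbind, out)
}

# random-intercept regression returning the fixed-slope triple; falls back
# to a fixed per-subject-intercept lm when lme cannot converge
mixed_slope <- function(df, yname, xname) {
  df <- df[stats::complete.cases(df[, c(yname, xname, "subject")]), ]
  fml <- stats::as.formula(paste(yname, "~", xname))
  res <- tryCatch({
    m <- nlme::lme(fml, random = ~ 1 | subject, data = df,
                   control = nlme::lmeControl(returnObject = TRUE))
    tt <- summary(m)$tTable
    list(estimate = tt[xname, "Value"], se = tt[xname, "Std.Error"],
         df = tt[xname, "DF"], p_value = tt[xname, "p-value"],
         engine = "lme")
  }, error = function(e) NULL)
  if (is.null(res)) {
    m <- stats::lm(stats::as.formula(
      paste(yname, "~ 0 + factor(subject) +", xname)), data = df)
    sm <- summary(m)$coefficients
    res <- list(estimate = sm[xname, 1], se = sm[xname, 2],
                df = m$df.residual, p_value = sm[xname, 4], engine = "lm")
  }
  res$n <- nrow(df)
  structure(res, class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("slope = %.4f (se %.4f), p = %.3g  [%s, n = %d]\n",
              x$estimate, x$se, x$p_value, x$engine, x$n))
  invisible(x)
}

#' Quadratic relationship between non-decision time and value
#'
#' Regresses subject- and condition-specific MAP non-decision times on the
#' quadratic regressor `(target_p - 0.5)^2` with random subject
#' intercepts. Requires a variant with per-condition `t0` (M2-family).
#'
#' @param map_df output of [map_table()] on an M2-family fit (columns
#'   `subject`, `target_p`, `t0`), or such a fit itself.
#' @return a `slope_test` (estimate, se, p) for the quadratic coefficient.
#' @export
t0_value_regression <- function(map_df) {
  map_df <- as_map_df(map_df, need_t0 = TRUE)
  map_df$q <- (map_df$target_p - 0.5)^2
  mixed_slope(map_df, "t0", "q")
}

#' Non-decision time versus minimum and median response time
#'
#' Regresses MAP non-decision times on the condition-wise minimum RT and,
#' separately, on the condition-wise median RT (random subject
#' intercepts).
#'
#' @param map_df see [t0_value_regression()].
#' @param summaries output of [condition_summary()] on the same data.
#' @return list with `min_rt` and `median_rt` slope tests.
#' @export
t0_rt_regressions <- function(map_df, summaries) {
  map_df <- as_map_df(map_df, need_t0 = TRUE)
  d <- merge(map_df[, c("subject", "condition", "t0")],
             summaries[, c("subject", "condition", "min_rt", "median_rt")],
             by = c("subject", "condition"))
  list(min_rt = mixed_slope(d, "t0", "min_rt"),
       median_rt = mixed_slope(d, "t0", "median_rt"))
}

as_map_df <- function(x, need_t0 = FALSE) {
  if (inherits(x, "hlba_fit")) {
    if (need_t0 && !"t0" %in% x$variant$free) {
      stop("variant ", x$variant$name,
           " has a single non-decision time; per-condition t0 analyses ",
           "need an M2-family fit")
    }
    x <- map_table(x)
  }
  x
}

#' Sigmoidal drift-rate / choice-probability linkage
#'
#' Fits, per subject, a trial-level logistic regression of delayed choices
#' on the MAP delayed drift rate of the trial's condition,
#' \eqn{P(\mathrm{delayed}) = \mathrm{logistic}(\beta_0 + \beta_1 \nu_d)},
#' with the drift regressor centred within subject for numerical
#' stability (the linear predictor is unchanged). A group-level one-sample
#' t-test on the per-subject slopes summarises the linkage.
#'
#' @param trials filtered trial table.
#' @param map_df MAP table ([map_table()]) or an `hlba_fit`.
#' @return object of class `drift_linkage`: per-subject coefficient table
#'   (`$subjects`, with flags for degenerate fits) and the group test
#'   (`$group`).
#' @export
drift_value_logistic <- function(trials, map_df) {
  map_df <- as_map_df(map_df)
  dat <- normalize_trials(trials)
  rows <- lapply(split(dat, dat$subject), function(d) {
    mp <- map_df[map_df$subject == d$subject[1], ]
    nu <- mp$nu_d[match(d$condition, mp$condition)]
    nu_c <- nu - mean(mp$nu_d)
    flag <- NA_character_
    if (stats::sd(nu) < 1e-8) {
      return(data.frame(subject = d$subject[1], beta0 = NA_real_,
                        beta1 = NA_real_, se1 = NA_real_,
                        nu_center = mean(mp$nu_d),
                        flag = "constant_drift"))
    }
    fit <- suppressWarnings(stats::glm(d$choice ~ nu_c, family = stats::binomial()))
    if (!fit$converged) flag <- "not_converged"
    if (any(abs(coef(fit)) > 50)) flag <- "separation"
    sm <- summary(fit)$coefficients
    data.frame(subject = d$subject[1], beta0 = sm[1, 1], beta1 = sm[2, 1],
               se1 = sm[2, 2], nu_center = mean(mp$nu_d), flag = flag)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- is.na(tab$flag) & is.finite(tab$beta1)
  grp <- if (sum(ok) >= 2) {
    tt <- stats::t.test(tab$beta1[ok])
    list(mean_beta1 = unname(tt$estimate), se = unname(tt$stderr),
         p_value = tt$p.value, n = sum(ok))
  } else list(mean_beta1 = NA_real_, se = NA_real_, p_value = NA_real_,
              n = sum(ok))
  structure(list(subjects = tab, group = grp), class = "drift_linkage")
}

#' @export
print.drift_linkage <- function(x, ...) {
  cat(sprintf("Drift-value logistic linkage: mean beta1 = %.2f (se %.2f), p = %.3g over %d subjects\n",
              x$group$mean_beta1, x$group$se, x$group$p_value, x$group$n))
  if (any(!is.na(x$subjects$flag))) {
    cat("  flagged subjects:", sum(!is.na(x$subjects$flag)), "\n")
  }
  invisible(x)
}

#' Identity test between softmax value scaling and drift-rate linkage
#'
#' If drift rates are a linear transform of subjective value, the softmax
#' and drift-based logistic descriptions of choice coincide, so
#' \eqn{m (V_D - 10) = \beta_0 + \beta_1 \nu_d} should hold with all
#' components estimated independently. The left side uses each subject's
#' discounting fit (sensitivity `m` and the model-implied mean subjective
#' value of the condition's offers); the right side uses the per-subject
#' logistic coefficients and MAP drifts. The regression of left on right
#' (random subject intercepts) should have slope near one.
#'
#' @param linkage a [drift_value_logistic()] result.
#' @param discount_fits named list of [discount_fit] objects, one per
#'   subject (any of the three value models).
#' @param trials filtered trial table (supplies each subject x condition's
#'   offers).
#' @param map_df MAP table or `hlba_fit` (drift rates).
#' @return a `slope_test` for the identity slope.
#' @export
identity_test <- function(linkage, discount_fits, trials, map_df) {
  map_df <- as_map_df(map_df)
  dat <- normalize_trials(trials)
  raw <- if ("delayed_amount" %in% names(trials)) trials else
    stop("trials need delayed_amount and delay_days columns")
  missing <- setdiff(unique(dat$subject), names(discount_fits))
  if (length(missing)) {
    stop("missing discounting fits for subjects: ",
         paste(missing, collapse = ", "))
  }
  subj <- if ("subject_id" %in% names(raw)) raw$subject_id else raw$subject
  rows <- list()
  for (s in unique(dat$subject)) {
    dfit <- discount_fits[[as.character(s)]]
    lk <- linkage$subjects[linkage$subjects$subject == s, ]
    if (!nrow(lk) || is.na(lk$beta1)) next
    mp <- map_df[map_df$subject == s, ]
    di <- dat$subject == s
    for (cond in sort(unique(dat$condition[di]))) {
      i <- di & dat$condition == cond
      v_d <- mean(subjective_value(raw$delayed_amount[i & (subj == s)],
                                   raw$delay_days[i & (subj == s)], dfit))
      nu <- mp$nu_d[mp$condition == cond]
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, condition = cond,
        lhs = dfit$m * (v_d - 10),
        rhs = lk$beta0 + lk$beta1 * (nu - lk$nu_center))
    }
  }
  d <- do.call(rbind, rows)
  mixed_slope(d, "lhs", "rhs")
}

#' Run the identity test under all three value models
#'
#' Refits the discounting model per subject for each of the hyperbolic,
#' exponential and quasi-hyperbolic value functions and repeats
#' [identity_test()] with each, testing whether the drift-value relation
#' depends on the assumed discounting form.
#'
#' @param trials filtered trial table (with `delayed_amount`,
#'   `delay_days`).
#' @param map_df MAP table or `hlba_fit`.
#' @param models value models to run.
#' @return named list of `slope_test`s.
#' @export
identity_tests_all_models <- function(trials, map_df,
                                      models = c("hyperbolic", "exponential",
                                                 "quasi_hyperbolic")) {
  map_df <- as_map_df(map_df)
  linkage <- drift_value_logistic(trials, map_df)
  dat <- normalize_trials(trials)
  subj_col <- if ("subject_id" %in% names(trials)) trials$subject_id else trials$subject
  out <- list()
  for (m in models) {
    fits <- lapply(unique(dat$subject), function(s) {
      fit_discounting(trials[subj_col == s, , drop = FALSE], model = m)
    })
    names(fits) <- unique(dat$subject)
    out[[m]] <- identity_test(linkage, fits, trials, map_df)
  }
  out
}
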