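#' Read and write trial tables
#'
#' Trial tables are tab-delimited text with header columns `subject_id`,
#' `session`, `condition_target_p`, `delay_days`, `delayed_amount`,
#' `choice` (0 = immediate, 1 = delayed) and `rt_seconds` (empty for
#' session-1 staircase trials; measured from decision-period onset).
#'
#' @param path file path.
#' @param trials trial data frame.
#' @return `read_trials`: validated data frame; `write_trials`: the path,
#'   invisibly.
#' @export
read_trials <- function(path) {
  tr <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "condition_target_p", "delay_days",
            "delayed_amount", "choice", "rt_seconds")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("trial table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!tr$choice %in% c(0, 1))
  if (length(bad)) {
    stop("invalid choice values (must be 0/1) in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(!is.na(tr$rt_seconds) & tr$rt_seconds < 0)
  if (length(bad)) {
    stop("negative rt_seconds in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  tr
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read posterior draws as long-format text
#'
#' The draw file is tab-delimited with columns `level`
#' (`subject`/`group_mu`/`group_sigma`), `subject`, `parameter`, `chain`,
#' `iteration`, `value` (transformed scale); the companion summary file
#' holds group-level posterior means, sds, credible intervals and split
#' R-hat, plus a configuration echo as comment lines.
#'
#' @param fit an `hlba_fit`.
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_posterior <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(fit$draws$theta)  # S d C K
  S <- dims[1]; d <- dims[2]; C <- dims[3]; K <- dims[4]
  pn <- fit$variant$par_names
  subj_long <- data.frame(
    level = "subject",
    subject = rep(fit$subjects, times = d * C * K),
    parameter = rep(rep(pn, each = S), times = C * K),
    chain = rep(rep(seq_len(C), each = S * d), times = K),
    iteration = rep(seq_len(K), each = S * d * C),
    value = as.numeric(fit$draws$theta))
  grp_long <- function(arr, lvl) data.frame(
    level = lvl, subject = NA,
    parameter = rep(pn, times = C * K),
    chain = rep(rep(seq_len(C), each = d), times = K),
    iteration = rep(seq_len(K), each = d * C),
    value = as.numeric(arr))
  draws_path <- file.path(dir, "posterior_draws.tsv")
  write.table(rbind(subj_long, grp_long(fit$draws$mu, "group_mu"),
                    grp_long(fit$draws$sigma, "group_sigma")),
              draws_path, sep = "\t", quote = FALSE, row.names = FALSE)

  sm <- summary(fit)$group
  summary_path <- file.path(dir, "posterior_summary.tsv")
  ctl <- fit$control
  con <- file(summary_path, "w")
  writeLines(c(
    sprintf("# variant: %s", fit$variant$name),
    sprintf("# subjects: %d", S),
    sprintf("# chains: %d burn_in: %d keep: %d thin: %d seed: %d",
            ctl$n_chains, ctl$burn_in, ctl$keep, ctl$thin, ctl$seed),
    sprintf("# retained_draws: %d", fit$n_retained)), con)
  close(con)
  suppressWarnings(write.table(sm, summary_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(c(draws = draws_path, summary = summary_path))
}

#' @rdname write_posterior
#' @param path path to a `posterior_draws.tsv` file.
#' @export
read_posterior_draws <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
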