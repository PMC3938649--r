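#' Model variant specifications (M1–M8)
#'
#' The variant lattice controls which LBA parameters are free to vary
#' across the five value conditions. The delayed mean drift `nu_d` always
#' varies by condition. M1 frees nothing else (9 subject parameters);
#' M2 additionally frees the non-decision time `t0` (13); M3/M4/M5 instead
#' free `A` / the threshold gap `b` / `s` (13 each); M6/M7/M8 free `t0`
#' together with `A` / `b` / `s` (17 each). Freeing "b" frees the threshold
#' gap `chi = b - A` with `A` common, so the threshold itself varies;
#' freeing "A" varies the start-point range (and with it the threshold,
#' since `chi` stays common).
#'
#' @param name one of `"M1"`..`"M8"`.
#' @return a `variant_spec` list with elements `name`, `free` (parameters
#'   free across conditions besides `nu_d`), `n_params`, `par_names`, and
#'   an index map used internally.
#' @export
variant_spec <- function(name) {
  free <- switch(name,
    M1 = character(0),
    M2 = "t0",
    M3 = "A",
    M4 = "b",
    M5 = "s",
    M6 = c("t0", "A"),
    M7 = c("t0", "b"),
    M8 = c("t0", "s"),
    stop("unknown variant '", name, "'; available: ",
         paste(lba_variants(), collapse = ", ")))
  base <- c(A = "A", chi = "b", s = "s", t0 = "t0")
  idx <- list(); par_names <- character(0); pos <- 0L
  for (p in names(base)) {
    k <- if (base[[p]] %in% free) 5L else 1L
    idx[[p]] <- pos + seq_len(k)
    pos <- pos + k
    nm <- paste0("log_", p)
    par_names <- c(par_names, if (k == 1) nm else paste0(nm, "[", 1:5, "]"))
  }
  idx$nu <- pos + 1:5
  par_names <- c(par_names, paste0("logit_nu[", 1:5, "]"))
  structure(list(name = name, free = free, n_params = pos + 5L,
                 par_names = par_names, idx = idx),
            class = "variant_spec")
}

#' @rdname variant_spec
#' @export
lba_variants <- function() paste0("M", 1:8)

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("Variant %s: nu_d%s free across conditions; %d subject parameters\n",
              x$name,
              if (length(x$free)) paste0(", ", paste(x$free, collapse = ", ")) else "",
              x$n_params))
  invisible(x)
}

#' Parameter transforms between natural and unconstrained scales
#'
#' Subject parameters are sampled on an unconstrained scale: log for the
#' positive parameters (`A`, `chi = b - A`, `s`, `t0`) and logit for the
#' drift rates (bounded by 0 and 1). `to_transformed` compresses an
#' [lba_params] object to the variant's parameter vector (condition-common
#' parameters must be constant across conditions); `from_transformed`
#' inverts it.
#'
#' @param params an [lba_params] object.
#' @param theta named numeric vector of length `variant$n_params`.
#' @param variant a [variant_spec] or variant name.
#' @return `to_transformed`: named numeric vector; `from_transformed`: an
#'   [lba_params] object.
#' @export
to_transformed <- function(params, variant = "M2") {
  spec <- as_variant(variant)
  take <- function(x, free) {
    if (free) return(x)
    if (diff(range(x)) > 1e-12) {
      stop("parameter constant under ", spec$name, " but varies by condition")
    }
    x[1]
  }
  if (any(params$t0 <= 0)) stop("log transform requires t0 > 0")
  th <- c(log(take(params$A, "A" %in% spec$free)),
          log(take(params$chi, "b" %in% spec$free)),
          log(take(params$s, "s" %in% spec$free)),
          log(take(params$t0, "t0" %in% spec$free)),
          qlogis(params$nu_d))
  names(th) <- spec$par_names
  th
}

#' @rdname to_transformed
#' @export
from_transformed <- function(theta, variant = "M2") {
  spec <- as_variant(variant)
  if (length(theta) != spec$n_params) {
    stop("theta must have length ", spec$n_params, " for ", spec$name)
  }
  g <- function(p) exp(theta[spec$idx[[p]]])
  lba_params(A = g("A"), chi = g("chi"), s = g("s"), t0 = g("t0"),
             nu_d = plogis(theta[spec$idx$nu]))
}

as_variant <- function(variant) {
  if (inherits(variant, "variant_spec")) variant else variant_spec(variant)
}

# Decode a (n_params x n_chains) matrix of transformed parameters into
# 5 x n_chains natural-scale matrices for the vectorised likelihood.
decode_chains <- function(theta, spec) {
  expand <- function(rows) {
    m <- exp(theta[rows, , drop = FALSE])
    if (nrow(m) == 1) m[rep(1L, 5), , drop = FALSE] else m
  }
  A <- expand(spec$idx$A)
  chi <- expand(spec$idx$chi)
  list(A = A, b = A + chi, s = expand(spec$idx$s), t0 = expand(spec$idx$t0),
       nu = plogis(theta[spec$idx$nu, , drop = FALSE]))
}
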