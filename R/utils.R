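#' Derive a reproducible child seed from a base seed and a label
#'
#' Every stochastic stage of the pipeline draws its random stream from a seed
#' derived from `(base seed, stage label, unit id)`, so stages and subjects are
#' independently reproducible. The derivation is a small multiplicative hash
#' kept strictly below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed base integer seed.
#' @param ... further integer or character labels (stage name, subject id, ...).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    for (el in part) {
      codes <- if (is.character(el)) utf8ToInt(el) else as.numeric(el)
      for (v in codes) {
        h <- (h * 48271 + (v %% m) + 1) %% m
      }
    }
  }
  as.integer(h)
}

#' Round a dollar amount to whole cents
#' @param x numeric dollars.
#' @return `x` rounded to 2 decimal places.
#' @export
round_money <- function(x) round(x, 2)

## logistic helpers (kept explicit so model code reads like the equations)
logistic <- function(eta) stats::plogis(eta)
logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

## internal: stop with a named-bound configuration message
config_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
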