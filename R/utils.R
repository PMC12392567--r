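# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage substream seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage
#' draws from its own substream so that adding a stage never perturbs the
#' streams of the others. Kept below 2^31 - 1 so the result is a valid R
#' integer seed.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  invisible(x)
}

# logistic helpers used by panel_select and validate
plogis_clip <- function(eta) {
  p <- stats::plogis(eta)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
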