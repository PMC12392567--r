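# Passing-Bablok method-comparison regression and application of the
# resulting conversion formulas across assay platforms.

#' Passing-Bablok method-comparison regression
#'
#' Classical procedure (the variant assuming the two methods are
#' positively related, as two assays of the same analyte are): all
#' pairwise slopes \code{S_ij = (y_j - y_i)/(x_j - x_i)} for \code{i < j}
#' with \code{x_i != x_j} are formed; slopes equal to -1 are discarded
#' and \code{K}, the number of slopes below -1, shifts the median, making
#' the estimator invariant to swapping the axes. The slope is the
#' K-offset median of the sorted slopes; the intercept is
#' \code{median(y - slope * x)}. The 95 percent slope CI comes from the
#' rank-based normal approximation
#' \code{C = 1.96 * sqrt(n (n-1) (2n+5) / 18)}; intercept bounds are
#' recomputed from the CI-boundary slopes (upper slope gives the lower
#' intercept bound). The estimator is robust: single gross outliers move
#' it far less than least squares.
#'
#' @param pairs a \code{paired_measurements} (see
#'   \code{\link{simulate_paired_measurements}}) or a list/data.frame
#'   with numeric \code{x} and \code{y}.
#' @param conf_level confidence level (fixed normal quantile 1.96 at the
#'   default 0.95).
#' @return a \code{conversion_fit}: slope, intercept, slope_ci,
#'   intercept_ci, n_pairs, n_slopes_used.
#' @export
passing_bablok <- function(pairs, conf_level = 0.95) {
  x <- pairs$x; y <- pairs$y
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (all(x == x[1])) stop("all x values identical; no slope is estimable",
                           call. = FALSE)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  S <- dy[dx != 0] / dx[dx != 0]
  S <- S[S != -1]           # exactly -1 carries no direction information
  N <- length(S)
  if (N == 0) stop("no usable pairwise slopes", call. = FALSE)
  S <- sort(S)
  K <- sum(S < -1)
  # shifted median: offset the central rank(s) by K
  slope <- if (N %% 2 == 1) S[(N + 1) / 2 + K]
           else mean(S[c(N / 2 + K, N / 2 + 1 + K)])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  lo <- S[max(1, M1 + K)]
  hi <- S[min(N, M2 + K)]
  intercept <- stats::median(y - slope * x)
  structure(list(slope = slope, intercept = intercept,
                 slope_ci = c(lower = lo, upper = hi),
                 intercept_ci = c(lower = stats::median(y - hi * x),
                                  upper = stats::median(y - lo * x)),
                 n_pairs = n, n_slopes_used = N),
            class = "conversion_fit")
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat(sprintf("<conversion_fit> y = %.4g x + %.4g  (n = %d, %d pairwise slopes)\n",
              x$slope, x$intercept, x$n_pairs, x$n_slopes_used))
  cat(sprintf("  slope 95%% CI [%.4g, %.4g], intercept 95%% CI [%.4g, %.4g]\n",
              x$slope_ci[1], x$slope_ci[2], x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Apply (or invert) a platform conversion
#'
#' @param values numeric vector on the source platform's scale.
#' @param fit a \code{conversion_fit} (or any list with slope and
#'   intercept).
#' @param inverse if TRUE, map method-B values back to method-A units via
#'   \code{(value - intercept) / slope}.
#' @return converted values.
#' @export
convert_values <- function(values, fit, inverse = FALSE) {
  if (!is.finite(fit$slope) || !is.finite(fit$intercept))
    stop("conversion fit must be finite", call. = FALSE)
  if (inverse) {
    if (fit$slope == 0) stop("slope 0 cannot be inverted", call. = FALSE)
    (values - fit$intercept) / fit$slope
  } else {
    fit$slope * values + fit$intercept
  }
}

#' Write / read a conversion fit as JSON
#'
#' Schema: \code{\{slope, intercept, slope_ci, intercept_ci, n_pairs\}}.
#'
#' @param fit a \code{conversion_fit}.
#' @param path JSON file path.
#' @return \code{path} (write) or a \code{conversion_fit} (read).
#' @export
write_conversion_json <- function(fit, path) {
  jsonlite::write_json(list(slope = fit$slope, intercept = fit$intercept,
                            slope_ci = as.list(fit$slope_ci),
                            intercept_ci = as.list(fit$intercept_ci),
                            n_pairs = fit$n_pairs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_conversion_json
#' @export
read_conversion_json <- function(path) {
  o <- jsonlite::read_json(path)
  structure(list(slope = as.numeric(o$slope), intercept = as.numeric(o$intercept),
                 slope_ci = c(lower = as.numeric(o$slope_ci$lower),
                              upper = as.numeric(o$slope_ci$upper)),
                 intercept_ci = c(lower = as.numeric(o$intercept_ci$lower),
                                  upper = as.numeric(o$intercept_ci$upper)),
                 n_pairs = as.integer(o$n_pairs),
                 n_slopes_used = NA_integer_),
            class = "conversion_fit")
}
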