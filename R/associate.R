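# Covariate-adjusted partial non-parametric correlations between panel
# proteins and clinical scores.

#' Partial Spearman correlation
#'
#' Rank-transforms both variables and every covariate column (average
#' ranks for ties), residualizes the two ranked variables on the ranked
#' covariates by least squares, and correlates the residuals; the p-value
#' uses the t approximation with \code{n - 2 - k} degrees of freedom
#' (k = covariate columns). With no covariates this reduces exactly to
#' the plain Spearman coefficient. Being rank-based, it is invariant to
#' strictly monotone transforms of either variable. Rows with any missing
#' value among a, b and the covariates are dropped (listwise per pair).
#'
#' @param a,b numeric vectors.
#' @param covariates optional data.frame/matrix; character or factor
#'   columns are dummy-coded (one-hot, first level dropped).
#' @return list: rho, p, n_used, covariates (column names after coding).
#' @export
partial_spearman <- function(a, b, covariates = NULL) {
  cv <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- dummy_code(as.data.frame(covariates))
  }
  ok <- !is.na(a) & !is.na(b)
  if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
  a <- a[ok]; b <- b[ok]
  cv <- if (is.null(cv)) NULL else cv[ok, , drop = FALSE]
  k <- if (is.null(cv)) 0L else ncol(cv)
  n <- length(a)
  if (n < k + 3) stop("need at least k + 3 complete observations", call. = FALSE)
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("constant variable after ranking", call. = FALSE)
  if (k > 0) {
    rc <- apply(cv, 2, rank)
    qx <- qr(cbind(1, rc))
    ra <- qr.resid(qx, ra)
    rb <- qr.resid(qx, rb)
    if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
      stop("variable is fully explained by the covariates", call. = FALSE)
  }
  rho <- stats::cor(ra, rb)
  df <- n - 2 - k
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(rho = rho, p = p, n_used = n,
       covariates = if (is.null(cv)) character(0) else colnames(cv))
}

# one-hot coding with the first level dropped; numeric columns pass through
dummy_code <- function(df) {
  out <- NULL
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x) || is.logical(x)) {
      col <- matrix(as.numeric(x), ncol = 1,
                    dimnames = list(NULL, nm))
    } else {
      f <- factor(x)
      lv <- levels(f)
      if (length(lv) < 2) next  # constant categorical adjusts nothing
      col <- vapply(lv[-1], function(l) as.numeric(f == l),
                    numeric(length(f)))
      col <- matrix(col, ncol = length(lv) - 1,
                    dimnames = list(NULL, paste(nm, lv[-1], sep = "_")))
      col[is.na(f), ] <- NA
    }
    out <- cbind(out, col)
  }
  out
}

#' Partial-Spearman correlation matrix of panel proteins and clinical scores
#'
#' All pairwise covariate-adjusted rank correlations between the given
#' variables (typically the panel markers plus MMSE and FTLD-CDR),
#' computed in the full cohort or within one diagnostic group. Pairs that
#' fail (e.g. a score constant within the chosen group) are recorded as
#' missing cells, not errors.
#'
#' @param npx an \code{\link{npx_matrix}}.
#' @param meta sample metadata.
#' @param markers protein IDs to include.
#' @param scores metadata score columns to include (default MMSE and
#'   FTLD-CDR).
#' @param covariates metadata columns to adjust for; categorical columns
#'   (e.g. the FTLD-CDR rater) are dummy-coded.
#' @param group optional diagnostic group to restrict to.
#' @return list: \code{rho} and \code{p} matrices (diagonal 1 / 0),
#'   \code{n_used}, and \code{long} (variable_a, variable_b, rho, p,
#'   n_used).
#' @export
correlation_matrix <- function(npx, meta, markers,
                               scores = c("mmse", "ftld_cdr"),
                               covariates = c("age", "sex", "cdr_rater"),
                               group = NULL) {
  validate_metadata(meta, npx)
  keep <- subset_analysis(meta)
  if (!is.null(group)) keep <- keep & group_label(meta) == group
  m <- meta[keep, , drop = FALSE]
  miss <- setdiff(markers, protein_ids(npx))
  if (length(miss))
    stop("marker(s) not in the matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vars <- cbind(as.data.frame(npx$values[m$sample_id, markers, drop = FALSE]),
                m[, intersect(scores, names(m)), drop = FALSE])
  if (ncol(vars) < 2) stop("need at least 2 variables", call. = FALSE)
  cov_df <- m[, intersect(covariates, names(m)), drop = FALSE]
  nm <- colnames(vars)
  rho <- p <- nu <- matrix(NA_real_, length(nm), length(nm),
                           dimnames = list(nm, nm))
  diag(rho) <- 1; diag(p) <- 0
  long <- NULL
  for (i in seq_along(nm)[-length(nm)]) {
    for (j in seq((i + 1), length(nm))) {
      res <- tryCatch(partial_spearman(vars[[i]], vars[[j]], cov_df),
                      error = function(e) NULL)
      if (!is.null(res)) {
        rho[i, j] <- rho[j, i] <- res$rho
        p[i, j] <- p[j, i] <- res$p
        nu[i, j] <- nu[j, i] <- res$n_used
      }
      long <- rbind(long, data.frame(
        variable_a = nm[i], variable_b = nm[j],
        rho = if (is.null(res)) NA_real_ else res$rho,
        p = if (is.null(res)) NA_real_ else res$p,
        n_used = if (is.null(res)) NA_integer_ else res$n_used,
        stringsAsFactors = FALSE))
    }
  }
  list(rho = rho, p = p, n_used = nu, long = long)
}
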