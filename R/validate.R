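# External-cohort validation of frozen panels (including partial marker
# availability), cross-cohort fold-change concordance, and single-marker
# comparators.

boot_auc_ci <- function(scores, labels, n_boot = 2000, seed) {
  y <- as_binary(labels)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  pos <- which(y == 1); neg <- which(y == 0)
  stats_boot <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    auc(scores[idx], y[idx])
  }, numeric(1))
  stats::quantile(stats_boot, c(0.025, 0.975), names = FALSE)
}

#' Validate a panel in an external cohort
#'
#' Frozen mode scores the cohort with the panel's stored coefficients and
#' training standardization parameters; markers absent from the cohort
#' are dropped together with their coefficients (never imputed), and the
#' AUC gets a stratified-bootstrap percentile CI (2000 resamples). Refit
#' mode re-estimates the ridge signature within the cohort on the
#' available markers and evaluates it by
#' \code{\link{repeated_cv_auc}}. Refit is the default because a panel
#' re-measured on a different assay generation is on a different scale;
#' the mode is recorded in the report.
#'
#' @param panel a \code{panel_model}.
#' @param npx cohort \code{\link{npx_matrix}}.
#' @param meta cohort metadata.
#' @param positive,negative group labels defining the classification.
#' @param mode "refit" (default) or "frozen".
#' @param covariates covariate column names (must match the panel's terms
#'   in frozen mode when the panel has any).
#' @param repeats,folds repeated-CV controls for refit mode.
#' @param n_boot bootstrap resamples for the frozen-mode CI.
#' @param seed integer seed.
#' @return a \code{validation_report}: cohort, mode, markers_used,
#'   markers_missing, auc, auc_ci, performance (a \code{cv_performance}
#'   in refit mode), scores, labels.
#' @export
apply_panel <- function(panel, npx, meta, positive, negative,
                        mode = c("refit", "frozen"),
                        covariates = names(panel$covariate_terms),
                        repeats = 1000, folds = 5, n_boot = 2000, seed,
                        cohort = "validation") {
  mode <- match.arg(mode)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(inherits(panel, "panel_model"))
  validate_metadata(meta, npx)
  glab <- group_label(meta)
  keep <- subset_analysis(meta) & glab %in% c(positive, negative)
  m <- meta[keep, , drop = FALSE]
  if (length(covariates)) {
    cc <- stats::complete.cases(m[, covariates, drop = FALSE])
    m <- m[cc, , drop = FALSE]
  }
  X <- npx$values[m$sample_id, , drop = FALSE]
  y <- as.integer(group_label(m) == positive)
  if (!any(y == 1) || !any(y == 0))
    stop("both groups must be present in the cohort", call. = FALSE)
  used <- intersect(panel$markers, colnames(X))
  missing_mk <- setdiff(panel$markers, colnames(X))
  if (!length(used))
    stop("no panel marker is measured in this cohort", call. = FALSE)
  cov_df <- if (length(covariates)) m[, covariates, drop = FALSE] else NULL

  if (mode == "frozen") {
    sub <- panel
    sub$markers <- used
    sub$coefficients <- panel$coefficients[used]
    sub$standardization <- list(mean = panel$standardization$mean[used],
                                sd = panel$standardization$sd[used])
    scores <- predict(sub, X, covariates = cov_df)
    a <- auc(scores, y)
    ci <- boot_auc_ci(scores, y, n_boot, substream_seed(seed, "frozen_boot"))
    perf <- NULL
  } else {
    perf <- repeated_cv_auc(X[, used, drop = FALSE], y, covariates = cov_df,
                            penalty = panel$penalty, folds = folds,
                            repeats = repeats, seed = seed)
    refit <- ridge_refit(X[, used, drop = FALSE], y, covariates = cov_df,
                         penalty = panel$penalty, trained_on = cohort,
                         seed = as.integer(seed))
    scores <- predict(refit, X, covariates = cov_df)
    a <- perf$auc_mean
    ci <- perf$auc_ci
  }
  structure(list(cohort = cohort, mode = mode, markers_used = used,
                 markers_missing = missing_mk, auc = a,
                 auc_ci = c(lower = ci[[1]], upper = ci[[2]]),
                 performance = perf, scores = scores, labels = y),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> cohort '%s' (%s mode): AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$cohort, x$mode, x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  markers used: %d, missing: %d\n",
              length(x$markers_used), length(x$markers_missing)))
  invisible(x)
}

#' Cross-cohort concordance of per-protein fold changes
#'
#' Spearman rank correlation of the betas (log2 fold-changes) estimated
#' in two cohorts over their common proteins, with the t-approximation
#' p-value.
#'
#' @param discovery,validation \code{\link{nested_lm_contrast}} results.
#' @param proteins optional protein set to restrict to (default: all
#'   proteins present in both with non-missing betas).
#' @return list: rho, p, n.
#' @export
beta_concordance <- function(discovery, validation, proteins = NULL) {
  common <- intersect(discovery$protein_id, validation$protein_id)
  if (!is.null(proteins)) common <- intersect(common, proteins)
  b1 <- discovery$beta[match(common, discovery$protein_id)]
  b2 <- validation$beta[match(common, validation$protein_id)]
  ok <- !is.na(b1) & !is.na(b2)
  if (sum(ok) < 3) stop("need >= 3 common proteins with betas", call. = FALSE)
  ct <- stats::cor.test(b1[ok], b2[ok], method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Single-marker (or marker-ratio) ROC performance
#'
#' AUC of one measured value (or of a derived ratio such as pTau/tTau)
#' against a binary outcome, with a stratified-bootstrap percentile CI.
#'
#' @param values numeric marker values, or when \code{denominator} is
#'   given the numerator of a ratio.
#' @param labels binary labels.
#' @param denominator optional vector; scores become
#'   \code{values / denominator}.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list: auc, ci, n.
#' @export
single_marker_roc <- function(values, labels, denominator = NULL,
                              n_boot = 2000, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  scores <- if (is.null(denominator)) values else values / denominator
  a <- auc(scores, labels)
  ci <- boot_auc_ci(scores, labels, n_boot, substream_seed(seed, "marker_boot"))
  list(auc = a, ci = c(lower = ci[1], upper = ci[2]),
       n = sum(!is.na(scores) & !is.na(labels)))
}
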