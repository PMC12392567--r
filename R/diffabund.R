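# Per-protein differential abundance via nested linear models with
# covariate adjustment, BH FDR control, cross-contrast overlap
# categorization, sensitivity re-analysis, and hypergeometric term
# enrichment against a fixed background.

#' Nested linear-model contrast for every protein
#'
#' For each protein, fits the full model \code{NPX ~ group + covariates}
#' and the reduced model \code{NPX ~ covariates} by least squares and
#' tests the group term with the nested-model F comparison (1 numerator
#' degree of freedom for a two-level group). \code{beta} is the
#' group-indicator coefficient, reported as \code{group} minus
#' \code{reference} (disease minus reference, matching volcano-plot
#' directionality); on log2-scale NPX it is a log2 fold-change. Samples
#' with missing NPX or covariates are dropped per protein and
#' \code{n_used} records it. QC and bridging measurements are never used.
#'
#' @param npx an \code{\link{npx_matrix}}.
#' @param meta sample metadata.
#' @param group,reference group labels; the contrast is
#'   \code{group - reference}.
#' @param covariates metadata column names entering both models
#'   (default \code{c("age", "sex")}; may be empty). A covariate that is
#'   constant in the analysed samples is an error.
#' @param q_method multiplicity correction applied per contrast over all
#'   tested proteins ("BH").
#' @return a \code{differential_result} data.frame: protein_id, beta, se,
#'   p, q, n_used, direction; the contrast is in
#'   \code{attr(, "contrast")}.
#' @export
nested_lm_contrast <- function(npx, meta, group, reference,
                               covariates = c("age", "sex"),
                               q_method = "BH") {
  stopifnot(inherits(npx, "npx_matrix"))
  validate_metadata(meta, npx)
  for (g in c(group, reference)) {
    sel <- subset_analysis(meta)
    if (!any(group_label(meta)[sel] == g))
      stop("group '", g, "' absent from metadata", call. = FALSE)
  }
  glab <- group_label(meta)
  keep <- subset_analysis(meta) & glab %in% c(group, reference)
  m <- meta[keep, , drop = FALSE]
  Y <- npx$values[m$sample_id, , drop = FALSE]
  missing_cov <- setdiff(covariates, names(m))
  if (length(missing_cov))
    stop("covariate(s) not in metadata: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  cov_ok <- stats::complete.cases(m[, covariates, drop = FALSE])
  m <- m[cov_ok, , drop = FALSE]
  Y <- Y[cov_ok, , drop = FALSE]
  if (sum(glab[keep][cov_ok] == group) < 3 ||
      sum(glab[keep][cov_ok] == reference) < 3)
    stop("each group needs >= 3 samples with complete covariates", call. = FALSE)
  g01 <- as.numeric(group_label(m) == group)
  Xr <- matrix(1, nrow(m), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    x <- m[[cv]]
    if (length(unique(x)) < 2)
      stop("covariate '", cv, "' is constant in the analysed samples",
           call. = FALSE)
    Xr <- cbind(Xr, x)
    colnames(Xr)[ncol(Xr)] <- cv
  }
  Xf <- cbind(Xr[, 1, drop = FALSE], grp = g01,
              Xr[, -1, drop = FALSE])

  fit_one_block <- function(Xf, Xr, Y) {
    n <- nrow(Xf)
    qf <- qr(Xf)
    if (qf$rank < ncol(Xf)) return(NULL)  # singular design
    res_f <- qr.resid(qf, Y)
    res_r <- qr.resid(qr(Xr), Y)
    rss_f <- colSums(res_f^2)
    rss_r <- colSums(res_r^2)
    df2 <- n - ncol(Xf)
    Fstat <- (rss_r - rss_f) / (rss_f / df2)
    p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
    beta <- qr.coef(qf, Y)["grp", ]
    sigma2 <- rss_f / df2
    gg <- solve(crossprod(Xf))[2, 2]  # (X'X)^-1 entry for the group column
    list(beta = beta, se = sqrt(sigma2 * gg), p = p, n = n)
  }

  pids <- protein_ids(npx)
  beta <- se <- p <- rep(NA_real_, length(pids))
  n_used <- integer(length(pids))
  full <- !is.na(colSums(Y))
  singular <- 0L
  if (any(full)) {
    fb <- fit_one_block(Xf, Xr, Y[, full, drop = FALSE])
    if (is.null(fb)) {
      singular <- singular + sum(full)
    } else {
      beta[full] <- fb$beta; se[full] <- fb$se; p[full] <- fb$p
      n_used[full] <- fb$n
    }
  }
  for (j in which(!full)) {
    ok <- !is.na(Y[, j])
    if (sum(g01[ok] == 1) < 3 || sum(g01[ok] == 0) < 3) { n_used[j] <- sum(ok); next }
    fb <- fit_one_block(Xf[ok, , drop = FALSE], Xr[ok, , drop = FALSE],
                        Y[ok, j, drop = FALSE])
    if (is.null(fb)) { singular <- singular + 1L; n_used[j] <- sum(ok); next }
    beta[j] <- fb$beta; se[j] <- fb$se; p[j] <- fb$p; n_used[j] <- fb$n
  }
  if (singular > 0)
    warning(singular, " protein fit(s) had a singular design; reported as NA")
  q <- rep(NA_real_, length(pids))
  tested <- !is.na(p)
  q[tested] <- fdr_adjust(p[tested], method = q_method)
  out <- data.frame(protein_id = pids, beta = beta, se = se, p = p, q = q,
                    n_used = n_used, direction = sign(beta),
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- c(group = group, reference = reference)
  class(out) <- c("differential_result", class(out))
  out
}

group_label <- function(meta) {
  # FTLD subtypes are addressable as groups for the subtype contrasts
  g <- meta$group
  if ("subtype" %in% names(meta)) {
    st <- meta$subtype
    g[!is.na(st) & st %in% c("FTLD-Tau", "FTLD-TDP")] <-
      st[!is.na(st) & st %in% c("FTLD-Tau", "FTLD-TDP")]
    g[meta$group == "CON"] <- "CON"
    g[meta$group == "AD"] <- "AD"
  }
  g
}

subset_analysis <- function(meta) {
  !(isTRUE_vec(meta$is_qc %||% FALSE) | isTRUE_vec(meta$is_bridging %||% FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment over the tested features of one contrast.
#'
#' @param p p-value vector, all in [0, 1].
#' @param method adjustment method passed to \code{\link[stats]{p.adjust}}.
#' @return q-values in [0, 1], same order as \code{p}.
#' @export
fdr_adjust <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no NA", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Categorize proteins by their pattern of significance across contrasts
#'
#' Partition driven by three pairwise contrasts at FDR threshold
#' \code{alpha}: FTD-unique (significant vs controls and vs AD, not
#' AD vs controls), shared-dementia (significant in FTD vs controls and
#' AD vs controls but not between the dementias), significant in all
#' three split by direction into opposite-direction versus
#' AD-dominant-shared, AD-only (no FTD-vs-controls signal), else none.
#'
#' @param res_ftd_con,res_ftd_ad,res_ad_con
#'   \code{\link{nested_lm_contrast}} results over the same protein set.
#' @param alpha q-value threshold.
#' @return data.frame: protein_id, category.
#' @export
categorize_overlap <- function(res_ftd_con, res_ftd_ad, res_ad_con,
                               alpha = 0.05) {
  pid <- res_ftd_con$protein_id
  if (!identical(pid, res_ftd_ad$protein_id) ||
      !identical(pid, res_ad_con$protein_id))
    stop("the three contrasts must cover the same proteins in the same order",
         call. = FALSE)
  sig <- function(r) !is.na(r$q) & r$q <= alpha
  sf <- sig(res_ftd_con); sa <- sig(res_ftd_ad); sc <- sig(res_ad_con)
  category <- rep("none", length(pid))
  category[sf & sa & !sc] <- "ftd_unique"
  category[sf & !sa & sc] <- "shared_dementia"
  all3 <- sf & sa & sc
  opp <- all3 & sign(res_ftd_con$beta) != sign(res_ad_con$beta)
  category[all3 & !opp] <- "ad_dominant_shared"
  category[opp] <- "opposite_direction"
  category[!sf & (sc | sa)] <- "ad_only"
  data.frame(protein_id = pid, category = category, stringsAsFactors = FALSE)
}

#' Sensitivity re-analysis excluding flagged samples
#'
#' Reruns the given contrasts after removing samples carrying a metadata
#' flag (e.g. FTD cases with AD co-pathology) and reports, per contrast,
#' the Spearman correlation and maximum absolute difference of the betas
#' against the full analysis.
#'
#' @param npx an \code{\link{npx_matrix}}.
#' @param meta sample metadata.
#' @param flag name of a logical metadata column; TRUE rows are excluded.
#' @param contrasts list of \code{c(group, reference)} pairs.
#' @param covariates passed to \code{\link{nested_lm_contrast}}.
#' @return data.frame: contrast, n_excluded, beta_spearman, max_abs_diff.
#' @export
sensitivity_exclude <- function(npx, meta, flag, contrasts,
                                covariates = c("age", "sex")) {
  if (!flag %in% names(meta)) stop("flag '", flag, "' not in metadata", call. = FALSE)
  excl <- isTRUE_vec(meta[[flag]])
  meta2 <- meta[!excl, , drop = FALSE]
  out <- NULL
  for (ct in contrasts) {
    glab2 <- group_label(meta2)[subset_analysis(meta2)]
    if (!all(ct %in% glab2))
      stop("exclusion empties group '", setdiff(ct, glab2)[1], "'", call. = FALSE)
    full <- nested_lm_contrast(npx, meta, ct[1], ct[2], covariates)
    red <- nested_lm_contrast(npx[meta2$sample_id, ], meta2, ct[1], ct[2],
                              covariates)
    ok <- !is.na(full$beta) & !is.na(red$beta)
    out <- rbind(out, data.frame(
      contrast = paste(ct[1], "vs", ct[2]),
      n_excluded = sum(excl),
      beta_spearman = stats::cor(full$beta[ok], red$beta[ok], method = "spearman"),
      max_abs_diff = max(abs(full$beta[ok] - red$beta[ok])),
      stringsAsFactors = FALSE))
  }
  out
}

#' Hypergeometric term enrichment against a fixed background
#'
#' For each annotation term: \code{k} = hits annotated with the term,
#' upper-tail hypergeometric p for drawing at least \code{k} annotated
#' proteins in \code{|hits|} draws from the background, and enrichment
#' factor = observed/expected = \code{(k/|hits|) / (K/|background|)}.
#' Terms are retained only when they pass all three default thresholds
#' (p < 0.01, count >= 3, enrichment factor > 1.5); the full table is
#' returned with a \code{retained} flag. Term clustering by membership
#' similarity is deliberately not performed.
#'
#' @param hits character vector of hit protein IDs (subset of background).
#' @param background character vector of all tested protein IDs.
#' @param annotations data.frame: protein_id, term_id, term_name
#'   (term_name optional); rows outside the background are ignored.
#' @param min_count,p_max,min_enrichment retention thresholds.
#' @return data.frame: term_id, term_name, count, expected, enrichment,
#'   p, retained; sorted by p.
#' @export
enrich_terms <- function(hits, background, annotations,
                         min_count = 3, p_max = 0.01, min_enrichment = 1.5) {
  hits <- unique(hits); background <- unique(background)
  extra <- setdiff(hits, background)
  if (length(extra))
    stop("hit(s) not in background: ", paste(utils::head(extra, 5), collapse = ", "),
         call. = FALSE)
  if (!all(c("protein_id", "term_id") %in% names(annotations)))
    stop("annotations need columns protein_id and term_id", call. = FALSE)
  ann <- annotations[annotations$protein_id %in% background, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("protein_id", "term_id")]), , drop = FALSE]
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  N <- length(background); n <- length(hits)
  out <- NULL
  for (tid in unique(ann$term_id)) {
    members <- ann$protein_id[ann$term_id == tid]
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expected <- n * K / N
    enr <- if (expected > 0) k / expected else NA_real_
    out <- rbind(out, data.frame(
      term_id = tid, term_name = ann$term_name[match(tid, ann$term_id)],
      count = k, expected = expected, enrichment = enr, p = p,
      retained = (k >= min_count && p < p_max && enr > min_enrichment),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(term_id = character(0), term_name = character(0),
                      count = integer(0), expected = numeric(0),
                      enrichment = numeric(0), p = numeric(0),
                      retained = logical(0)))
  out[order(out$p), , drop = FALSE]
}
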