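# Classification-signature construction: elastic-net penalized logistic
# regression over a (mixing parameter x marker cap) grid, balanced
# cross-validation on model likelihood, fold-based stability selection,
# ridge refit of the final marker set, and repeated-CV performance.

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive scores above
#' a random negative, with ties counting one half. Computed from average
#' ranks, which is algebraically identical to the pairwise comparison.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or two-level).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(scores) & !is.na(y)
  y <- y[ok]; scores <- scores[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("labels must have exactly two levels", call. = FALSE)
  as.integer(as.character(labels) == lv[2])
}

#' Stratified (balanced) fold assignment
#'
#' Each class is shuffled with the given seed and dealt round-robin into
#' \code{k} folds, so per-fold class counts differ from exact
#' proportionality by less than one sample.
#'
#' @param labels binary label vector.
#' @param k number of folds; must not exceed the minority class count.
#' @param seed integer seed.
#' @return integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(labels, k, seed) {
  y <- as_binary(labels)
  if (min(table(y)) < k)
    stop("k = ", k, " exceeds the minority class count (", min(table(y)), ")",
         call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid specification for signature selection
#'
#' @param alphas elastic-net mixing values in (0, 1] (1 = lasso).
#' @param max_markers marker-cardinality caps, each at most 21.
#' @param n_folds folds for the balanced selection CV.
#' @param lambda_path_length points on the decreasing lambda path.
#' @param stability_threshold minimum fold-based selection proportion for
#'   a marker to enter the final signature.
#' @param ridge_penalty L2 penalty of the final refit.
#' @param seed integer seed for fold assignment.
#' @return a validated \code{grid_spec} list.
#' @export
grid_spec <- function(alphas = seq(0.1, 1, by = 0.1),
                      max_markers = c(5, 10, 15, 21),
                      n_folds = 10, lambda_path_length = 50,
                      stability_threshold = 0.9, ridge_penalty = 0.1,
                      seed) {
  if (missing(seed)) stop_config("seed", "is mandatory")
  if (any(alphas <= 0 | alphas > 1)) stop_config("alphas", "must lie in (0, 1]")
  if (any(max_markers < 1)) stop_config("max_markers", "must be positive")
  if (any(max_markers > 21)) stop_config("max_markers", "must not exceed 21")
  if (n_folds < 2) stop_config("n_folds", "must be >= 2")
  if (stability_threshold < 0 || stability_threshold > 1)
    stop_config("stability_threshold", "must be in [0, 1]")
  structure(list(alphas = alphas, max_markers = sort(unique(max_markers)),
                 n_folds = n_folds, lambda_path_length = lambda_path_length,
                 stability_threshold = stability_threshold,
                 ridge_penalty = ridge_penalty, seed = as.integer(seed)),
            class = "grid_spec")
}

#' Elastic-net logistic coefficient path
#'
#' Thin wrapper around \code{glmnet}: logistic loss plus
#' \code{lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)} over a
#' decreasing lambda path starting at the smallest lambda with all
#' penalized coefficients zero. Marker columns are expected standardized
#' (mean 0, sd 1 on the training data); covariate columns and the
#' intercept are never penalized.
#'
#' @param X numeric matrix (markers first, then covariates).
#' @param y binary labels.
#' @param alpha mixing parameter in (0, 1].
#' @param covariate_cols column names (or indices) of unpenalized columns.
#' @param lambda optional fixed lambda path (reused across CV folds).
#' @param nlambda path length when \code{lambda} is NULL.
#' @return the fitted \code{glmnet} object.
#' @export
fit_enet_path <- function(X, y, alpha, covariate_cols = NULL,
                          lambda = NULL, nlambda = 50) {
  y <- as_binary(y)
  if (length(unique(y)) != 2) stop("y must contain both classes", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("degenerate (constant) feature column(s): ",
         paste(utils::head(colnames(X)[sds == 0], 3), collapse = ", "),
         call. = FALSE)
  pf <- rep(1, ncol(X))
  if (!is.null(covariate_cols)) {
    idx <- if (is.character(covariate_cols)) match(covariate_cols, colnames(X))
           else covariate_cols
    pf[idx] <- 0
  }
  glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                 penalty.factor = pf, standardize = FALSE,
                 lambda = lambda, nlambda = nlambda,
                 lambda.min.ratio = 1e-3)
}

# standardize marker columns on training rows; returns scaled matrices +
# the (mean, sd) used, so nothing leaks from test rows
std_train_test <- function(X, train, markers) {
  mu <- colMeans(X[train, markers, drop = FALSE])
  sd <- apply(X[train, markers, drop = FALSE], 2, stats::sd)
  sd[sd == 0] <- 1  # constant-in-fold marker carries no information
  Xs <- X
  Xs[, markers] <- sweep(sweep(X[, markers, drop = FALSE], 2, mu, `-`),
                         2, sd, `/`)
  list(X = Xs, mean = mu, sd = sd)
}

#' Select a classification signature over the (alpha, cap) grid
#'
#' For every grid cell (elastic-net mixing value alpha, marker cap): the
#' lambda path is fit on the full data, balanced \code{n_folds}-fold
#' cross-validation scores each lambda by held-out model log-likelihood,
#' and the cell's lambda is the likelihood maximizer among path points
#' whose full-data model uses at least 1 and at most cap markers. Each
#' cell is scored by the AUC of its pooled out-of-fold predictions. The
#' winning cell has the highest AUC, ties broken by fewer markers, then
#' larger alpha. Fold-based selection proportions (the fraction of fold
#' refits in which each marker is nonzero at the winning lambda) are
#' computed and markers at or above \code{stability_threshold} are
#' retained, then refit with \code{\link{ridge_refit}} at the configured
#' penalty together with the covariates.
#'
#' @param X numeric matrix of raw (unstandardized) marker columns, named.
#' @param y binary labels (1 = positive class).
#' @param grid a \code{\link{grid_spec}}.
#' @param covariates optional data.frame/matrix of unpenalized covariate
#'   columns (e.g. age, sex), included in every model.
#' @param trained_on cohort tag stored in the panel.
#' @return list: \code{panel} (a \code{panel_model}), \code{grid_table}
#'   (per-cell alpha, cap, lambda, cv_auc, n_markers), \code{selection}
#'   (per-marker fold selection proportions of the winning cell),
#'   \code{winner}.
#' @export
select_signature <- function(X, y, grid, covariates = NULL,
                             trained_on = "discovery") {
  stopifnot(inherits(grid, "grid_spec"))
  y <- as_binary(y)
  if (nrow(X) < 2 * grid$n_folds)
    stop("need at least 2 samples per fold", call. = FALSE)
  markers <- colnames(X)
  if (is.null(markers)) stop("X must have column names", call. = FALSE)
  cov_mat <- NULL
  if (!is.null(covariates)) {
    cov_mat <- as.matrix(as.data.frame(covariates))
    storage.mode(cov_mat) <- "double"
  }
  Xall <- if (is.null(cov_mat)) X else cbind(X, cov_mat)
  cov_cols <- if (is.null(cov_mat)) NULL else colnames(cov_mat)
  folds <- stratified_folds(y, grid$n_folds, grid$seed)

  grid_table <- NULL
  best <- NULL
  for (alpha in grid$alphas) {
    stf <- std_train_test(Xall, seq_len(nrow(Xall)), markers)
    full_fit <- fit_enet_path(stf$X, y, alpha, cov_cols,
                              nlambda = grid$lambda_path_length)
    lam <- full_fit$lambda
    bmat <- as.matrix(full_fit$beta[markers, , drop = FALSE])
    nz_full <- colSums(bmat != 0)

    # fold fits share the full-data lambda path
    ll <- rep(0, length(lam))
    oof <- matrix(NA_real_, nrow(Xall), length(lam))
    fold_nonzero <- array(FALSE, c(grid$n_folds, length(markers), length(lam)))
    for (f in seq_len(grid$n_folds)) {
      tr <- folds != f
      stf_f <- std_train_test(Xall, which(tr), markers)
      fit_f <- fit_enet_path(stf_f$X[tr, , drop = FALSE], y[tr], alpha,
                             cov_cols, lambda = lam)
      eta <- stats::predict(fit_f, stf_f$X[!tr, , drop = FALSE], s = lam)
      kf <- min(ncol(eta), length(lam))
      pr <- plogis_clip(eta[, seq_len(kf), drop = FALSE])
      ll[seq_len(kf)] <- ll[seq_len(kf)] +
        colSums(log(pr) * y[!tr] + log(1 - pr) * (1 - y[!tr]))
      if (kf < length(lam)) ll[(kf + 1):length(lam)] <- -Inf
      oof[!tr, seq_len(kf)] <- eta[, seq_len(kf), drop = FALSE]
      bf <- as.matrix(fit_f$beta[markers, , drop = FALSE])
      fold_nonzero[f, , seq_len(min(ncol(bf), length(lam)))] <-
        bf[, seq_len(min(ncol(bf), length(lam))), drop = FALSE] != 0
    }

    for (cap in grid$max_markers) {
      adm <- which(nz_full >= 1 & nz_full <= cap & is.finite(ll) &
                     !is.na(colSums(oof)))
      if (!length(adm)) next
      li <- adm[which.max(ll[adm])]
      cell_auc <- auc(oof[, li], y)
      cell_markers <- markers[bmat[, li] != 0]
      props <- colMeans(matrix(fold_nonzero[, , li], grid$n_folds,
                               length(markers)))
      grid_table <- rbind(grid_table, data.frame(
        alpha = alpha, cap = cap, lambda = lam[li], cv_auc = cell_auc,
        n_markers = length(cell_markers), stringsAsFactors = FALSE))
      cand <- list(alpha = alpha, cap = cap, lambda = lam[li],
                   cv_auc = cell_auc, markers = cell_markers,
                   selection_prop = stats::setNames(as.numeric(props), markers))
      if (is.null(best) ||
          cell_auc > best$cv_auc + 1e-12 ||
          (abs(cell_auc - best$cv_auc) <= 1e-12 &&
           (length(cell_markers) < length(best$markers) ||
            (length(cell_markers) == length(best$markers) && alpha > best$alpha))))
        best <- cand
    }
  }
  if (is.null(best))
    stop("no grid cell produced a non-empty marker set; widen the lambda path ",
         "or the alpha/cap grid", call. = FALSE)

  sel_tab <- data.frame(protein_id = names(best$selection_prop),
                        selection_proportion = as.numeric(best$selection_prop),
                        stringsAsFactors = FALSE)
  retained <- intersect(best$markers,
                        names(best$selection_prop)[best$selection_prop >=
                                                     grid$stability_threshold])
  if (!length(retained))
    stop("stability filter removed every marker (threshold ",
         grid$stability_threshold, "); lower the threshold or widen the grid",
         call. = FALSE)
  panel <- ridge_refit(X[, retained, drop = FALSE], y,
                       covariates = cov_mat, penalty = grid$ridge_penalty,
                       trained_on = trained_on, seed = grid$seed)
  list(panel = panel, grid_table = grid_table, selection = sel_tab,
       winner = best)
}

new_panel_model <- function(markers, coefficients, intercept, covariate_terms,
                            standardization, penalty, trained_on, seed) {
  stopifnot(length(markers) >= 1, all(standardization$sd > 0))
  structure(list(markers = markers,
                 coefficients = stats::setNames(coefficients, markers),
                 intercept = intercept,
                 covariate_terms = covariate_terms,
                 standardization = standardization,
                 penalty = penalty, trained_on = trained_on, seed = seed),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d markers, ridge penalty %.3g, trained on '%s'\n",
              length(x$markers), x$penalty, x$trained_on))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Ridge-refit a fixed marker set by penalized IRLS
#'
#' Minimizes the average logistic negative log-likelihood plus
#' \code{penalty/2 * ||b_markers||^2}, with marker columns standardized
#' internally (training mean/sd stored in the returned panel) and
#' covariates and intercept unpenalized. Newton/IRLS iterations stop when
#' the largest coefficient change falls below \code{tol} (default 1e-8)
#' or after \code{max_iter} iterations, which is an error.
#'
#' @param X raw marker matrix (named columns).
#' @param y binary labels.
#' @param covariates optional covariate matrix/data.frame (unpenalized).
#' @param penalty ridge penalty on standardized marker coefficients.
#' @param max_iter,tol convergence controls.
#' @param trained_on,seed provenance stored in the panel.
#' @return a \code{panel_model}.
#' @export
ridge_refit <- function(X, y, covariates = NULL, penalty = 0.1,
                        max_iter = 100, tol = 1e-8,
                        trained_on = "discovery", seed = NA_integer_) {
  y <- as_binary(y)
  markers <- colnames(X)
  if (is.null(markers)) stop("X must have column names", call. = FALSE)
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  if (any(sd == 0)) stop("constant marker column(s): ",
                         paste(markers[sd == 0], collapse = ", "), call. = FALSE)
  Z <- sweep(sweep(X, 2, mu, `-`), 2, sd, `/`)
  cov_mat <- NULL
  if (!is.null(covariates)) {
    cov_mat <- as.matrix(as.data.frame(covariates))
    storage.mode(cov_mat) <- "double"
  }
  D <- cbind(1, Z, cov_mat)
  pen <- c(0, rep(penalty, ncol(Z)), rep(0, if (is.null(cov_mat)) 0 else ncol(cov_mat)))
  n <- nrow(D)
  beta <- rep(0, ncol(D))
  beta[1] <- stats::qlogis(min(max(mean(y), 0.01), 0.99))
  objective <- function(b) {
    eta <- drop(D %*% b)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      sum(pen * b^2) / 2
  }
  obj <- objective(beta)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    p <- plogis_clip(eta)
    g <- drop(crossprod(D, p - y)) / n + pen * beta
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(D * w, D) / n + diag(pen + 1e-12, ncol(D))
    delta <- solve(H, g)
    # step halving keeps the penalized objective monotone; on separable
    # data with unpenalized covariates the optimum can lie along a flat
    # direction, where a vanishing objective change is the stopping rule
    step <- 1
    repeat {
      cand <- beta - step * delta
      obj_new <- objective(cand)
      if (obj_new <= obj + 1e-14 || step < 1e-10) break
      step <- step / 2
    }
    beta <- cand
    trace <- c(trace, max(abs(step * delta)))
    if (max(abs(step * delta)) < tol ||
        abs(obj - obj_new) < 1e-13 * (abs(obj) + 1e-13)) {
      converged <- TRUE
      obj <- obj_new
    } else {
      obj <- obj_new
    }
    if (converged) {
      beta <- unname(beta)
      coef <- beta[1 + seq_along(markers)]
      cov_terms <- if (is.null(cov_mat)) stats::setNames(list(), character(0))
                   else stats::setNames(as.list(beta[(1 + length(markers)) +
                                                       seq_len(ncol(cov_mat))]),
                                        colnames(cov_mat))
      return(new_panel_model(markers, coef, beta[1], cov_terms,
                             list(mean = stats::setNames(mu, markers),
                                  sd = stats::setNames(sd, markers)),
                             penalty, trained_on, seed))
    }
  }
  stop("ridge IRLS did not converge in ", max_iter,
       " iterations; max |delta| trace tail: ",
       paste(signif(utils::tail(trace, 5), 3), collapse = ", "), call. = FALSE)
}

#' Score samples with a fitted panel
#'
#' Linear predictor: intercept + sum of coefficient times standardized
#' marker value (using the panel's stored training mean/sd) + covariate
#' terms. Higher scores mean higher predicted probability of the positive
#' class; \code{type = "response"} maps through the logistic function.
#'
#' @param object a \code{panel_model}.
#' @param X raw marker matrix containing at least the panel's markers.
#' @param covariates covariate values matching the panel's covariate
#'   terms (required when the panel has any).
#' @param type "link" (default) or "response".
#' @param ... unused.
#' @return numeric scores.
#' @export
predict.panel_model <- function(object, X, covariates = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$markers, colnames(X))
  if (length(miss))
    stop("markers absent from the matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  Z <- sweep(sweep(X[, object$markers, drop = FALSE], 2,
                   object$standardization$mean, `-`),
             2, object$standardization$sd, `/`)
  eta <- object$intercept + drop(Z %*% object$coefficients)
  if (length(object$covariate_terms)) {
    if (is.null(covariates))
      stop("panel has covariate terms; supply 'covariates'", call. = FALSE)
    cv <- as.data.frame(covariates)
    for (nm in names(object$covariate_terms)) {
      if (!nm %in% names(cv)) stop("covariate '", nm, "' missing", call. = FALSE)
      eta <- eta + object$covariate_terms[[nm]] * cv[[nm]]
    }
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' Repeated stratified k-fold cross-validated AUC
#'
#' Per repeat: a fresh stratified split; within each training fold the
#' marker set is re-standardized and ridge-refit (nothing leaks from test
#' folds), held-out samples are scored, and one AUC is computed on the
#' pooled out-of-fold scores; each fold's own held-out AUC is kept as
#' well. The reported mean is the mean of the per-repeat pooled AUCs. The
#' 95 percent interval is the 2.5/97.5 resampling percentile of the
#' fold-level AUCs: pooled per-repeat AUCs vary only through the split
#' and give intervals too narrow to reflect sampling uncertainty, whereas
#' the fold-level resample distribution spans it (see the methods
#' vignette).
#'
#' @param X raw marker matrix (the fixed signature's markers).
#' @param y binary labels.
#' @param covariates optional covariate matrix (unpenalized in refits).
#' @param penalty ridge penalty of the per-fold refits.
#' @param folds folds per repeat (default 5).
#' @param repeats number of repeats (default 1000).
#' @param seed integer seed; repeat r uses substream seed + r.
#' @return a \code{cv_performance}: auc_mean, auc_ci, auc_samples, scheme.
#' @export
repeated_cv_auc <- function(X, y, covariates = NULL, penalty = 0.1,
                            folds = 5, repeats = 1000, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  y <- as_binary(y)
  cov_mat <- if (is.null(covariates)) NULL else {
    cm <- as.matrix(as.data.frame(covariates)); storage.mode(cm) <- "double"; cm
  }
  base <- substream_seed(seed, "repeated_cv")
  pooled <- numeric(repeats)
  fold_aucs <- matrix(NA_real_, repeats, folds)
  for (r in seq_len(repeats)) {
    fld <- stratified_folds(y, folds, (base + r) %% 2147483629L)
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fld != f
      fit <- ridge_refit(X[tr, , drop = FALSE], y[tr],
                         covariates = if (is.null(cov_mat)) NULL
                                      else cov_mat[tr, , drop = FALSE],
                         penalty = penalty)
      oof[!tr] <- predict(fit, X[!tr, , drop = FALSE],
                          covariates = if (is.null(cov_mat)) NULL
                                       else cov_mat[!tr, , drop = FALSE])
      fold_aucs[r, f] <- auc(oof[!tr], y[!tr])
    }
    pooled[r] <- auc(oof, y)
  }
  new_cv_performance(pooled, as.numeric(t(fold_aucs)),
                     sprintf("repeated %d-fold CV x %d, seed %d",
                             folds, repeats, as.integer(seed)))
}

new_cv_performance <- function(auc_samples, fold_auc_samples = auc_samples,
                               scheme = "") {
  ci <- stats::quantile(fold_auc_samples, c(0.025, 0.975), names = FALSE,
                        type = 7)
  structure(list(auc_mean = mean(auc_samples),
                 auc_ci = c(lower = ci[1], upper = ci[2]),
                 auc_samples = auc_samples,
                 fold_auc_samples = fold_auc_samples, scheme = scheme),
            class = "cv_performance")
}

#' @export
print.cv_performance <- function(x, ...) {
  cat(sprintf("<cv_performance> AUC %.3f (95%% CI %.3f-%.3f), %s\n",
              x$auc_mean, x$auc_ci[1], x$auc_ci[2], x$scheme))
  invisible(x)
}
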