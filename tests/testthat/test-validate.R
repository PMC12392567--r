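make_two_cohorts <- function(seed_a = 31, seed_b = 32) {
  args <- list(n_per_group = 60, n_tau = 0, n_tdp = 0, n_proteins = 40,
               category_sizes = c(ftd_unique = 8), effect_size = 1.2,
               noise_sd = 0.6, n_rounds = 1, n_bridging = 0, lod_quantile = 0)
  list(a = simulate_cohort(do.call(simulation_config, c(args, seed = seed_a))),
       b = simulate_cohort(do.call(simulation_config, c(args, seed = seed_b))))
}

train_panel <- function(co, markers = NULL) {
  keep <- co$meta$group %in% c("FTD", "CON")
  m <- co$meta[keep, ]
  X <- co$npx$values[m$sample_id, , drop = FALSE]
  y <- as.integer(m$group == "FTD")
  if (is.null(markers))
    markers <- co$truth$protein_id[co$truth$category == "ftd_unique"]
  list(panel = ridge_refit(X[, markers, drop = FALSE], y,
                           covariates = m[, c("age", "sex")], penalty = 0.1),
       X = X, y = y, meta = m)
}

test_that("frozen-mode scoring of the training cohort reproduces training scores", {
  cos <- make_two_cohorts()
  tr <- train_panel(cos$a)
  rep <- apply_panel(tr$panel, cos$a$npx, cos$a$meta, "FTD", "CON",
                     mode = "frozen", covariates = c("age", "sex"),
                     n_boot = 200, seed = 1)
  direct <- predict(tr$panel, tr$X, covariates = tr$meta[, c("age", "sex")])
  expect_equal(unname(rep$scores), unname(direct), tolerance = 1e-12)
  expect_identical(rep$markers_missing, character(0))
  expect_true(rep$auc_ci["lower"] <= rep$auc && rep$auc <= rep$auc_ci["upper"])
})

test_that("refit mode with all markers equals repeated_cv_auc bit for bit", {
  cos <- make_two_cohorts()
  tr <- train_panel(cos$a)
  rep <- apply_panel(tr$panel, cos$b$npx, cos$b$meta, "FTD", "CON",
                     mode = "refit", covariates = c("age", "sex"),
                     repeats = 20, seed = 99)
  keep <- cos$b$meta$group %in% c("FTD", "CON")
  m <- cos$b$meta[keep, ]
  direct <- repeated_cv_auc(
    cos$b$npx$values[m$sample_id, tr$panel$markers, drop = FALSE],
    as.integer(m$group == "FTD"), covariates = m[, c("age", "sex")],
    penalty = 0.1, repeats = 20, seed = 99)
  expect_identical(rep$performance$auc_samples, direct$auc_samples)
  expect_identical(rep$auc, direct$auc_mean)
})

test_that("an exchangeable validation cohort scores close to training performance", {
  cos <- make_two_cohorts()
  tr <- train_panel(cos$a)
  train_cv <- repeated_cv_auc(tr$X[, tr$panel$markers], tr$y,
                              covariates = tr$meta[, c("age", "sex")],
                              repeats = 20, seed = 3)
  frozen <- apply_panel(tr$panel, cos$b$npx, cos$b$meta, "FTD", "CON",
                        mode = "frozen", covariates = c("age", "sex"),
                        n_boot = 200, seed = 4)
  expect_lt(abs(frozen$auc - train_cv$auc_mean), 0.08)
})

test_that("missing markers are dropped, never imputed, and never help", {
  cos <- make_two_cohorts()
  tr <- train_panel(cos$a)
  full_markers <- tr$panel$markers
  reduced_npx <- cos$b$npx[, setdiff(protein_ids(cos$b$npx), full_markers[1:4])]
  rep <- apply_panel(tr$panel, reduced_npx, cos$b$meta, "FTD", "CON",
                     mode = "frozen", covariates = c("age", "sex"),
                     n_boot = 100, seed = 5)
  expect_identical(sort(rep$markers_missing), sort(full_markers[1:4]))
  expect_setequal(c(rep$markers_used, rep$markers_missing), full_markers)
  full <- apply_panel(tr$panel, cos$b$npx, cos$b$meta, "FTD", "CON",
                      mode = "frozen", covariates = c("age", "sex"),
                      n_boot = 100, seed = 5)
  expect_lte(rep$auc, full$auc + 0.05)

  none_npx <- cos$b$npx[, setdiff(protein_ids(cos$b$npx), full_markers)]
  expect_error(apply_panel(tr$panel, none_npx, cos$b$meta, "FTD", "CON",
                           seed = 1), "no panel marker")
})

test_that("beta concordance matches the rank-correlation oracle", {
  pid <- sprintf("P%02d", 1:18)
  set.seed(33)
  b1 <- rnorm(18)
  b2 <- b1 + rnorm(18, 0, 0.2)
  d1 <- fake_diff(pid, b1, rep(0.01, 18))
  d2 <- fake_diff(pid, b2, rep(0.01, 18))
  res <- beta_concordance(d1, d2)
  expect_equal(res$rho, cor(b1, b2, method = "spearman"), tolerance = 1e-12)
  expect_equal(beta_concordance(d1, d1)$rho, 1)
  d3 <- fake_diff(pid, -b1, rep(0.01, 18))
  expect_equal(beta_concordance(d1, d3)$rho, -1)
  expect_error(beta_concordance(fake_diff(pid[1:2], b1[1:2], c(0.1, 0.1)),
                                fake_diff(pid[1:2], b1[1:2], c(0.1, 0.1))),
               ">= 3")
})

test_that("single-marker ROC handles perfect markers, nulls, and ratios", {
  y <- rep(0:1, each = 20)
  perfect <- single_marker_roc(y + 0, y, n_boot = 100, seed = 1)
  expect_equal(perfect$auc, 1)
  expect_equal(unname(perfect$ci), c(1, 1))

  set.seed(34)
  null <- single_marker_roc(rnorm(400), rep(0:1, 200), n_boot = 100, seed = 2)
  expect_lt(abs(null$auc - 0.5), 0.08)

  for (i in 1:5) {
    num <- runif(30, 1, 5); den <- runif(30, 1, 5)
    yy <- rep(0:1, 15)
    r1 <- single_marker_roc(num, yy, denominator = den, n_boot = 50, seed = 3)
    r2 <- single_marker_roc(num / den, yy, n_boot = 50, seed = 3)
    expect_identical(r1$auc, r2$auc)
  }
})
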