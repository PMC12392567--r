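test_that("AUC equals the brute-force pairwise oracle", {
  expect_equal(auc(c(0.1, 0.2, 0.9), c(0, 0, 1)), 1)
  expect_equal(auc(rep(2, 10), rep(0:1, 5)), 0.5)
  set.seed(20)
  for (i in 1:20) {
    s <- sample(1:8, 20, replace = TRUE)  # heavy ties
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-14)
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("stratified folds balance both classes to within one sample", {
  y <- rep(0:1, each = 50)
  f <- stratified_folds(y, 10, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab == 5))

  y2 <- rep(0:1, c(196, 189))
  f2 <- stratified_folds(y2, 10, seed = 2)
  tab2 <- table(f2, y2)
  expect_true(all(tab2[, "1"] %in% 18:19))
  expect_true(all(tab2[, "0"] %in% 19:20))

  expect_identical(stratified_folds(y2, 10, seed = 3),
                   stratified_folds(y2, 10, seed = 3))
  f4 <- stratified_folds(y2, 10, seed = 4)
  expect_false(identical(f2, f4))
  expect_identical(unname(table(f4, y2)[, "1"]), unname(tab2[, "1"]))
  expect_error(stratified_folds(rep(0:1, c(5, 95)), 10, seed = 1), "minority")
})

test_that("the elastic-net path starts empty and admits the strongest feature first", {
  set.seed(22)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("M", 1:10)))
  y <- rbinom(n, 1, plogis(3 * X[, 4]))
  Xs <- scale(X)
  fit <- fit_enet_path(Xs, y, alpha = 1)
  b <- as.matrix(fit$beta)
  expect_true(all(b[, 1] == 0))
  expect_equal(unname(drop(fit$a0[1])), qlogis(mean(y)), tolerance = 1e-6)
  first <- which(colSums(b != 0) > 0)[1]
  expect_identical(rownames(b)[b[, first] != 0], "M4")
  expect_error(fit_enet_path(cbind(Xs, K = 0), y, 0.5), "constant")
})

test_that("the near-ridge end of the elastic net matches the IRLS ridge fit", {
  set.seed(23)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("M", 1:4)))
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  lam <- 0.1
  Z <- scale(X)
  enet <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                         lambda = c(10, 1, lam), standardize = FALSE,
                         thresh = 1e-14)
  ridge <- ridge_refit(X, y, penalty = lam)
  # both coefficient vectors are on the same standardized scale
  expect_equal(unname(as.matrix(enet$beta)[, 3]),
               unname(ridge$coefficients), tolerance = 1e-5)
})

test_that("ridge refit matches a generic convex-optimizer oracle", {
  set.seed(24)
  for (i in 1:5) {
    n <- 60
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("M", 1:3)))
    y <- rbinom(n, 1, plogis(X[, 1]))
    if (length(unique(y)) < 2) next
    fit <- ridge_refit(X, y, penalty = 0.1)
    Z <- sweep(sweep(X, 2, fit$standardization$mean), 2, fit$standardization$sd, `/`)
    obj <- function(b) {
      eta <- b[1] + Z %*% b[-1]
      mean(log(1 + exp(eta)) - y * eta) + 0.05 * sum(b[-1]^2)
    }
    opt <- optim(rep(0, 4), obj, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 2000))
    expect_equal(unname(c(fit$intercept, fit$coefficients)), opt$par,
                 tolerance = 1e-6)
  }
})

test_that("extreme ridge penalties shrink markers to zero and keep the base rate", {
  set.seed(25)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("A", "B")))
  y <- rep(0:1, c(30, 70))
  fit <- ridge_refit(X, y, penalty = 1e6)
  expect_lt(max(abs(fit$coefficients)), 1e-4)
  expect_equal(fit$intercept, qlogis(0.7), tolerance = 1e-3)

  # separable toy data stays finite under the default penalty
  Xs <- cbind(S1 = c(rnorm(20, -3), rnorm(20, 3)), S2 = rnorm(40))
  ys <- rep(0:1, each = 20)
  sep <- ridge_refit(Xs, ys, penalty = 0.1)
  expect_true(all(is.finite(sep$coefficients)))
})

test_that("panel predictions are monotone in each marker", {
  set.seed(26)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  y <- rbinom(100, 1, plogis(X[, 1] - X[, 2]))
  fit <- ridge_refit(X, y, penalty = 0.1)
  x0 <- X[1, , drop = FALSE]
  for (m in colnames(X)) {
    x1 <- x0; x1[, m] <- x1[, m] + 1
    d <- predict(fit, x1) - predict(fit, x0)
    expect_equal(unname(sign(d)), sign(unname(fit$coefficients[m])))
  }
})

test_that("a planted separator is selected with fold proportion 1 and caps hold", {
  set.seed(27)
  n <- 120
  X <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, sprintf("N%02d", 1:40)))
  y <- rep(0:1, each = n / 2)
  X[, 1] <- ifelse(y == 1, rnorm(n, 3), rnorm(n, -3))
  colnames(X)[1] <- "PLANTED"
  g <- grid_spec(alphas = c(0.5, 1), max_markers = c(5, 21), n_folds = 10,
                 seed = 5)
  sel <- select_signature(X, y, g)
  expect_true("PLANTED" %in% sel$panel$markers)
  expect_equal(sel$selection$selection_proportion[
    sel$selection$protein_id == "PLANTED"], 1)
  expect_true(all(sel$grid_table$n_markers <= sel$grid_table$cap))
  expect_true(all(sel$grid_table$cap <= 21))
  expect_error(grid_spec(max_markers = 30, seed = 1), "21")
})

test_that("grid selection is deterministic under a fixed seed", {
  set.seed(28)
  n <- 80
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, sprintf("M%02d", 1:15)))
  y <- rbinom(n, 1, plogis(1.5 * X[, 2] - X[, 7]))
  g <- grid_spec(alphas = c(0.5, 1), max_markers = c(5, 10), n_folds = 5,
                 stability_threshold = 0.5, seed = 9)
  s1 <- select_signature(X, y, g)
  s2 <- select_signature(X, y, g)
  expect_identical(s1$panel$coefficients, s2$panel$coefficients)
  expect_identical(s1$grid_table, s2$grid_table)
})

test_that("repeated CV is seed-deterministic and honest under permutation", {
  set.seed(29)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("M", 1:5)))
  X[, 1] <- X[, 1] + rep(c(0, 1.5), each = n / 2)
  y <- rep(0:1, each = n / 2)
  p1 <- repeated_cv_auc(X, y, repeats = 20, seed = 6)
  p2 <- repeated_cv_auc(X, y, repeats = 20, seed = 6)
  expect_identical(p1$auc_samples, p2$auc_samples)
  expect_true(p1$auc_ci["lower"] <= p1$auc_mean &&
                p1$auc_mean <= p1$auc_ci["upper"])
  expect_gt(p1$auc_mean, 0.7)

  # permutation canary: shuffled labels must score at chance
  yp <- sample(y)
  pc <- repeated_cv_auc(X, yp, repeats = 20, seed = 7)
  expect_lt(abs(pc$auc_mean - 0.5), 0.1)
})

test_that("informative markers get higher selection proportions than noise", {
  set.seed(30)
  diffs <- replicate(15, {
    n <- 80
    X <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(NULL, sprintf("M%02d", 1:12)))
    y <- rep(0:1, each = n / 2)
    X[, 1:2] <- X[, 1:2] + outer(y, c(1.2, 1.2))
    g <- grid_spec(alphas = 1, max_markers = 10, n_folds = 5,
                   stability_threshold = 0, seed = 11)
    sel <- select_signature(X, y, g)
    pr <- sel$selection$selection_proportion
    mean(pr[1:2]) - mean(pr[-(1:2)])
  })
  # proportions are multiples of 1/5, so ties are expected: normal approx
  expect_lt(wilcox.test(diffs, alternative = "greater", exact = FALSE)$p.value,
            0.01)
  expect_gt(median(diffs), 0)
})
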