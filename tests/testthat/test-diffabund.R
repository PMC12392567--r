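test_that("with no covariates the nested F equals the squared pooled t", {
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- rnorm(n1 + n2)
    v <- matrix(x, ncol = 1, dimnames = list(sprintf("s%02d", seq_along(x)), "P1"))
    meta <- data.frame(sample_id = rownames(v),
                       group = rep(c("FTD", "CON"), c(n1, n2)),
                       stringsAsFactors = FALSE)
    res <- nested_lm_contrast(npx_matrix(v), meta, "FTD", "CON",
                              covariates = character(0))
    tt <- t.test(x[1:n1], x[-(1:n1)], var.equal = TRUE)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    expect_equal(res$beta, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("age confounding is adjusted away and beta recovers the planted shift", {
  co <- simulate_cohort(simulation_config(
    n_per_group = 100, n_tau = 0, n_tdp = 0, n_proteins = 30,
    category_sizes = c(ftd_unique = 10), effect_size = 1, noise_sd = 0.5,
    age_effect = 0.05, age_group_shift = 8, n_rounds = 1, n_bridging = 0,
    lod_quantile = 0, seed = 13))
  res <- nested_lm_contrast(co$npx, co$meta, "FTD", "CON")
  planted <- co$truth$category == "ftd_unique"
  expect_true(all(abs(abs(res$beta[planted]) - 1) <= 2 * res$se[planted]))
  # unadjusted means are biased by the age effect; the model must not be
  raw <- colMeans(co$npx$values[co$meta$group == "FTD", planted]) -
    colMeans(co$npx$values[co$meta$group == "CON", planted])
  expect_gt(mean(abs(abs(raw) - 1)), mean(abs(abs(res$beta[planted]) - 1)))
})

test_that("null proteins produce uniform p-values at the nominal rate", {
  co <- simulate_cohort(simulation_config(
    n_per_group = 40, n_tau = 0, n_tdp = 0, n_proteins = 500,
    category_sizes = c(), n_rounds = 1, n_bridging = 0,
    lod_quantile = 0, seed = 14))
  res <- nested_lm_contrast(co$npx, co$meta, "FTD", "CON")
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
})

test_that("missing values drop samples per protein and n_used records it", {
  co <- toy_cohort(n_per_group = 10, n_proteins = 3, seed = 15)
  v <- co$npx$values
  v[1:4, 2] <- NA
  res <- nested_lm_contrast(npx_matrix(v, co$npx$lod), co$meta, "FTD", "CON")
  expect_equal(res$n_used[1], 20L)
  expect_lt(res$n_used[2], 20L)
  expect_error(nested_lm_contrast(co$npx, co$meta, "DLB", "CON"), "DLB")
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_adjust(1), 1)
  set.seed(16)
  for (i in 1:50) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("overlap categorization handles each canonical pattern", {
  pid <- letters[1:7]
  mk <- function(qf, qa, qc, bf = 0.3, bc = 0.3)
    list(fc = fake_diff(pid, rep(bf, 7), rep(qf, 7)),
         fa = fake_diff(pid, rep(0.2, 7), rep(qa, 7)),
         ac = fake_diff(pid, rep(bc, 7), rep(qc, 7)))
  u <- mk(0.01, 0.01, 0.50)
  expect_true(all(categorize_overlap(u$fc, u$fa, u$ac)$category == "ftd_unique"))
  s <- mk(0.01, 0.90, 0.01)
  expect_true(all(categorize_overlap(s$fc, s$fa, s$ac)$category == "shared_dementia"))
  o <- mk(0.01, 0.01, 0.01, bf = 0.3, bc = -0.4)
  expect_true(all(categorize_overlap(o$fc, o$fa, o$ac)$category == "opposite_direction"))
  d <- mk(0.01, 0.01, 0.01, bf = 0.3, bc = 0.4)
  expect_true(all(categorize_overlap(d$fc, d$fa, d$ac)$category == "ad_dominant_shared"))
  a <- mk(0.50, 0.50, 0.01)
  expect_true(all(categorize_overlap(a$fc, a$fa, a$ac)$category == "ad_only"))
  n <- mk(0.50, 0.50, 0.50)
  expect_true(all(categorize_overlap(n$fc, n$fa, n$ac)$category == "none"))
  # partition: every protein gets exactly one category
  expect_equal(nrow(categorize_overlap(u$fc, u$fa, u$ac)), 7)
  bad <- fake_diff(rev(pid), rep(0.3, 7), rep(0.01, 7))
  expect_error(categorize_overlap(u$fc, u$fa, bad), "same proteins")
})

test_that("sensitivity exclusion reports concordance with the full analysis", {
  co <- simulate_cohort(simulation_config(
    n_per_group = 60, n_tau = 0, n_tdp = 0, n_proteins = 50,
    category_sizes = c(ftd_unique = 20), effect_size = 1.2, noise_sd = 0.5,
    n_rounds = 1, n_bridging = 0, lod_quantile = 0, seed = 17))
  meta <- co$meta
  meta$flag_none <- FALSE
  rep0 <- sensitivity_exclude(co$npx, meta, "flag_none",
                              list(c("FTD", "CON")))
  expect_equal(rep0$beta_spearman, 1)
  expect_equal(rep0$max_abs_diff, 0)
  set.seed(18)
  meta$flag_some <- meta$group == "FTD" & runif(nrow(meta)) < 0.10
  rep1 <- sensitivity_exclude(co$npx, meta, "flag_some",
                              list(c("FTD", "CON")))
  expect_gt(rep1$beta_spearman, 0.95)
  meta$flag_all_ftd <- meta$group == "FTD"
  expect_error(sensitivity_exclude(co$npx, meta, "flag_all_ftd",
                                   list(c("FTD", "CON"))), "empties")
})

test_that("hypergeometric enrichment matches the exact tail and thresholds", {
  bg <- sprintf("P%03d", 1:100)
  ann <- data.frame(protein_id = bg[1:10], term_id = "T1",
                    term_name = "pathway one", stringsAsFactors = FALSE)
  res <- enrich_terms(bg[1:10], bg, ann)
  expect_equal(res$enrichment, 10)
  expect_equal(res$p, oracle_hyper_tail(10, 10, 100, 10), tolerance = 1e-12)
  expect_true(res$retained)

  # a count of 2 is filtered regardless of p
  ann2 <- data.frame(protein_id = bg[1:2], term_id = "T2")
  res2 <- enrich_terms(bg[1:2], bg, ann2)
  expect_false(res2$retained)
  expect_error(enrich_terms(c("XX"), bg, ann), "background")
})

test_that("random hit draws give mean enrichment factor 1", {
  bg <- sprintf("P%03d", 1:100)
  ann <- data.frame(protein_id = bg[1:20], term_id = "T1")
  set.seed(19)
  enr <- replicate(200, enrich_terms(sample(bg, 25), bg, ann)$enrichment)
  expect_lt(abs(mean(enr) - 1), 0.1)
})
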