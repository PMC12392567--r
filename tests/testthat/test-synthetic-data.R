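test_that("configuration errors name the violated field", {
  expect_error(simulation_config(n_proteins = 10,
                                 category_sizes = c(ftd_unique = 20), seed = 1),
               "category_sizes")
  expect_error(simulation_config(noise_sd = 0, seed = 1), "noise_sd")
  expect_error(simulation_config(lod_quantile = 1, seed = 1), "lod_quantile")
  expect_error(simulation_config(n_per_group = 50, n_tau = 40, n_tdp = 20,
                                 seed = 1), "n_tau")
  expect_error(simulation_config(), "seed")
})

test_that("identical config and seed give a bit-identical cohort", {
  cf <- simulation_config(n_per_group = 20, n_tau = 5, n_tdp = 5,
                          n_proteins = 30,
                          category_sizes = c(ftd_unique = 4, tau_specific = 2),
                          seed = 42)
  a <- simulate_cohort(cf)
  b <- simulate_cohort(cf)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  d <- simulate_cohort(simulation_config(n_per_group = 20, n_tau = 5,
                                         n_tdp = 5, n_proteins = 30,
                                         category_sizes = c(ftd_unique = 4),
                                         seed = 43))
  expect_false(identical(a$npx$values, d$npx$values))
})

test_that("npx rows and metadata align and truth is a partition", {
  co <- toy_cohort(n_per_group = 8, n_proteins = 6, seed = 3)
  expect_identical(rownames(co$npx$values), co$meta$sample_id)
  expect_equal(nrow(co$truth), 6)
  expect_true(all(co$truth$category %in%
                    c("ftd_unique", "shared_dementia", "ad_dominant",
                      "opposite_direction", "tau_specific", "tdp_specific",
                      "null")))
})

test_that("a planted FTD-unique effect is recovered in the group means", {
  co <- simulate_cohort(simulation_config(
    n_per_group = 100, n_tau = 0, n_tdp = 0, n_proteins = 20,
    category_sizes = c(ftd_unique = 5), effect_size = 1, noise_sd = 0.5,
    age_effect = 0, sex_effect = 0, n_rounds = 1, n_bridging = 0,
    lod_quantile = 0, seed = 7))
  v <- co$npx$values
  g <- co$meta$group
  planted <- which(co$truth$category == "ftd_unique")
  for (p in planted) {
    diff <- mean(v[g == "FTD", p]) - mean(v[g == "CON", p])
    expect_equal(abs(diff), 1, tolerance = 0.15)
    expect_equal(sign(diff), sign(co$truth$effect_ftd[p]))
  }
})

test_that("with no planted effects per-protein t-tests reject at the nominal rate", {
  # equivalent to many seeds x one protein: many independent null proteins
  co <- simulate_cohort(simulation_config(
    n_per_group = 50, n_tau = 0, n_tdp = 0, n_proteins = 400,
    category_sizes = c(), age_effect = 0, sex_effect = 0,
    n_rounds = 1, n_bridging = 0, lod_quantile = 0, seed = 11))
  g <- co$meta$group
  pvals <- apply(co$npx$values, 2, function(x)
    stats::t.test(x[g == "FTD"], x[g == "CON"], var.equal = TRUE)$p.value)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("bridging subjects appear once per round with unique row IDs", {
  co <- simulate_cohort(simulation_config(
    n_per_group = 20, n_tau = 0, n_tdp = 0, n_proteins = 10,
    category_sizes = c(), n_rounds = 2, n_bridging = 16, seed = 5))
  br <- co$meta[co$meta$is_bridging, ]
  in_both <- intersect(br$subject_id[br$round == 1], br$subject_id[br$round == 2])
  expect_length(in_both, 16)
  expect_false(anyDuplicated(co$meta$sample_id) > 0)
})

test_that("the LOD sits at the configured quantile of each protein's marginal", {
  co <- simulate_cohort(simulation_config(
    n_per_group = 100, n_tau = 0, n_tdp = 0, n_proteins = 25,
    category_sizes = c(), lod_quantile = 0.1, n_rounds = 1,
    n_bridging = 0, seed = 9))
  frac_below <- colMeans(sweep(co$npx$values, 2, co$npx$lod, `<`))
  expect_true(all(abs(frac_below - 0.1) < 0.05))
})

test_that("a planted clinical link reproduces its rank-correlation strength", {
  co <- simulate_cohort(simulation_config(
    n_per_group = 100, n_tau = 0, n_tdp = 0, n_proteins = 10,
    category_sizes = c(),
    clinical_link = list(list(protein = 1, score = "mmse", rho = 0.4)),
    n_rounds = 1, n_bridging = 0, seed = 21))
  rho <- cor(co$npx$values[, 1], co$meta$mmse, method = "spearman")
  expect_lt(abs(rho - 0.4), 0.12)
})

test_that("paired-measurement simulation obeys its line", {
  pm <- simulate_paired_measurements(10, slope = 1, intercept = 0,
                                     noise_sd = 0, seed = 1)
  expect_equal(pm$y, pm$x)
  pm2 <- simulate_paired_measurements(10, slope = 2, intercept = 5,
                                      noise_sd = 0, seed = 2)
  fit <- passing_bablok(pm2)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 5)
  expect_error(simulate_paired_measurements(2, 1, seed = 1), ">= 3")
})

test_that("noisy paired fits recover the slope over many seeds", {
  slopes <- vapply(1:100, function(s)
    passing_bablok(simulate_paired_measurements(200, 0.8, 10, noise_sd = 1,
                                                seed = s))$slope,
    numeric(1))
  expect_lt(abs(median(slopes) - 0.8), 0.05)
})
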