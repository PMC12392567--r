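#' Configuration for the synthetic CSF-cohort generator
#'
#' Defines a three-group (CON/FTD/AD) targeted-proteomics cohort with the
#' statistical structure the downstream analysis assumes: planted log2
#' group effects in defined overlap categories, FTLD-Tau/FTLD-TDP
#' subgroup effects, age and sex confounding (patients older than
#' controls, unequal sex ratios), two measurement rounds with additive
#' per-protein batch offsets estimated from bridging aliquots, and
#' left-censoring limits (LOD) stored per protein. Defaults mirror the
#' discovery-cohort structure: 196/189/232 samples, 642 proteins of which
#' 36 are FTD-unique, 19 shared-dementia, 21 AD-dominant, 7 opposite
#' direction, 3 FTLD-Tau-specific and 2 FTLD-TDP-specific, 87/67
#' Tau/TDP subgroup labels, two rounds bridged by 16 samples.
#'
#' @param n_per_group named counts for CON, FTD, AD (scalar recycled).
#' @param n_tau,n_tdp FTD samples labelled FTLD-Tau / FTLD-TDP
#'   (\code{n_tau + n_tdp <= n_FTD}).
#' @param n_proteins total protein count.
#' @param category_sizes named counts of planted proteins per category:
#'   \code{ftd_unique, shared_dementia, ad_dominant, opposite_direction,
#'   tau_specific, tdp_specific}; the remainder are null.
#' @param effect_size planted group-mean shift in NPX (log2) units. The
#'   AD-dominant category gets \code{0.5 * effect_size} in FTD and the
#'   full effect in AD so all three pairwise contrasts carry signal.
#' @param age_effect,sex_effect covariate coefficients, NPX units per
#'   year and per sex level.
#' @param age_group_shift mean age offset (years) of patient groups over
#'   controls.
#' @param sex_prob named probability of sex == 1 per group.
#' @param noise_sd residual SD in NPX units (> 0).
#' @param n_rounds measurement rounds.
#' @param round_shift_sd SD of the per-protein additive round offsets
#'   (round 1 is the reference and carries none).
#' @param n_bridging bridging subjects re-measured in every round.
#' @param lod_quantile fraction of each protein's simulated marginal set
#'   below its LOD, in [0, 1).
#' @param clinical_link list of \code{list(protein = index or id,
#'   score = "mmse" or "ftld_cdr", rho = signed target Spearman
#'   strength)} links planted via a Gaussian copula.
#' @param seed mandatory integer seed; identical config + seed gives a
#'   bit-identical cohort (Mersenne-Twister, inversion normals).
#'
#' @return a validated \code{simulation_config} list.
#' @export
simulation_config <- function(n_per_group = c(CON = 196, FTD = 189, AD = 232),
                              n_tau = 87, n_tdp = 67,
                              n_proteins = 642,
                              category_sizes = c(ftd_unique = 36,
                                                 shared_dementia = 19,
                                                 ad_dominant = 21,
                                                 opposite_direction = 7,
                                                 tau_specific = 3,
                                                 tdp_specific = 2),
                              effect_size = 0.5,
                              age_effect = 0.02, sex_effect = 0.1,
                              age_group_shift = 7,
                              sex_prob = c(CON = 0.49, FTD = 0.37, AD = 0.41),
                              noise_sd = 1,
                              n_rounds = 2, round_shift_sd = 0.2,
                              n_bridging = 16,
                              lod_quantile = 0.02,
                              clinical_link = list(),
                              seed) {
  if (missing(seed)) stop_config("seed", "is mandatory")
  assert_scalar_number(seed, "seed")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 3L)
  if (is.null(names(n_per_group))) names(n_per_group) <- c("CON", "FTD", "AD")
  n_per_group <- n_per_group[c("CON", "FTD", "AD")]
  if (any(is.na(n_per_group)) || any(n_per_group < 0))
    stop_config("n_per_group", "must give nonnegative counts for CON, FTD, AD")
  if (n_tau < 0 || n_tdp < 0) stop_config("n_tau/n_tdp", "must be >= 0")
  if (n_tau + n_tdp > n_per_group[["FTD"]])
    stop_config("n_tau", "+ n_tdp must be <= the FTD count")
  if (n_proteins < 1) stop_config("n_proteins", "must be >= 1")
  full_sizes <- c(ftd_unique = 0, shared_dementia = 0, ad_dominant = 0,
                  opposite_direction = 0, tau_specific = 0, tdp_specific = 0)
  if (length(category_sizes)) {
    bad <- setdiff(names(category_sizes), names(full_sizes))
    if (length(bad)) stop_config("category_sizes", paste("has unknown category:", bad[1]))
    full_sizes[names(category_sizes)] <- category_sizes
  }
  if (any(full_sizes < 0)) stop_config("category_sizes", "must be >= 0")
  if (sum(full_sizes) > n_proteins)
    stop_config("category_sizes", "sum exceeds n_proteins")
  if (noise_sd <= 0) stop_config("noise_sd", "must be > 0")
  if (lod_quantile < 0 || lod_quantile >= 1)
    stop_config("lod_quantile", "must be in [0, 1)")
  if (n_rounds < 1) stop_config("n_rounds", "must be >= 1")
  if (n_bridging < 0) stop_config("n_bridging", "must be >= 0")
  if (round_shift_sd < 0) stop_config("round_shift_sd", "must be >= 0")
  for (lk in clinical_link) {
    if (!all(c("protein", "score", "rho") %in% names(lk)) ||
        !lk$score %in% c("mmse", "ftld_cdr") || abs(lk$rho) >= 1)
      stop_config("clinical_link",
                  "entries need protein, score in {mmse, ftld_cdr}, |rho| < 1")
  }
  structure(list(
    n_per_group = n_per_group, n_tau = n_tau, n_tdp = n_tdp,
    n_proteins = n_proteins, category_sizes = full_sizes,
    effect_size = effect_size, age_effect = age_effect,
    sex_effect = sex_effect, age_group_shift = age_group_shift,
    sex_prob = sex_prob, noise_sd = noise_sd, n_rounds = n_rounds,
    round_shift_sd = round_shift_sd, n_bridging = n_bridging,
    lod_quantile = lod_quantile, clinical_link = clinical_link,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a cohort with known planted structure
#'
#' Generates NPX values as
#' \code{baseline_p + effect(group, p) + age_effect * age +
#' sex_effect * sex + round_offset(round, p) + noise}, with
#' opposite-direction proteins shifted oppositely in FTD and AD,
#' Tau-/TDP-specific effects applied only within the flagged FTD
#' subgroup, and the per-protein LOD set at the configured quantile of
#' that protein's simulated marginal. Values below LOD are retained (the
#' pipeline filters assays, it never masks values). Bridging subjects are
#' duplicated aliquots: their underlying value is drawn once and
#' re-measured in every round, so only the round offset differs between
#' their measurements. Each measurement row gets a unique \code{sample_id}
#' (bridging re-measurements are suffixed with the round); the underlying
#' subject is in \code{meta$subject_id}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{synthetic_cohort}: list with \code{npx}
#'   (\code{\link{npx_matrix}}), \code{meta} (data.frame), \code{truth}
#'   (protein_id, category, effect_ftd, effect_ad, effect_subtype),
#'   \code{clinical_truth}, and \code{config}.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must come from simulation_config()", call. = FALSE)
  cf <- config
  set.seed(cf$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  groups <- rep(c("CON", "FTD", "AD"), times = cf$n_per_group)
  n_sub <- length(groups)
  subject_id <- sprintf("S%04d", seq_len(n_sub))

  # FTLD subtype labels within FTD
  subtype <- rep("none", n_sub)
  ftd_idx <- which(groups == "FTD")
  if (cf$n_tau > 0) subtype[ftd_idx[seq_len(cf$n_tau)]] <- "FTLD-Tau"
  if (cf$n_tdp > 0) subtype[ftd_idx[cf$n_tau + seq_len(cf$n_tdp)]] <- "FTLD-TDP"

  mutation_status <- rep("none", n_sub)
  n_carrier <- min(length(ftd_idx), round(0.2 * length(ftd_idx)))
  if (n_carrier > 0)
    mutation_status[sample(ftd_idx, n_carrier)] <- "symptomatic_carrier"

  age <- stats::rnorm(n_sub, 60 + ifelse(groups == "CON", 0, cf$age_group_shift), 6)
  age <- pmax(age, 40)
  sex <- stats::rbinom(n_sub, 1, cf$sex_prob[groups])
  ad_copathology <- ifelse(groups == "FTD", stats::rbinom(n_sub, 1, 0.1) == 1, NA)
  ad_copathology[groups != "FTD"] <- NA

  # bridging subjects: extra aliquots spanning the clinical groups,
  # measured once per round
  n_br <- cf$n_bridging
  br_groups <- rep_len(c("CON", "FTD", "AD"), n_br)
  br_subject <- if (n_br) sprintf("BR%02d", seq_len(n_br)) else character(0)
  br_age <- pmax(stats::rnorm(n_br, 60 + ifelse(br_groups == "CON", 0, cf$age_group_shift), 6), 40)
  br_sex <- stats::rbinom(n_br, 1, cf$sex_prob[br_groups])

  # per-protein truth
  pid <- sprintf("P%04d", seq_len(cf$n_proteins))
  sizes <- cf$category_sizes
  category <- rep("null", cf$n_proteins)
  pos <- 0L
  for (cat in names(sizes)) {
    k <- sizes[[cat]]
    if (k > 0) category[pos + seq_len(k)] <- cat
    pos <- pos + k
  }
  sgn <- rep_len(c(1, -1), cf$n_proteins)  # alternate planted direction
  e <- cf$effect_size
  effect_ftd <- ifelse(category %in% c("ftd_unique", "shared_dementia",
                                       "opposite_direction"), sgn * e,
                ifelse(category == "ad_dominant", sgn * 0.5 * e, 0))
  effect_ad <- ifelse(category %in% c("shared_dementia", "ad_dominant"), sgn * e,
               ifelse(category == "opposite_direction", -sgn * e, 0))
  effect_sub <- ifelse(category %in% c("tau_specific", "tdp_specific"), sgn * e, 0)

  baseline <- stats::runif(cf$n_proteins, 2, 10)
  round_offset <- matrix(0, cf$n_rounds, cf$n_proteins)
  if (cf$n_rounds > 1)
    round_offset[-1, ] <- stats::rnorm((cf$n_rounds - 1) * cf$n_proteins,
                                       0, cf$round_shift_sd)

  rnd <- rep_len(seq_len(cf$n_rounds), n_sub)[sample.int(n_sub)]
  plate <- sprintf("PL%02d", 1 + (seq_len(n_sub) - 1) %/% 88)

  group_eff <- function(g, st) {
    # n x p effect matrix for group/subtype vectors
    out <- matrix(0, length(g), cf$n_proteins)
    add <- function(rows, cols, eff) {
      if (any(rows) && any(cols))
        out[rows, cols] <<- out[rows, cols] +
          matrix(eff[cols], sum(rows), sum(cols), byrow = TRUE)
    }
    add(g == "FTD", rep(TRUE, cf$n_proteins), effect_ftd)
    add(g == "AD", rep(TRUE, cf$n_proteins), effect_ad)
    add(st == "FTLD-Tau", category == "tau_specific", effect_sub)
    add(st == "FTLD-TDP", category == "tdp_specific", effect_sub)
    out
  }

  # underlying (round-free) values: subjects ...
  base_mat <- matrix(baseline, n_sub, cf$n_proteins, byrow = TRUE)
  signal <- base_mat + group_eff(groups, subtype) +
    cf$age_effect * age + cf$sex_effect * sex
  noise <- matrix(stats::rnorm(n_sub * cf$n_proteins, 0, cf$noise_sd),
                  n_sub, cf$n_proteins)
  under_sub <- signal + noise
  # ... and bridging aliquots (value drawn once, re-used in every round)
  br_subtype <- rep("none", n_br)
  under_br <- if (n_br) {
    matrix(baseline, n_br, cf$n_proteins, byrow = TRUE) +
      group_eff(br_groups, br_subtype) +
      cf$age_effect * br_age + cf$sex_effect * br_sex +
      matrix(stats::rnorm(n_br * cf$n_proteins, 0, cf$noise_sd), n_br, cf$n_proteins)
  } else matrix(0, 0, cf$n_proteins)

  values <- under_sub + round_offset[rnd, , drop = FALSE]
  rownames(values) <- subject_id

  meta <- data.frame(
    sample_id = subject_id, subject_id = subject_id, group = groups,
    subtype = subtype, mutation_status = mutation_status,
    age = age, sex = sex, mmse = NA_real_, ftld_cdr = NA_real_,
    cdr_rater = NA_character_, plate = plate, round = rnd,
    is_bridging = FALSE, is_qc = FALSE, ad_copathology = ad_copathology,
    stringsAsFactors = FALSE
  )

  if (n_br) {
    for (r in seq_len(cf$n_rounds)) {
      vr <- under_br + matrix(round_offset[r, ], n_br, cf$n_proteins, byrow = TRUE)
      rid <- sprintf("%s_r%d", br_subject, r)
      rownames(vr) <- rid
      values <- rbind(values, vr)
      meta <- rbind(meta, data.frame(
        sample_id = rid, subject_id = br_subject, group = br_groups,
        subtype = "none", mutation_status = "none",
        age = br_age, sex = br_sex, mmse = NA_real_, ftld_cdr = NA_real_,
        cdr_rater = NA_character_, plate = sprintf("PL%02d", r),
        round = r, is_bridging = TRUE, is_qc = FALSE,
        ad_copathology = NA, stringsAsFactors = FALSE
      ))
    }
  }

  # clinical scores: group-shifted latents, optionally copula-linked to a
  # protein so a target Spearman strength is planted
  n_all <- nrow(meta)
  z_mmse <- stats::rnorm(n_all)
  z_cdr <- stats::rnorm(n_all)
  links <- list(mmse = NULL, ftld_cdr = NULL)
  for (lk in cf$clinical_link) {
    p <- if (is.character(lk$protein)) match(lk$protein, pid) else as.integer(lk$protein)
    if (is.na(p) || p < 1 || p > cf$n_proteins)
      stop_config("clinical_link", "references an unknown protein")
    r_lat <- 2 * sin(pi * lk$rho / 6)  # bivariate-normal r hitting target Spearman
    zp <- as.numeric(scale(values[, p]))
    zn <- stats::rnorm(n_all)
    z <- r_lat * zp + sqrt(1 - r_lat^2) * zn
    if (lk$score == "mmse") z_mmse <- z else z_cdr <- z
    links[[lk$score]] <- rbind(links[[lk$score]],
      data.frame(protein_id = pid[p], score = lk$score, rho = lk$rho,
                 stringsAsFactors = FALSE))
  }
  # when a link is planted, the score is a pure monotone map of the copula
  # latent (group shifts would dilute the planted rank correlation)
  if (is.null(links$mmse)) {
    mmse_base <- c(CON = 28.5, FTD = 24, AD = 21)[meta$group]
    meta$mmse <- round(pmin(30, pmax(0, mmse_base + 2.5 * z_mmse)))
  } else {
    meta$mmse <- round(pmin(30, pmax(0, 24 + 4 * z_mmse)))
  }
  is_ftd <- meta$group == "FTD" & !meta$is_bridging
  meta$ftld_cdr[is_ftd] <- round(pmax(0, 4 + 3 * z_cdr[is_ftd]), 1)
  meta$cdr_rater[is_ftd] <- sample(c("R1", "R2", "R3"), sum(is_ftd), replace = TRUE)

  lod <- if (cf$lod_quantile > 0)
    apply(values[!meta$is_bridging, , drop = FALSE], 2, stats::quantile,
          probs = cf$lod_quantile, names = FALSE)
  else rep(-Inf, cf$n_proteins)
  names(lod) <- pid
  colnames(values) <- pid

  truth <- data.frame(protein_id = pid, category = category,
                      effect_ftd = effect_ftd, effect_ad = effect_ad,
                      effect_subtype = effect_sub, stringsAsFactors = FALSE)
  clinical_truth <- do.call(rbind, Filter(Negate(is.null), links))

  out <- list(npx = npx_matrix(values, lod), meta = meta, truth = truth,
              clinical_truth = clinical_truth, config = cf)
  class(out) <- "synthetic_cohort"
  validate_metadata(out$meta, out$npx)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d measurements (%d bridging) x %d proteins, seed %d\n",
              nrow(x$npx$values), sum(x$meta$is_bridging), ncol(x$npx$values),
              x$config$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Simulate paired measurements of one analyte on two platforms
#'
#' Test input for method-comparison regression: true concentrations are
#' drawn from a lognormal (meanlog \code{log(50)}, sdlog 0.5, so values
#' are positive and right-skewed like immunoassay concentrations), and
#' measurement error of equal SD is added on both axes
#' (error-in-both-variables, the setting Passing-Bablok is built for).
#'
#' @param n number of pairs (>= 3).
#' @param slope,intercept true line (\code{slope != 0}).
#' @param noise_sd measurement noise SD applied to each axis.
#' @param seed integer seed.
#' @return a \code{paired_measurements} list: \code{ids}, \code{x},
#'   \code{y}.
#' @export
simulate_paired_measurements <- function(n, slope, intercept = 0,
                                         noise_sd = 0, seed) {
  if (n < 3) stop("'n' must be >= 3", call. = FALSE)
  if (slope == 0) stop("'slope' must be nonzero", call. = FALSE)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  true_x <- stats::rlnorm(n, log(50), 0.5)
  x <- true_x + stats::rnorm(n, 0, noise_sd)
  y <- slope * true_x + intercept + stats::rnorm(n, 0, noise_sd)
  structure(list(ids = sprintf("PM%03d", seq_len(n)), x = x, y = y),
            class = "paired_measurements")
}
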