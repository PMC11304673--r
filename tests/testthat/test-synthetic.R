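test_that("config validation rejects bad mixtures and windows", {
  p <- function(mix) pattern_spec("A", mix, c(DM = 0.1), "HYP", c(0, 0.4))
  expect_error(synthetic_config(10, "uk", "male", 1,
                                list(p(0.5), pattern_spec("B", 0.4, c(DM = 0.1)))),
               "sum")
  expect_error(pattern_spec("A", 0.5, c(DM = 0.1), "HYP", c(0.2, 1.2)),
               "first_window")
  expect_error(pattern_spec("A", 0.5, c(DM = 1.4)), "incidence")
  cfg <- synthetic_config(0, "uk", "male", 1, list(p(1)))
  out <- generate_cohort(cfg)
  expect_equal(nrow(out$trajectories), 0)
  expect_length(out$labels, 0)
})

test_that("generation is seed-deterministic and windows are respected", {
  cfg <- study_emulation_config("uk", "male", n = 600, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # EarlyHyp members: hypertension within the first 40% of follow-up
  hyp_t <- a$trajectories$t_hyp[a$labels == "EarlyHyp"]
  expect_true(all(hyp_t <= 0.4))
  late_t <- a$trajectories$t_hyp[a$labels == "LateHyp"]
  expect_true(all(late_t > 0.4 & late_t <= 0.8))
  # designated first disease is first: DM pattern members all have DM
  expect_true(all(a$trajectories$occ_dm[a$labels == "FirstDM"]))
})

test_that("pattern frequencies converge to mixing proportions without covariate effects", {
  # Healthy share fixed at the published female stratum fraction
  sizes <- c(EarlyHyp = 241, FirstDM = 101, FirstHD = 71, Healthy = 8490,
             LateHyp = 339)
  mix <- sizes / sum(sizes)
  patterns <- list(
    pattern_spec("EarlyHyp", mix[["EarlyHyp"]], c(DM = 0.05), "HYP", c(0.02, 0.4)),
    pattern_spec("FirstDM", mix[["FirstDM"]], c(HYP = 0.5), "DM", c(0.02, 0.7)),
    pattern_spec("FirstHD", mix[["FirstHD"]], c(HYP = 0.45), "HD", c(0.02, 0.6)),
    pattern_spec("Healthy", mix[["Healthy"]], c(HYP = 0.003), NA, c(0.6, 1)),
    pattern_spec("LateHyp", mix[["LateHyp"]], c(DM = 0.05), "HYP", c(0.4, 0.8)))
  cfg <- synthetic_config(20000, "uk", "female", seed = 7,
                          pattern_specs = patterns)
  out <- generate_cohort(cfg)
  p_healthy <- mix[["Healthy"]]
  se <- sqrt(p_healthy * (1 - p_healthy) / 20000)
  expect_lt(abs(mean(out$labels == "Healthy") - p_healthy), 3 * se)
  # jointly, observed pattern counts are consistent with the mixture
  obs <- table(factor(out$labels, levels = names(mix)))
  gof <- stats::chisq.test(as.integer(obs), p = as.numeric(mix))
  expect_gt(gof$p.value, 0.001)
})

test_that("MCAR missingness injection hits the requested rate", {
  cfg <- study_emulation_config("brasil", "female", n = 500, seed = 5,
                                missingness_rate = 0)
  cov <- generate_cohort(cfg)$covariates
  expect_identical(inject_missingness(cov, 0, 1), cov)
  all_na <- inject_missingness(cov, 1, 1)
  maskable <- setdiff(names(cov), c("participant_id", "sex", "follow_up_years"))
  expect_true(all(is.na(as.matrix(all_na[, maskable]))))
  expect_false(anyNA(all_na$participant_id))
  r <- inject_missingness(cov, 0.1, 2)
  cells <- length(maskable) * nrow(cov)
  frac <- sum(is.na(as.matrix(r[, maskable]))) / cells
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / cells))
})

test_that("study-emulation configs reproduce the published stratum fractions", {
  for (d in c("uk", "brasil")) for (s in c("male", "female")) {
    cfg <- study_emulation_config(d, s)
    mix <- vapply(cfg$pattern_specs, `[[`, 0, "mixing_proportion")
    expect_equal(sum(mix), 1, tolerance = 1e-12)
  }
  expect_equal(study_emulation_config("uk", "female")$
                 pattern_specs$Healthy$mixing_proportion, 8490 / 9242)
  expect_equal(study_emulation_config("brasil", "male")$
                 pattern_specs$Healthy$mixing_proportion, 1981 / 2870)
  expect_equal(study_emulation_config("uk", "male")$n, 8458)
})

test_that("a planted monotone covariate effect separates pattern groups", {
  patterns <- list(
    pattern_spec("Healthy", 0.7, c(HYP = 0.01), NA, c(0.6, 1)),
    pattern_spec("EarlyHyp", 0.3, c(DM = 0.05), "HYP", c(0.02, 0.4)))
  covs <- list(covariate_spec("risk", "continuous", mean = 0, sd = 1,
                              effects = list(EarlyHyp = 0.5)))
  cfg <- synthetic_config(5000, "uk", "male", seed = 17,
                          pattern_specs = patterns, covariate_specs = covs)
  out <- generate_cohort(cfg)
  ht <- compare_groups(out$covariates$risk, out$labels, test = "anova")
  expect_true(ht$significant)
  expect_gt(mean(out$covariates$risk[out$labels == "EarlyHyp"]),
            mean(out$covariates$risk[out$labels == "Healthy"]))
})

test_that("synthetic configs survive a YAML round trip", {
  cfg <- study_emulation_config("brasil", "male", n = 120, seed = 9)
  f <- tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, f)
  back <- read_synthetic_config(f)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})
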