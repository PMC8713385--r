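test_that("generate_worked_spectrum honours the noise and seeding contract", {
  p <- true_params()
  exact <- generate_worked_spectrum(p, noise_cv = 0)
  expect_equal(exact$z, cole_eval(p, default_grid()), tolerance = 1e-15)
  a <- generate_worked_spectrum(p, noise_cv = 0.01, seed = 1)
  b <- generate_worked_spectrum(p, noise_cv = 0.01, seed = 2)
  expect_false(identical(a$z, b$z))
  expect_identical(a$z, generate_worked_spectrum(p, 0.01, seed = 1)$z)
  # law of large numbers: many replicates average back to the curve
  set.seed(3)
  zbar <- Reduce(`+`, lapply(1:1000, function(i)
    generate_worked_spectrum(p, noise_cv = 0.01)$z)) / 1000
  expect_lt(max(Mod(zbar - exact$z) / Mod(exact$z)), 1e-3)
})

test_that("cohorts are reproducible and structurally valid", {
  cfg <- cohort_preset("diagnosis", n = 30, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1[[7]]$spectra[[3]]$z, c2[[7]]$spectra[[3]]$z)
  ns <- vapply(c1, function(r) length(r$spectra), integer(1))
  expect_true(all(ns >= 8 & ns <= 12))
  lat <- attr(c1, "latent")
  expect_equal(nrow(lat), 30)
  expect_true(all(lat$rinf < lat$r0))
  # all patients valid and labelled
  expect_true(all(vapply(c1, `[[`, logical(1), "valid")))
  expect_true(all(vapply(c1, `[[`, numeric(1), "label") %in% 0:1))
})

test_that("the diagnosis preset reproduces the design prevalence", {
  cfg <- cohort_preset("diagnosis", seed = 2)
  lab <- attr(generate_cohort(cfg), "latent")$label
  expect_equal(length(lab), 1704)
  # binomial(1704, 0.3099): realized count within 4 sd of 528
  expect_lt(abs(sum(lab) - 528), 4 * sqrt(1704 * 0.31 * 0.69))
})

test_that("null configuration carries no group signal", {
  cfg <- cohort_preset("null", n = 120, seed = 9)
  fe <- suppressWarnings(extract_features_cohort(generate_cohort(cfg)))
  p <- manova_test(fe[, c("r0_mean", "alpha_mean", "d_r0", "d_alpha")],
                   fe$label)$p_value
  expect_gt(p, 0.001)
  expect_lt(abs(roc_auc(fe$alpha_mean, fe$label)$auc - 0.5), 0.2)
})

test_that("lesion extent routes signal through the expected feature family", {
  # small single-site lesions: spread features beat mean features;
  # full-coverage lesions: mean features beat spread features
  auc_of <- function(cfg, col) {
    fe <- suppressWarnings(extract_features_cohort(generate_cohort(cfg)))
    vapply(col, function(cl) {
      a <- roc_auc(fe[[cl]], fe$label)$auc
      max(a, 1 - a)  # orientation-free discriminability
    }, numeric(1))
  }
  small_cfg <- cohort_config(n_patients = 150, prevalence = 0.4,
                             lesion = list(p_large = 0, large_frac = 1,
                                           small_max = 1L),
                             seed = 21)
  large_cfg <- cohort_config(n_patients = 150, prevalence = 0.4,
                             lesion = list(p_large = 1, large_frac = 1,
                                           small_max = 1L),
                             seed = 22)
  a_small <- auc_of(small_cfg, c("r0_mean", "d_r0"))
  a_large <- auc_of(large_cfg, c("r0_mean", "d_r0"))
  expect_gt(a_small[["d_r0"]], a_small[["r0_mean"]])
  expect_gt(a_large[["r0_mean"]], a_large[["d_r0"]])
})

test_that("the latent likelihood-ratio score is the best ranking available", {
  cfg <- cohort_preset("diagnosis", seed = 1)
  lat <- generate_latent(cfg, 4000, seed = 3)
  llr <- bayes_score(lat, cfg)
  auc_llr <- roc_auc(llr, lat$label)$auc
  # any single-coordinate ranking is weaker
  for (cl in c("r0", "alpha", "fc", "rinf")) {
    a <- roc_auc(lat[[cl]], lat$label)$auc
    expect_gte(auc_llr, max(a, 1 - a))
  }
  # oracle is reproducible and sits in the engineered high range
  expect_equal(oracle_auc(cfg, n = 2e4, seed = 5),
               oracle_auc(cfg, n = 2e4, seed = 5))
  expect_gt(oracle_auc(cfg, n = 2e4, seed = 5), 0.9)
  # mixture lesion configs have no closed-form score
  expect_error(bayes_score(lat, cohort_preset("prognosis")),
               "full-coverage")
})
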