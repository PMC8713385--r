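test_that("stratified folds preserve class proportions to within one", {
  set.seed(3)
  for (i in 1:20) {
    n1 <- sample(10:80, 1); n0 <- sample(100:600, 1)
    k <- sample(2:6, 1)
    labels <- sample(rep(c(1, 0), c(n1, n0)))
    plan <- cv_plan(k = k, seed = i)
    f <- stratified_folds(labels, plan)
    sizes <- tabulate(f, k)
    for (j in seq_len(k)) for (cls in c(0, 1)) {
      got <- sum(labels == cls & f == j)
      expect_lte(abs(got - sum(labels == cls) * sizes[j] / (n0 + n1)), 1)
    }
  }
})

test_that("the 35/534 five-fold split puts exactly 7 positives in each fold", {
  labels <- rep(c(1, 0), c(35, 534))
  f <- stratified_folds(labels, cv_plan(k = 5, seed = 42))
  expect_equal(as.vector(tapply(labels, f, sum)), rep(7, 5))
})

test_that("asymmetric two-fold sizes reproduce the population rate in-train", {
  labels <- rep(c(1, 0), c(528, 1176))
  plan <- cv_plan(k = 2, seed = 1, fold_sizes = c(1000, 704))
  f <- stratified_folds(labels, plan)
  expect_equal(sum(f == 1), 1000)
  expect_equal(sum(labels == 1 & f == 1), 310)  # 31.0% of 1000
  # determinism
  expect_identical(f, stratified_folds(labels, plan))
  expect_error(stratified_folds(rep(c(1, 0), c(3, 100)), cv_plan(k = 5)),
               "fewer members")
})

test_that("AUC equals the pairwise Mann-Whitney oracle and pROC agrees", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(8:120, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    sc <- round(rnorm(n), 1)  # coarse scores force ties
    r <- roc_auc(sc, y)
    pos <- sc[y == 1]; neg <- sc[y == 0]
    u <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, u, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(300, 1, 0.3); sc <- rnorm(300) + y
  expect_equal(roc_auc(sc, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("the Youden operating point matches the exhaustive-threshold oracle", {
  set.seed(16)
  for (i in 1:30) {
    n <- sample(10:150, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    sc <- round(runif(n), 2)
    r <- roc_auc(sc, y)
    js <- vapply(r$thresholds, function(t)
      mean(sc[y == 1] >= t) + mean(sc[y == 0] < t) - 1, numeric(1))
    expect_equal(r$youden_j, max(js), tolerance = 1e-12)
    expect_equal(r$oop_sensitivity + r$oop_specificity - 1, r$youden_j,
                 tolerance = 1e-12)
    # smallest threshold among the maximizers
    expect_equal(r$oop_threshold,
                 min(r$thresholds[js >= max(js) - 1e-12]))
  }
  # perfect separation and degenerate scores
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_warning(rd <- roc_auc(rep(0.5, 20), rep(c(0, 1), 10)), "degenerate")
  expect_equal(rd$auc, 0.5)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(17)
  y <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(rnorm(2000), y)$auc - 0.5), 0.03)
})

test_that("cv_select is deterministic, ranks by mean AUC and breaks ties by size", {
  set.seed(18)
  fe <- make_feature_table(240, seed = 18)
  fe$label <- rbinom(240, 1, plogis(-1 + 4 * fe$alpha_mean))
  bases <- list(basis_spec(c(alpha_mean = 1)),
                basis_spec(c(alpha_mean = 1), c(d_alpha = 1)),
                basis_spec(c(d_rinf = 1)))
  plan <- cv_plan(k = 2, repeats = 1, seed = 5)
  cv1 <- cv_select(fe, bases, plan)
  cv2 <- cv_select(fe, bases, plan)
  expect_identical(cv1$table, cv2$table)
  expect_identical(cv1$auc, cv2$auc)
  # the alpha bases outrank the noise basis
  expect_true(which(cv1$table$basis == "d_rinf") == 3)
  # equal mean AUC -> fewer terms first
  aucs <- c(0.7, 0.7)
  tab <- data.frame(basis = c("big", "small"), n_terms = c(3, 1),
                    mean_auc = aucs, failed = FALSE)
  ord <- order(tab$failed, -tab$mean_auc, tab$n_terms)
  expect_equal(tab$basis[ord], c("small", "big"))
})

test_that("with cubic generating signal the degree-3 structure usually wins", {
  b_lin <- basis_spec(c(r0_mean = 1), c(alpha_mean = 1), c(d_r0 = 1),
                      include_ci = TRUE, include_ref = TRUE)
  b_sq <- basis_spec(c(r0_mean = 2), c(alpha_mean = 2), c(d_r0 = 2),
                     include_ci = TRUE, include_ref = TRUE)
  b_cub <- basis_spec(c(r0_mean = 3), c(alpha_mean = 3), c(d_r0 = 3),
                      include_ci = TRUE, include_ref = TRUE)
  wins <- 0L
  for (r in 1:10) {
    fe <- make_feature_table(2000, seed = 100 + r)
    # cubic signal with strong curvature over the feature range
    a <- 0.5 - 3e-9 * fe$r0_mean^3 + 150 * fe$alpha_mean^3 +
      6e-8 * fe$d_r0^3 + 1.5 * fe$ci + 1.3 * fe$ref
    fe$label <- eiscole:::with_seed(200 + r, rbinom(2000, 1, plogis(a)))
    cv <- cv_select(fe, list(b_lin, b_sq, b_cub),
                    cv_plan(k = 2, repeats = 3, seed = 300 + r))
    if (cv$table$basis[1] == basis_label(b_cub)) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("baseline raw-spectrum scores behave as documented", {
  g <- default_grid()
  flat <- eis_spectrum(g, rep(500 - 1i, 14))
  expect_equal(unname(baseline_single_feature(list(flat), "slope")), 0,
               tolerance = 1e-12)
  # two patients differing only in R0 order by the 152 Hz feature
  lo <- make_patient("lo", true_params(r0 = 1200), noise_cv = 0)
  hi <- make_patient("hi", true_params(r0 = 1800), noise_cv = 0)
  s <- baseline_single_feature(list(lo, hi), "z_152")
  expect_lt(s[["lo"]], s[["hi"]])
  # |slope| grows with alpha over the identifiable low range
  slopes <- vapply(seq(0.02, 0.3, length.out = 8), function(a)
    unname(baseline_single_feature(
      list(eis_spectrum(g, cole_eval(true_params(alpha = a), g))), "slope")),
    numeric(1))
  expect_true(all(diff(abs(slopes)) > 0))
  bad <- eis_spectrum(c(10, 20, 50), rep(100 + 0i, 3))
  expect_error(baseline_single_feature(list(bad), "z_152"), "outside")
})
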