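test_that("basis terms validate and label deterministically", {
  b <- basis_spec(c(alpha_mean = 2), c(d_alpha = 2))
  expect_equal(basis_label(b), "alpha_mean^2 + d_alpha^2")
  bc <- basis_spec(c(alpha_mean = 1, d_alpha = 1))
  expect_equal(basis_label(bc), "alpha_mean*d_alpha")
  expect_error(basis_spec(c(r0_mean = 4)), "degree")
  expect_error(basis_spec(c(r0_mean = 0.5)), "positive integers")
  expect_error(basis_spec(c(a = 1), c(a = 1)), "duplicate")
  expect_error(basis_spec(), "at least one term")
})

test_that("design_matrix evaluates monomials, intercept and dummies", {
  fe <- data.frame(alpha_mean = 0.2, d_alpha = 0.1, r0_mean = 1000,
                   ci = 1, ref = 0)
  X <- design_matrix(fe, basis_spec(c(alpha_mean = 2), c(d_alpha = 2)))
  expect_equal(unname(X[1, 1:2]), c(0.04, 0.01))
  Xc <- design_matrix(fe, basis_spec(c(alpha_mean = 1, d_alpha = 1)))
  expect_equal(unname(Xc[1, 1]), 0.02)
  X3 <- design_matrix(fe, basis_spec(c(r0_mean = 3), include_ci = TRUE,
                                     include_ref = TRUE))
  expect_equal(unname(X3[1, ]), c(1e9, 1, 1, 0))
  expect_equal(colnames(X3), c("r0_mean^3", "(Intercept)", "CI", "Ref"))
  expect_error(design_matrix(fe, basis_spec(c(nope = 2))), "nope")
})

test_that("logistic fit recovers known coefficients and Wald intervals", {
  beta <- c(3.4, 3.0, -3)  # alpha_mean^2, d_alpha^2, intercept
  b <- basis_spec(c(alpha_mean = 2), c(d_alpha = 2))
  set.seed(77)
  d <- data.frame(alpha_mean = runif(5000), d_alpha = runif(5000))
  a <- beta[3] + beta[1] * d$alpha_mean^2 + beta[2] * d$d_alpha^2
  d$label <- rbinom(5000, 1, plogis(a))
  fit <- fit_logistic(d, basis = b)
  expect_true(fit$converged)
  expect_true(all(abs(coef(fit) - beta) / fit$se < 4))
  expect_true(all(fit$p_values < 1e-6))
})

test_that("degenerate outcomes raise the documented diagnostics", {
  d <- data.frame(alpha_mean = runif(20), d_alpha = runif(20))
  b <- basis_spec(c(alpha_mean = 1))
  d$label <- 1
  expect_error(fit_logistic(d, basis = b), "constant")
  # 10 linearly separable points -> separation diagnostic, not an error
  d2 <- data.frame(alpha_mean = c(1:5, 11:15) / 10,
                   label = rep(c(0, 1), each = 5))
  fit <- fit_logistic(d2, basis = b)
  expect_false(fit$converged)
  expect_true(fit$separation)
  # collinear columns are named
  d3 <- data.frame(alpha_mean = runif(30), label = rbinom(30, 1, 0.5))
  d3$d_alpha <- 2 * d3$alpha_mean
  expect_error(
    fit_logistic(d3, basis = basis_spec(c(alpha_mean = 1), c(d_alpha = 1))),
    "collinear")
})

test_that("predictions obey the logistic symmetry and dummy shifts", {
  b <- basis_spec(c(alpha_mean = 2), c(d_alpha = 2), include_ci = TRUE)
  m <- logistic_model(b, c(2, -1, 0.5, 1.2))
  m_neg <- logistic_model(b, -c(2, -1, 0.5, 1.2))
  fe <- make_feature_table(50, seed = 9)
  p <- predict_prob(m, fe)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p + predict_prob(m_neg, fe), rep(1, 50), tolerance = 1e-12)
  # toggling CI shifts a(x) by exactly beta_CI
  fe1 <- fe; fe1$ci <- 0
  fe2 <- fe; fe2$ci <- 1
  expect_equal(predict(m, fe2, type = "link") - predict(m, fe1, type = "link"),
               rep(1.2, 50), tolerance = 1e-12)
})

test_that("a fit always beats the intercept-only model on training likelihood", {
  set.seed(31)
  d <- make_feature_table(200, seed = 31)
  d$label <- rbinom(200, 1, plogis(-1 + 2 * d$alpha_mean))
  fit <- fit_logistic(d, basis = basis_spec(c(alpha_mean = 1)))
  expect_lte(fit$deviance, fit$null_deviance + 1e-8)
})

test_that("huge raw-scale cubic features are handled and reported raw", {
  set.seed(41)
  d <- make_feature_table(800, seed = 41)
  a <- -3 - 7.5e-11 * d$r0_mean^3 + 3.4 * d$alpha_mean^3 + 2.4 * d$ci
  d$label <- rbinom(800, 1, plogis(a))
  b <- basis_spec(c(r0_mean = 3), c(alpha_mean = 3), include_ci = TRUE)
  fit <- fit_logistic(d, basis = b)
  expect_true(fit$converged)
  # coefficient on the cubic ohm column comes back on the raw scale
  expect_lt(abs(coef(fit)[["r0_mean^3"]]), 1e-8)
  expect_true(is.finite(fit$se[["r0_mean^3"]]))
})
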