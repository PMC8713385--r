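test_that("cole_eval reproduces the analytic limits and special points", {
  p <- true_params(r_inf = 300, r0 = 1500, fc = 5000, alpha = 0.15)
  # f -> 0: Z -> R0; f -> Inf: Z -> Rinf
  expect_equal(Re(cole_eval(p, 1e-9)), 1500, tolerance = 1e-6)
  expect_equal(Re(cole_eval(p, 1e12)), 300, tolerance = 1e-3)
  # alpha = 0 at f = fc: Z = Rinf + (R0-Rinf)/(1+j)
  p0 <- true_params(alpha = 0)
  z <- cole_eval(p0, 5000)
  expect_equal(Re(z), 300 + 1200 / 2, tolerance = 1e-12)
  expect_equal(Im(z), -1200 / 2, tolerance = 1e-12)
  # capacitive: Im(Z) <= 0 everywhere
  expect_true(all(Im(cole_eval(p, default_grid())) <= 0))
  # alpha = 1 (degenerate flat dispersion) is rejected
  expect_error(cole_eval(true_params(alpha = 1), 100), "alpha")
  expect_error(cole_eval(true_params(r_inf = 2000), 100), "r_inf < r0")
})

test_that("initial guess reads the spectrum ends and handles degeneracy", {
  p <- true_params()
  sp <- generate_worked_spectrum(p, noise_cv = 0)
  g <- cole_initial_guess(sp)
  expect_lt(abs(g[["r0"]] - p[["r0"]]) / p[["r0"]], 0.05)
  expect_gt(g[["fc"]], 0)
  # monotone -Im with max at the last grid point
  f <- default_grid()
  z <- complex(real = seq(1500, 300, length.out = 14),
               imaginary = -seq(1, 14))
  g2 <- cole_initial_guess(eis_spectrum(f, z))
  expect_equal(g2[["fc"]], 625000)
  # flat, purely real spectrum -> geometric mid-grid fc with warning
  zf <- rep(500 + 0i, 14)
  expect_warning(g3 <- cole_initial_guess(eis_spectrum(f, zf)),
                 "no reactive")
  expect_equal(g3[["fc"]], sqrt(76 * 625000))
})

test_that("noise-free spectra are recovered to well under 0.1% per parameter", {
  set.seed(42)
  for (i in 1:20) {
    p <- true_params(r_inf = runif(1, 100, 800),
                     r0 = runif(1, 900, 3000),
                     fc = exp(runif(1, log(500), log(50000))),
                     alpha = runif(1, 0.05, 0.5))
    if (p[["r_inf"]] >= p[["r0"]]) next
    fit <- fit_cole(generate_worked_spectrum(p, noise_cv = 0))
    expect_true(fit$converged)
    expect_lt(max(abs(coef(fit) - p) / p), 1e-3)
  }
})

test_that("fitted rss never exceeds the rss of the initial guess", {
  set.seed(7)
  for (i in 1:10) {
    p <- true_params(alpha = runif(1, 0.1, 0.4))
    sp <- generate_worked_spectrum(p, noise_cv = 0.05, seed = i)
    g <- cole_initial_guess(sp)
    rss0 <- sum(Mod(sp$z - cole_eval(g, sp$freq))^2)
    expect_lte(fit_cole(sp)$rss, rss0 + 1e-8)
  }
})

test_that("impedance scaling scales resistances; frequency scaling scales fc", {
  p <- true_params()
  f <- default_grid()
  z <- cole_eval(p, f)
  base <- coef(fit_cole(eis_spectrum(f, z)))
  for (cc in c(0.5, 3)) {
    sc <- coef(fit_cole(eis_spectrum(f, cc * z)))
    expect_equal(sc[["r0"]], cc * base[["r0"]], tolerance = 1e-6)
    expect_equal(sc[["r_inf"]], cc * base[["r_inf"]], tolerance = 1e-6)
    expect_equal(sc[["fc"]], base[["fc"]], tolerance = 1e-6)
    expect_equal(sc[["alpha"]], base[["alpha"]], tolerance = 1e-6)
    # scale the frequency axis: spectrum values at f*cc correspond to
    # a model with fc*cc
    zf <- cole_eval(p, f / cc)
    fc_fit <- coef(fit_cole(eis_spectrum(f, zf)))
    expect_equal(fc_fit[["fc"]], cc * p[["fc"]], tolerance = 1e-5)
    expect_equal(fc_fit[["alpha"]], p[["alpha"]], tolerance = 1e-6)
    expect_equal(fc_fit[["r0"]], p[["r0"]], tolerance = 1e-6)
  }
})

test_that("mean_spectrum averages pointwise and refuses mismatched grids", {
  p <- true_params()
  s1 <- generate_worked_spectrum(p, noise_cv = 0, site = 1)
  s2 <- generate_worked_spectrum(p, noise_cv = 0, site = 2)
  m <- mean_spectrum(list(s1, s2))
  expect_equal(m$z, s1$z)  # idempotent on identical spectra
  s3 <- eis_spectrum(s1$freq, s1$z * 3, site = 3)
  m2 <- mean_spectrum(list(s1, s3))
  expect_equal(m2$z, (s1$z + s3$z) / 2)  # linearity
  other <- eis_spectrum(default_grid(f_min = 100), s1$z, site = 4)
  expect_error(mean_spectrum(list(s1, other)), "grid")
})

test_that("fitting the mean spectrum beats the median single-site fit", {
  set.seed(11)
  p <- true_params()
  err_mean <- err_site <- numeric(20)
  for (r in 1:20) {
    spectra <- lapply(1:8, function(s)
      generate_worked_spectrum(p, noise_cv = 0.05, site = s))
    site_err <- vapply(spectra, function(sp)
      max(abs(coef(fit_cole(sp)) - p) / p), numeric(1))
    err_site[r] <- stats::median(site_err)
    err_mean[r] <- max(abs(coef(fit_cole(mean_spectrum(spectra))) - p) / p)
  }
  expect_lt(mean(err_mean), mean(err_site))
})

test_that("cole_fit methods are coherent", {
  p <- true_params()
  sp <- generate_worked_spectrum(p, noise_cv = 0.01, seed = 5)
  fit <- fit_cole(sp)
  expect_s3_class(fit, "cole_fit")
  expect_equal(sum(residuals(fit, "stacked")^2), fit$rss, tolerance = 1e-8)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 3, seed = 1, noise_cv = 0.02)
  expect_length(sims, 3)
  expect_false(identical(sims[[1]]$z, sims[[2]]$z))
  expect_output(print(summary(fit)), "Cole model fit")
})
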