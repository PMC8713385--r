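# Fixtures built in code: noise-free patients from known Cole
# parameters, and small spectrum CSVs written to tempfiles.

true_params <- function(r_inf = 300, r0 = 1500, fc = 5000, alpha = 0.15) {
  c(r_inf = r_inf, r0 = r0, fc = fc, alpha = alpha)
}

# patient whose sites are all generated from `params` (optionally noisy)
make_patient <- function(id = "P1", params = true_params(), n_sites = 8,
                         noise_cv = 0, seed = NULL, ci = 0, ref = 0,
                         label = 0) {
  grid <- default_grid()
  spectra <- eiscole:::with_seed(seed, lapply(seq_len(n_sites), function(s)
    generate_worked_spectrum(params, noise_cv = noise_cv, grid = grid,
                             site = s)))
  eis_patient(id, spectra, ci = ci, ref = ref, label = label)
}

write_spectrum_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write_spectra(records, path)
  path
}

write_covariate_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write_covariates(records, path)
  path
}

# feature table drawn directly in feature space (no spectra), for
# classifier-level tests
make_feature_table <- function(n, seed = 1) {
  eiscole:::with_seed(seed, data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    rinf_mean = rlnorm(n, log(350), 0.26),
    r0_mean = rlnorm(n, log(1500), 0.34),
    fc_mean = rlnorm(n, log(4000), 0.41),
    alpha_mean = 0.05 + 0.35 * rbeta(n, 2, 2),
    d_rinf = rlnorm(n, log(70), 0.3),
    d_r0 = rlnorm(n, log(300), 0.3),
    d_fc = rlnorm(n, log(900), 0.3),
    d_alpha = rlnorm(n, log(0.05), 0.3),
    ci = rbinom(n, 1, 0.3), ref = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE))
}
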