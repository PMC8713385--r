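# eiscole

Template-free analysis of multi-site **electrical impedance
spectroscopy (EIS)** readings of epithelial tissue, built for the
cervical screening setting: detecting high-grade cervical
intraepithelial neoplasia (HG CIN) as an adjunct to colposcopy, and
assessing whether readings taken at a negative colposcopy carry
prognostic information about later disease.

EIS probes tissue with a weak current at 14 logarithmically spaced
frequencies between 76 Hz and 625 kHz, at 8–12 reading sites around
the cervix per patient. Instead of matching raw spectra against
finite-element template libraries, `eiscole` summarises each site with
the single-dispersion **Cole model**

    Z(f) = R∞ + (R0 − R∞) / (1 + (j f / fc)^(1−α))

whose parameters carry tissue meaning (R0 ~ inverse extracellular
volume, R∞ ~ inverse total volume, fc ~ cell size, α ~ cellular
inhomogeneity), and classifies patients from fitted-parameter
features.

The analysis chain:

1. **`fit_cole()`** — bounded complex nonlinear least squares per
   site, returning a classed fit with `print`/`summary`/`coef`/
   `predict`/`plot`/`residuals`/`simulate` methods.
2. **`extract_features()`** — the 8-feature vector per patient:
   Cole parameters of the pointwise mean spectrum (R̄∞, R̄0, f̄c, ᾱ;
   sensitive to large lesions) plus max-minus-min spreads across
   sites (ΔR∞, ΔR0, Δfc, Δα; sensitive to small lesions).
3. **`rank_subsets()`** — exhaustive feature-subset ranking by
   two-group MANOVA (Wilks' Λ, exact F for two groups).
4. **`fit_logistic()`** — unpenalized polynomial-basis logistic
   regression, P(C₁|x) = 1/(1+e^(−a(x))) with
   a(x) = β₀ + Σ βᵢ φᵢ(x) + β_CI·CI + β_Ref·Ref, where φᵢ are
   monomials of total degree ≤ 3 and CI/Ref are binary clinical
   covariates (colposcopic impression, referral cytology).
5. **`cv_select()`** — model-structure selection by repeated
   *stratified* k-fold cross-validation on held-out AUC (2-fold with
   an asymmetric train/test split for detection; 5-fold with pooled
   held-out scores for prognosis).
6. **`roc_auc()`** — ROC, Mann–Whitney AUC, and the Youden-index
   operating point (J = sensitivity + specificity − 1).
7. **`generate_cohort()`** — a synthetic multi-site cohort generator
   with known group structure, including a closed-form Bayes-AUC
   ceiling (`oracle_auc()`) for full-coverage lesion configurations,
   so the whole chain is testable end to end without any clinical
   data.

`run_diagnosis_pipeline()` and `run_prognosis_pipeline()` orchestrate
the full chain and write plain CSV/JSON reports.

## Worked example

Fit one noisy spectrum generated from known parameters
(R∞ = 300 Ω, R0 = 1500 Ω, fc = 5 kHz, α = 0.15):

```r
library(eiscole)
truth <- c(r_inf = 300, r0 = 1500, fc = 5000, alpha = 0.15)
sp <- generate_worked_spectrum(truth, noise_cv = 0.01, seed = 42)
fit_cole(sp)
#> Cole model fit (bounded nonlinear least squares)
#>    r_inf       r0       fc    alpha
#>  298.510 1513.500 4914.600    0.159
#> rss 3761 ohm^2, 5 iterations, converged: TRUE
```

All four parameters come back within ~2% under 1% measurement noise
(and to machine precision without noise).

Run the detection analysis end to end on a synthetic cohort and
compare the cross-validated AUC with the generating model's ceiling:

```r
cfg <- cohort_preset("diagnosis", n = 400, seed = 1)
res <- run_diagnosis_pipeline(config = cfg, repeats = 3, seed = 1)
res$cv
#> Repeated stratified 2-fold CV (3 repetitions, master seed 1)
#>                                             basis n_terms mean_auc failed
#> 1 r0_mean^2 + fc_mean^2 + alpha_mean^2 + CI + Ref       3   0.9592  FALSE
#> 2       r0_mean + fc_mean + alpha_mean + CI + Ref       3   0.9584  FALSE
#> 3 r0_mean^3 + fc_mean^3 + alpha_mean^3 + CI + Ref       3   0.9570  FALSE
oracle_auc(cfg)
#> [1] 0.9633
res$roc
#> ROC: AUC = 0.9715 (128 pos / 272 neg)
#> OOP (max Youden J = 0.8332) at threshold 0.3479: sensitivity 91.4%, specificity 91.9%
```

The winning structure's held-out AUC (0.959) sits just below the
Bayes ceiling of the generating model (0.963) — the classifier is
extracting essentially all the information the cohort contains. The
final-model ROC row shows the Youden operating point with its
sensitivity/specificity pair; `plot(res$roc)` draws the curve with
the operating point marked.

## Scope

The package implements single-dispersion Cole analysis only
(multi-dispersion tissues are out of scope), works from tidy
long-format spectrum CSVs (`patient_id, site, freq_hz, z_re, z_im`,
magnitude/phase accepted via a flag), and makes no attempt to model
device-native file formats. See the vignette
(`vignettes/eis-cole-analysis.Rmd`) for the full methods account:
model assumptions, fitting bounds and tolerances, what the synthetic
generator does and does not emulate, and known limitations.
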