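#' Max-min spread of Cole parameters across reading sites
#'
#' For each Cole parameter, the maximum minus the minimum of the
#' per-site estimates over a patient's reading sites:
#' \deqn{\Delta R_\infty = \max_i R_{\infty i} - \min_i R_{\infty i}}
#' and analogously for `R0`, `fc` and `alpha`.  These spreads measure
#' the spatial inhomogeneity of the tissue around the cervix and are
#' the signal carriers for small lesions confined to one or a few
#' reading sites.  Non-converged site fits are excluded first: a failed
#' fit is a measurement artefact, not biology.
#'
#' @param site_fits list of `cole_fit` objects (one per site).
#' @return Named numeric vector `c(d_rinf, d_r0, d_fc, d_alpha)`, all
#'   `>= 0`, with attribute `n_used` (number of converged fits).
#'   Returns all-`NA` (with a warning) when fewer than 2 converged fits
#'   remain.
#' @export
max_differences <- function(site_fits) {
  stopifnot(is.list(site_fits),
            all(vapply(site_fits, inherits, logical(1), "cole_fit")))
  ok <- vapply(site_fits, `[[`, logical(1), "converged")
  fits <- site_fits[ok]
  if (length(fits) < 2L) {
    warning("fewer than 2 converged site fits; spread features undefined",
            call. = FALSE)
    return(structure(c(d_rinf = NA_real_, d_r0 = NA_real_,
                       d_fc = NA_real_, d_alpha = NA_real_),
                     n_used = length(fits)))
  }
  P <- t(vapply(fits, coef, numeric(4)))
  d <- apply(P, 2, max) - apply(P, 2, min)
  structure(c(d_rinf = d[["r_inf"]], d_r0 = d[["r0"]],
              d_fc = d[["fc"]], d_alpha = d[["alpha"]]),
            n_used = length(fits))
}

#' Extract the 8-dimensional feature vector of one patient
#'
#' Builds the per-patient features used for classification: the four
#' Cole parameters fitted to the pointwise mean spectrum over all
#' reading sites (`rinf_mean`, `r0_mean`, `fc_mean`, `alpha_mean`,
#' sensitive to large lesions covering many sites) and the four
#' max-min spreads of the per-site fits (`d_rinf`, `d_r0`, `d_fc`,
#' `d_alpha`, sensitive to small lesions).  Clinical covariates and the
#' outcome label are passed through unchanged.
#'
#' @param record an [eis_patient()].
#' @param control fit control passed to [fit_cole()].
#' @return One-row `data.frame` with columns `patient_id`, the 8
#'   features, `ci`, `ref`, `label` and a logical `incomplete` flag
#'   (set when the mean-spectrum fit fails to converge or fewer than 2
#'   site fits converge).
#' @seealso [extract_features_cohort()]
#' @export
extract_features <- function(record, control = list()) {
  stopifnot(inherits(record, "eis_patient"))
  if (!record$valid)
    warning(sprintf("patient %s has fewer than the minimum reading sites",
                    record$patient_id), call. = FALSE)
  mfit <- fit_cole(mean_spectrum(record$spectra), control = control)
  site_fits <- lapply(record$spectra, fit_cole, control = control)
  d <- suppressWarnings(max_differences(site_fits))
  incomplete <- !mfit$converged || anyNA(d)
  m <- coef(mfit)
  data.frame(patient_id = record$patient_id,
             rinf_mean = m[["r_inf"]], r0_mean = m[["r0"]],
             fc_mean = m[["fc"]], alpha_mean = m[["alpha"]],
             d_rinf = d[["d_rinf"]], d_r0 = d[["d_r0"]],
             d_fc = d[["d_fc"]], d_alpha = d[["d_alpha"]],
             ci = record$ci, ref = record$ref, label = record$label,
             incomplete = incomplete,
             stringsAsFactors = FALSE)
}

#' Extract features for a whole cohort
#'
#' Applies [extract_features()] to every valid patient record and binds
#' the rows.  Invalid records (fewer than the minimum reading sites)
#' are skipped with a warning.
#'
#' @param records list of [eis_patient()] objects.
#' @param control fit control passed to [fit_cole()].
#' @return `data.frame`, one row per retained patient.
#' @export
extract_features_cohort <- function(records, control = list()) {
  stopifnot(is.list(records), length(records) >= 1)
  keep <- vapply(records, `[[`, logical(1), "valid")
  if (!all(keep))
    warning(sprintf("skipping %d record(s) with fewer than the minimum sites: %s",
                    sum(!keep),
                    paste(vapply(records[!keep], `[[`, character(1),
                                 "patient_id"), collapse = ", ")),
            call. = FALSE)
  rows <- lapply(records[keep], extract_features, control = control)
  do.call(rbind, rows)
}
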