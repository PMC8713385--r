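#' Default EIS excitation-frequency grid
#'
#' The measurement grid used throughout the package: 14 logarithmically
#' spaced frequencies from 76 Hz to 625 kHz, the standard multi-frequency
#' protocol for cervical EIS probes.  Successive frequencies differ by a
#' factor of almost exactly 2.
#'
#' @param n_freq number of grid points (default 14).
#' @param f_min,f_max first and last frequency in Hz.
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @examples
#' round(default_grid()[1:3])
#' @export
default_grid <- function(n_freq = 14L, f_min = 76, f_max = 625e3) {
  stopifnot(n_freq >= 2L, f_min > 0, f_max > f_min)
  exp(seq(log(f_min), log(f_max), length.out = n_freq))
}

validate_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L || any(!is.finite(grid)) ||
      any(grid <= 0) || any(diff(grid) <= 0))
    stop("frequency grid must be strictly increasing, positive and finite",
         call. = FALSE)
  invisible(grid)
}

#' Construct a single-site impedance spectrum
#'
#' One reading site's complex impedance sampled on a frequency grid.
#'
#' @param freq frequency grid, Hz (strictly increasing).
#' @param z complex impedance at each frequency, ohms; finite with
#'   positive magnitude.
#' @param site integer reading-site index (1..12 by convention).
#' @return Object of class `"eis_spectrum"`: a list with elements
#'   `site`, `freq`, `z`.
#' @export
eis_spectrum <- function(freq, z, site = 1L) {
  validate_grid(freq)
  z <- as.complex(z)
  if (length(z) != length(freq))
    stop("`z` must have one value per frequency", call. = FALSE)
  if (any(!is.finite(Re(z))) || any(!is.finite(Im(z))) || any(Mod(z) <= 0))
    stop("impedance values must be finite with positive magnitude",
         call. = FALSE)
  structure(list(site = as.integer(site), freq = as.numeric(freq), z = z),
            class = "eis_spectrum")
}

#' @export
print.eis_spectrum <- function(x, ...) {
  cat(sprintf("EIS spectrum, site %d: %d frequencies %.3g-%.3g Hz, |Z| %.1f-%.1f ohm\n",
              x$site, length(x$freq), min(x$freq), max(x$freq),
              min(Mod(x$z)), max(Mod(x$z))))
  invisible(x)
}

#' Construct a per-patient EIS record
#'
#' Bundles one patient's reading-site spectra with the binary clinical
#' covariates (colposcopic impression `ci`, referral cytology `ref`,
#' both coded 1 = high grade, 0 = not) and the binary outcome label.
#' The measurement protocol takes 8 to 12 reading sites; records with
#' fewer than 8 usable sites are marked invalid rather than rejected so
#' that batch reads can continue.
#'
#' @param patient_id identifier string.
#' @param spectra list of [eis_spectrum()] objects with unique site indices.
#' @param ci,ref binary clinical covariates (may be `NA`).
#' @param label binary outcome; `NA` allowed for prediction-only use.
#' @param min_sites minimum usable site count (default 8).
#' @return Object of class `"eis_patient"`; element `valid` is `FALSE`
#'   when the record has fewer than `min_sites` spectra.
#' @export
eis_patient <- function(patient_id, spectra, ci = NA, ref = NA, label = NA,
                        min_sites = 8L) {
  stopifnot(is.list(spectra))
  if (!all(vapply(spectra, inherits, logical(1), "eis_spectrum")))
    stop("`spectra` must be a list of eis_spectrum objects", call. = FALSE)
  sites <- vapply(spectra, `[[`, integer(1), "site")
  if (anyDuplicated(sites))
    stop(sprintf("duplicate site indices for patient %s", patient_id),
         call. = FALSE)
  for (v in list(ci = ci, ref = ref, label = label))
    if (!is.na(v) && !v %in% c(0, 1))
      stop("ci/ref/label must be binary 0/1 or NA", call. = FALSE)
  spectra <- spectra[order(sites)]
  structure(list(patient_id = as.character(patient_id), spectra = spectra,
                 ci = ci, ref = ref, label = label,
                 valid = length(spectra) >= min_sites),
            class = "eis_patient")
}

#' @export
print.eis_patient <- function(x, ...) {
  cat(sprintf("EIS patient %s: %d sites%s, ci=%s ref=%s label=%s\n",
              x$patient_id, length(x$spectra),
              if (x$valid) "" else " (INVALID: <8 sites)",
              format(x$ci), format(x$ref), format(x$label)))
  invisible(x)
}

feature_names <- function() {
  c("rinf_mean", "r0_mean", "fc_mean", "alpha_mean",
    "d_rinf", "d_r0", "d_fc", "d_alpha")
}
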