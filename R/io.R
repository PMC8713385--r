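#' Read multi-site impedance spectra from CSV
#'
#' Reads a long-format (tidy) spectrum table -- one row per patient,
#' site and frequency -- and assembles [eis_patient()] records.  The
#' canonical columns are `patient_id, site, freq_hz, z_re, z_im`;
#' `schema` remaps names, and `polar = TRUE` accepts
#' magnitude/phase-in-degrees columns (`z_mod`, `z_phase_deg`) instead,
#' converting to complex form on read.  An optional covariate table
#' supplies `ci`, `ref` and `label` per patient.
#'
#' Frequencies are matched to the declared grid by nearest point within
#' a relative tolerance of 1e-6 (textual CSVs round).  A site missing
#' any grid frequency is dropped with a warning; a patient left with
#' fewer than `min_sites` sites is kept but flagged invalid.  Sites are
#' never reordered relative to their site index.
#'
#' @param path spectrum CSV path.
#' @param covariates optional covariate CSV path (columns
#'   `patient_id, ci, ref, label`).
#' @param schema named character vector remapping the expected column
#'   names, e.g. `c(freq_hz = "frequency")`.
#' @param polar spectra stored as magnitude/phase (degrees) instead of
#'   real/imaginary.
#' @param grid expected frequency grid.
#' @param min_sites minimum usable sites per patient (default 8).
#' @return List of [eis_patient()] records, ordered by patient id.
#' @export
read_spectra <- function(path, covariates = NULL, schema = character(),
                         polar = FALSE, grid = default_grid(),
                         min_sites = 8L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("patient_id", "site", "freq_hz",
            if (polar) c("z_mod", "z_phase_deg") else c("z_re", "z_im"))
  have <- want
  have[match(names(schema), want, nomatch = 0)] <- schema[names(schema) %in% want]
  missing <- setdiff(have, names(d))
  if (length(missing))
    stop(sprintf("spectrum CSV lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  d <- d[, have]
  names(d) <- want
  for (col in setdiff(want, "patient_id")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column `%s`, data row %d",
                   col, c(bad, which(is.na(v)))[1]), call. = FALSE)
    d[[col]] <- v
  }
  if (polar) {
    ph <- d$z_phase_deg * pi / 180
    d$z_re <- d$z_mod * cos(ph)
    d$z_im <- d$z_mod * sin(ph)
  }
  # snap frequencies onto the declared grid
  idx <- vapply(d$freq_hz, function(f) which.min(abs(grid - f)), integer(1))
  rel <- abs(d$freq_hz - grid[idx]) / grid[idx]
  if (any(rel > 1e-6))
    stop(sprintf("frequency %.6g Hz (data row %d) does not match the declared grid",
                 d$freq_hz[which(rel > 1e-6)[1]], which(rel > 1e-6)[1]),
         call. = FALSE)
  d$grid_idx <- idx

  cov <- NULL
  if (!is.null(covariates)) {
    if (!file.exists(covariates))
      stop(sprintf("file not found: %s", covariates), call. = FALSE)
    cov <- utils::read.csv(covariates, stringsAsFactors = FALSE)
    if (!"patient_id" %in% names(cov))
      stop("covariate CSV needs a patient_id column", call. = FALSE)
    cov$patient_id <- as.character(cov$patient_id)
  }

  records <- list()
  for (pid in sort(unique(as.character(d$patient_id)))) {
    dp <- d[as.character(d$patient_id) == pid, ]
    spectra <- list()
    for (s in sort(unique(dp$site))) {
      ds <- dp[dp$site == s, ]
      ds <- ds[order(ds$grid_idx), ]
      if (nrow(ds) != length(grid) ||
          !identical(ds$grid_idx, seq_along(grid)) ) {
        warning(sprintf("patient %s site %d: incomplete frequency coverage, site dropped",
                        pid, s), call. = FALSE)
        next
      }
      spectra[[length(spectra) + 1L]] <-
        eis_spectrum(grid, complex(real = ds$z_re, imaginary = ds$z_im),
                     site = s)
    }
    ci <- ref <- label <- NA
    if (!is.null(cov) && pid %in% cov$patient_id) {
      row <- cov[match(pid, cov$patient_id), ]
      ci <- row$ci %||% NA; ref <- row$ref %||% NA; label <- row$label %||% NA
    }
    if (length(spectra) == 0L) {
      warning(sprintf("patient %s has no usable sites; record skipped", pid),
              call. = FALSE)
      next
    }
    rec <- eis_patient(pid, spectra, ci = ci, ref = ref, label = label,
                       min_sites = min_sites)
    if (!rec$valid)
      warning(sprintf("patient %s has only %d usable site(s) (<%d); flagged invalid",
                      pid, length(spectra), min_sites), call. = FALSE)
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Write a cohort's spectra to long-format CSV
#'
#' Inverse of [read_spectra()]: columns
#' `patient_id, site, freq_hz, z_re, z_im`.
#'
#' @param records list of [eis_patient()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(records, path) {
  rows <- lapply(records, function(r)
    do.call(rbind, lapply(r$spectra, function(s)
      data.frame(patient_id = r$patient_id, site = s$site,
                 freq_hz = s$freq, z_re = Re(s$z), z_im = Im(s$z),
                 stringsAsFactors = FALSE))))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a covariate/label table for a cohort
#'
#' @param records list of [eis_patient()] objects.
#' @param path output CSV path (columns `patient_id, ci, ref, label`).
#' @return `path`, invisibly.
#' @export
write_covariates <- function(records, path) {
  d <- data.frame(
    patient_id = vapply(records, `[[`, character(1), "patient_id"),
    ci = vapply(records, function(r) as.numeric(r$ci), numeric(1)),
    ref = vapply(records, function(r) as.numeric(r$ref), numeric(1)),
    label = vapply(records, function(r) as.numeric(r$label), numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' One row per patient with the 8 Cole-derived features plus
#' `ci`/`ref`/`label`.  Values are written with full precision so a
#' read-back is value-identical.  Non-finite feature values are refused
#' with an error naming the offending patient.
#'
#' @param features data.frame as from [extract_features_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features))
  fcols <- intersect(feature_names(), names(features))
  if (nrow(features) > 0) {
    bad <- !apply(as.matrix(features[, fcols, drop = FALSE]), 1,
                  function(r) all(is.finite(r)))
    if (any(bad))
      stop(sprintf("non-finite feature value(s) for patient(s): %s",
                   paste(features$patient_id[bad], collapse = ", ")),
           call. = FALSE)
  }
  utils::write.csv(format(features, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("incomplete" %in% names(d)) d$incomplete <- as.logical(d$incomplete)
  d
}

#' Save a fitted logistic classifier as a JSON artifact
#'
#' Stores the basis-term descriptors, coefficients, standard errors,
#' Wald p-values and training metadata (n, deviances, seed) in a
#' plain-text JSON file.
#'
#' @param model an `eis_logit`.
#' @param path output JSON path.
#' @param seed optional RNG seed to record.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "eis_logit"))
  b <- model$basis
  obj <- list(
    type = "eis_logit",
    basis = if (is.null(b)) NULL else list(
      terms = lapply(b$terms, function(tm)
        as.list(stats::setNames(as.numeric(tm), names(tm)))),
      include_ci = b$include_ci, include_ref = b$include_ref),
    coefficients = as.list(model$coefficients),
    se = as.list(model$se),
    p_values = as.list(model$p_values),
    converged = model$converged,
    n = model$n, deviance = model$deviance,
    null_deviance = model$null_deviance,
    seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a logistic classifier saved by [write_model()]
#'
#' @param path JSON path.
#' @return An `eis_logit`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "eis_logit"))
    stop("not an eis_logit model artifact", call. = FALSE)
  basis <- NULL
  if (!is.null(obj$basis)) {
    terms <- lapply(obj$basis$terms, function(tm)
      stats::setNames(as.numeric(unlist(tm)), names(tm)))
    basis <- basis_spec(terms,
                        include_ci = isTRUE(obj$basis$include_ci),
                        include_ref = isTRUE(obj$basis$include_ref))
  }
  model <- logistic_model(basis, unlist(obj$coefficients))
  model$se <- unlist(obj$se)
  model$p_values <- unlist(obj$p_values)
  model$converged <- isTRUE(obj$converged)
  model$n <- obj$n %||% NA_integer_
  model$deviance <- obj$deviance %||% NA_real_
  model$null_deviance <- obj$null_deviance %||% NA_real_
  model
}
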