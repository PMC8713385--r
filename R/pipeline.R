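# End-to-end orchestration: cohort -> Cole fits -> features -> MANOVA
# ranking -> CV structure selection -> final model -> ROC/OOP report.

stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}

load_or_generate <- function(spectra = NULL, covariates = NULL,
                             config = NULL, seed = NULL) {
  if (!is.null(spectra)) {
    if (!file.exists(spectra))
      stage_stop("input", "spectrum file not found: %s", spectra)
    if (!is.null(covariates) && !file.exists(covariates))
      stage_stop("input", "covariate file not found: %s", covariates)
    read_spectra(spectra, covariates = covariates)
  } else if (!is.null(config)) {
    generate_cohort(config, seed = seed)
  } else stage_stop("input", "supply either input files or a cohort config")
}

# Pure-degree polynomial bases over a feature subset, optionally with
# the clinical dummies -- the candidate structures compared by CV.
degree_bases <- function(features, degrees = 1:3, include_ci = FALSE,
                         include_ref = FALSE) {
  lapply(degrees, function(d) {
    terms <- lapply(features, function(f) stats::setNames(d, f))
    basis_spec(terms, include_ci = include_ci, include_ref = include_ref)
  })
}

# Degree-<=2 candidate set over two features u, v: linear, pure
# quadratic, and quadratic with cross term.
quadratic_bases <- function(u, v) {
  list(
    basis_spec(stats::setNames(1, u), stats::setNames(1, v)),
    basis_spec(stats::setNames(2, u), stats::setNames(2, v)),
    basis_spec(stats::setNames(2, u), stats::setNames(c(1, 1), c(u, v)),
               stats::setNames(2, v)))
}

write_cv_report <- function(cv, path) {
  tab <- cbind(repetition = seq_len(nrow(cv$auc)), as.data.frame(cv$auc))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

write_roc_report <- function(roc, path) {
  d <- data.frame(threshold = roc$thresholds,
                  sensitivity = roc$sensitivity,
                  specificity = roc$specificity)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run the diagnosis analysis pipeline
#'
#' End-to-end detection analysis: load or generate a cohort, extract
#' per-patient Cole features, rank feature subsets by MANOVA, compare
#' polynomial logistic structures (degrees 1-3 over the top subset,
#' with clinical dummies) by repeated stratified 2-fold CV on AUC with
#' an asymmetric train/test split, refit the winning structure on the
#' full cohort, and report its coefficients and resubstitution ROC with
#' the Youden operating point.  All outputs are written as plain CSV /
#' JSON into `out_dir` and every seed is recorded.
#'
#' @param spectra,covariates optional input CSV paths (see
#'   [read_spectra()]); when omitted a synthetic cohort is generated
#'   from `config`.
#' @param config a [cohort_config()]; default the `"diagnosis"` preset.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   file output.
#' @param repeats CV repetitions (default 10).
#' @param max_subset_size MANOVA subset-search cap (default 4).
#' @param train_frac training-fold fraction for the asymmetric 2-fold
#'   split (default 1000/1704).
#' @param seed master seed for generation and CV.
#' @return Invisible list bundle: `features`, `ranking`, `cv`, `model`,
#'   `roc`, `selected_features`, `seed`, `files`.
#' @export
run_diagnosis_pipeline <- function(spectra = NULL, covariates = NULL,
                                   config = cohort_preset("diagnosis"),
                                   out_dir = NULL, repeats = 10L,
                                   max_subset_size = 4L,
                                   train_frac = 1000 / 1704, seed = 1L) {
  records <- load_or_generate(spectra, covariates, config, seed)
  features <- tryCatch(extract_features_cohort(records),
                       error = function(e) stage_stop("features",
                                                      conditionMessage(e)))
  features <- features[!features$incomplete, ]
  if (nrow(features) < 20L)
    stage_stop("features", "too few complete feature vectors (%d)",
               nrow(features))
  if (anyNA(features$label))
    stage_stop("features", "outcome labels are required for the analysis")

  ranking <- tryCatch(rank_subsets(features, max_size = max_subset_size),
                      error = function(e) stage_stop("manova",
                                                     conditionMessage(e)))
  top <- strsplit(ranking$subset[1], ",")[[1]]

  n <- nrow(features)
  n_train <- max(2L, min(n - 2L, round(train_frac * n)))
  plan <- cv_plan(k = 2L, repeats = repeats, seed = seed,
                  fold_sizes = c(n_train, n - n_train))
  bases <- degree_bases(top, degrees = 1:3,
                        include_ci = !anyNA(features$ci),
                        include_ref = !anyNA(features$ref))
  cv <- tryCatch(cv_select(features, bases, plan),
                 error = function(e) stage_stop("cv", conditionMessage(e)))
  winner <- cv$bases[[1]]

  model <- tryCatch(fit_logistic(features, basis = winner),
                    error = function(e) stage_stop("final-model",
                                                   conditionMessage(e)))
  roc <- roc_auc(predict_prob(model, features), features$label)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      features = write_features(features, file.path(out_dir, "features.csv")),
      manova = {
        utils::write.csv(as.data.frame(ranking),
                         file.path(out_dir, "manova_ranking.csv"),
                         row.names = FALSE)
        file.path(out_dir, "manova_ranking.csv")
      },
      cv = write_cv_report(cv, file.path(out_dir, "cv_auc.csv")),
      model = write_model(model, file.path(out_dir, "final_model.json"),
                          seed = seed),
      roc = write_roc_report(roc, file.path(out_dir, "roc.csv")),
      summary = {
        jsonlite::write_json(
          list(seed = seed, n_patients = n,
               selected_features = top,
               winning_basis = basis_label(winner),
               cv_mean_auc = cv$table$mean_auc[1],
               resubstitution_auc = roc$auc,
               youden_j = roc$youden_j,
               oop_sensitivity = roc$oop_sensitivity,
               oop_specificity = roc$oop_specificity),
          file.path(out_dir, "summary.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
        file.path(out_dir, "summary.json")
      })
  }
  invisible(list(features = features, ranking = ranking, cv = cv,
                 model = model, roc = roc, selected_features = top,
                 seed = seed, files = files))
}

#' Run the prognosis analysis pipeline
#'
#' Longitudinal analysis of follow-up outcome: as
#' [run_diagnosis_pipeline()] but with repeated stratified 5-fold CV
#' (held-out scores pooled per repetition), candidate structures up to
#' degree 2 including the cross term over the top two ranked features,
#' no clinical dummies, comparison baselines from the raw mean spectra
#' (impedance at 152 Hz; mid-band log-log slope), and -- when the
#' winning structure is the pure quadratic pair -- the semi-axes of its
#' elliptical decision boundary.  A 2-D histogram of the
#' `alpha_mean`-`d_alpha` plane by outcome group is written alongside.
#'
#' @inheritParams run_diagnosis_pipeline
#' @param config a [cohort_config()]; default the `"prognosis"` preset.
#' @param repeats CV repetitions (default 100).
#' @param k folds (default 5).
#' @return Invisible list bundle: `features`, `ranking`, `cv`, `model`,
#'   `roc`, `baselines`, `ellipse`, `hist2d`, `seed`, `files`.
#' @export
run_prognosis_pipeline <- function(spectra = NULL, covariates = NULL,
                                   config = cohort_preset("prognosis"),
                                   out_dir = NULL, repeats = 100L,
                                   k = 5L, max_subset_size = 3L,
                                   seed = 1L) {
  if (is.numeric(repeats) && repeats < 1)
    stage_stop("plan", "`repeats` must be at least 1")
  records <- load_or_generate(spectra, covariates, config, seed)
  features <- tryCatch(extract_features_cohort(records),
                       error = function(e) stage_stop("features",
                                                      conditionMessage(e)))
  features <- features[!features$incomplete, ]
  if (anyNA(features$label))
    stage_stop("features", "outcome labels are required for the analysis")

  ranking <- tryCatch(rank_subsets(features, max_size = max_subset_size),
                      error = function(e) stage_stop("manova",
                                                     conditionMessage(e)))
  # two features to build the low-order structures on: the top-ranked
  # pair if one exists, else the two most frequent features in the top
  # subsets
  pair_rows <- ranking[ranking$size == 2L & !is.na(ranking$p_value), ]
  uv <- if (nrow(pair_rows) > 0) strsplit(pair_rows$subset[1], ",")[[1]]
        else utils::head(strsplit(ranking$subset[1], ",")[[1]], 2L)

  plan <- cv_plan(k = k, repeats = repeats, seed = seed)
  bases <- quadratic_bases(uv[1], uv[2])
  cv <- tryCatch(cv_select(features, bases, plan),
                 error = function(e) stage_stop("cv", conditionMessage(e)))
  winner <- cv$bases[[1]]

  model <- tryCatch(fit_logistic(features, basis = winner),
                    error = function(e) stage_stop("final-model",
                                                   conditionMessage(e)))
  roc <- roc_auc(predict_prob(model, features), features$label)

  keep <- match(features$patient_id,
                vapply(records, `[[`, character(1), "patient_id"))
  baselines <- lapply(c(z_152 = "z_152", slope = "slope"), function(w) {
    sc <- baseline_single_feature(records[keep], which = w)
    # larger |slope| / lower impedance indicate disease; orient scores
    # so AUC >= 0.5 is the informative direction for reporting
    roc_auc(sc, features$label)
  })

  ellipse <- NULL
  cf <- coef(model)
  pure_quad <- setequal(model$basis$labels,
                        c(paste0(uv[1], "^2"), paste0(uv[2], "^2")))
  if (pure_quad) {
    b0 <- cf[["(Intercept)"]]
    b1 <- cf[[paste0(uv[1], "^2")]]; b2 <- cf[[paste0(uv[2], "^2")]]
    if (sign(b1) == sign(b2) && sign(b0) != sign(b1))
      ellipse <- list(features = uv,
                      semi_axis_1 = sqrt(-b0 / b1),
                      semi_axis_2 = sqrt(-b0 / b2))
  }

  brks_a <- pretty(features$alpha_mean, 20)
  brks_d <- pretty(features$d_alpha, 20)
  bin <- function(g) {
    d <- features[features$label == g, ]
    table(cut(d$alpha_mean, brks_a), cut(d$d_alpha, brks_d))
  }
  hist2d <- list(breaks_alpha_mean = brks_a, breaks_d_alpha = brks_d,
                 counts_neg = bin(0), counts_pos = bin(1))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- do.call(rbind, lapply(c(0, 1), function(g) {
      m <- if (g == 0) hist2d$counts_neg else hist2d$counts_pos
      data.frame(label = g, as.data.frame(m, stringsAsFactors = FALSE))
    }))
    names(h) <- c("label", "alpha_mean_bin", "d_alpha_bin", "count")
    files <- c(
      features = write_features(features, file.path(out_dir, "features.csv")),
      manova = {
        utils::write.csv(as.data.frame(ranking),
                         file.path(out_dir, "manova_ranking.csv"),
                         row.names = FALSE)
        file.path(out_dir, "manova_ranking.csv")
      },
      cv = write_cv_report(cv, file.path(out_dir, "cv_auc.csv")),
      model = write_model(model, file.path(out_dir, "final_model.json"),
                          seed = seed),
      roc = write_roc_report(roc, file.path(out_dir, "roc.csv")),
      hist2d = {
        utils::write.csv(h, file.path(out_dir, "hist2d.csv"),
                         row.names = FALSE)
        file.path(out_dir, "hist2d.csv")
      },
      summary = {
        jsonlite::write_json(
          list(seed = seed, n_patients = nrow(features),
               selected_features = uv,
               winning_basis = basis_label(winner),
               cv_mean_auc = cv$table$mean_auc[1],
               resubstitution_auc = roc$auc,
               youden_j = roc$youden_j,
               oop_sensitivity = roc$oop_sensitivity,
               oop_specificity = roc$oop_specificity,
               baseline_auc_z152 = baselines$z_152$auc,
               baseline_auc_slope = baselines$slope$auc,
               ellipse = ellipse),
          file.path(out_dir, "summary.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
        file.path(out_dir, "summary.json")
      })
  }
  invisible(list(features = features, ranking = ranking, cv = cv,
                 model = model, roc = roc, baselines = baselines,
                 ellipse = ellipse, hist2d = hist2d,
                 selected_features = uv, seed = seed, files = files))
}
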