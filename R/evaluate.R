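#' Cross-validation plan
#'
#' Describes a repeated stratified k-fold scheme.  `fold_sizes` allows
#' the asymmetric two-fold train/test split used for large diagnosis
#' cohorts (e.g. 1000/704); when omitted, folds are near-equal.
#'
#' @param k number of folds (>= 2).
#' @param repeats number of repetitions, each with a fresh seeded
#'   permutation (>= 1).
#' @param seed master seed; per-repetition seeds are spawned from it
#'   deterministically.
#' @param fold_sizes optional integer vector of length `k` summing to
#'   the sample size.
#' @return Object of class `"cv_plan"`.
#' @export
cv_plan <- function(k = 5L, repeats = 10L, seed = 1L, fold_sizes = NULL) {
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (is.na(k) || k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (is.na(repeats) || repeats < 1L)
    stop("`repeats` must be at least 1", call. = FALSE)
  if (!is.null(fold_sizes)) {
    fold_sizes <- as.integer(fold_sizes)
    if (length(fold_sizes) != k || any(fold_sizes < 1L))
      stop("`fold_sizes` must be k positive integers", call. = FALSE)
  }
  structure(list(k = k, repeats = repeats, seed = as.integer(seed),
                 fold_sizes = fold_sizes, stratified = TRUE),
            class = "cv_plan")
}

#' Stratified fold assignment
#'
#' Partitions samples into k folds preserving class proportions: within
#' each class, samples are randomly permuted (seeded) and allocated to
#' folds by largest-remainder quotas, so every fold's per-class count
#' deviates from exact proportionality by less than 1.
#'
#' @param labels binary class labels.
#' @param plan a [cv_plan()].
#' @param seed seed for this particular assignment; defaults to the
#'   plan's master seed.
#' @return Integer vector of fold ids in `1..k`.
#' @examples
#' f <- stratified_folds(rep(c(1, 0), c(35, 534)), cv_plan(k = 5, seed = 1))
#' table(f, rep(c(1, 0), c(35, 534)))
#' @export
stratified_folds <- function(labels, plan, seed = plan$seed) {
  stopifnot(inherits(plan, "cv_plan"))
  if (!is_binary(labels)) stop("`labels` must be binary 0/1", call. = FALSE)
  n <- length(labels); k <- plan$k
  sizes <- plan$fold_sizes
  if (is.null(sizes)) {
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  }
  if (sum(sizes) != n)
    stop("fold sizes must sum to the number of samples", call. = FALSE)
  fold <- integer(n)
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(labels == cls)
      nc <- length(idx)
      if (nc < k)
        stop(sprintf("class %s has fewer members (%d) than folds (%d)",
                     cls, nc, k), call. = FALSE)
      idx <- idx[sample.int(nc)]
      target <- nc * sizes / n
      cnt <- floor(target)
      rem <- nc - sum(cnt)
      if (rem > 0) {
        extra <- order(target - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[extra] <- cnt[extra] + 1L
      }
      fold[idx] <- rep(seq_len(k), times = cnt)
    }
  })
  fold
}

#' ROC curve, AUC and Youden operating point
#'
#' Sweeps all distinct score thresholds (classifying positive when
#' `score >= threshold`), computes sensitivity and specificity at each,
#' the area under the curve via the rank (Mann-Whitney) form -- ties
#' count 1/2, so the AUC equals the probability that a random positive
#' outscores a random negative -- and the optimal operating point (OOP)
#' maximizing the Youden index `J = sensitivity + specificity - 1`
#' (smallest threshold on ties).
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels binary outcome (1 = positive).
#' @return Object of class `"eis_roc"`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `youden_j`, `oop_threshold`,
#'   `oop_sensitivity`, `oop_specificity`, class counts, and a
#'   `degenerate` flag (constant scores give AUC 0.5 with a warning).
#' @examples
#' r <- roc_auc(c(.9, .8, .1, .2), c(1, 1, 0, 0))
#' c(r$auc, r$youden_j)
#' @export
roc_auc <- function(scores, labels) {
  if (!is_binary(labels)) stop("`labels` must be binary 0/1", call. = FALSE)
  if (length(scores) != length(labels) || anyNA(scores))
    stop("`scores` must be complete, one per label", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  degenerate <- length(unique(scores)) == 1L
  if (degenerate)
    warning("constant scores: degenerate ROC, AUC = 0.5", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # one ROC point per distinct threshold ("positive" when score >= t),
  # via cumulative class counts over the score-sorted samples
  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]; y_ord <- labels[ord]
  last <- which(!duplicated(s_ord, fromLast = TRUE))
  thr <- c(Inf, s_ord[last])
  sens <- c(0, cumsum(y_ord)[last] / n1)
  spec <- c(1, 1 - cumsum(1 - y_ord)[last] / n0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  oop <- best[which.min(thr[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_j = j[oop], oop_threshold = thr[oop],
                 oop_sensitivity = sens[oop], oop_specificity = spec[oop],
                 n_pos = n1, n_neg = n0, degenerate = degenerate),
            class = "eis_roc")
}

#' @export
print.eis_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d pos / %d neg)\n", x$auc, x$n_pos, x$n_neg))
  cat(sprintf("OOP (max Youden J = %.4f) at threshold %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$youden_j, x$oop_threshold, 100 * x$oop_sensitivity,
              100 * x$oop_specificity))
  invisible(x)
}

#' @export
plot.eis_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::points(1 - x$oop_specificity, x$oop_sensitivity, pch = 19,
                   col = 2)
  invisible(x)
}

#' Select a classifier structure by repeated stratified CV on AUC
#'
#' For each candidate basis and each repetition, re-partitions the data
#' with a fresh seeded permutation, fits the logistic model on the
#' training fold(s) and scores the held-out fold(s).  With `k = 2` the
#' second fold is the designated test fold (supporting the asymmetric
#' train/test split); with `k >= 3` each fold is held out in turn and
#' the held-out scores are pooled into one ROC per repetition (set
#' `pool = FALSE` to average per-fold AUCs instead).  Bases are ranked
#' by mean test AUC; ties go to the basis with fewer terms (parsimony).
#'
#' @param features feature data.frame with a binary `label` column.
#' @param bases list of [basis_spec()] candidates.
#' @param plan a [cv_plan()].
#' @param pool pool held-out scores across folds (default TRUE).
#' @return Object of class `"eis_cv"`: list with `table` (ranked
#'   data.frame of `basis`, `n_terms`, `mean_auc`, `failed`), `auc`
#'   (repeats x bases matrix of per-repetition AUCs), `plan`, `seeds`.
#' @export
cv_select <- function(features, bases, plan, pool = TRUE) {
  stopifnot(is.data.frame(features), is.list(bases),
            inherits(plan, "cv_plan"))
  if (inherits(bases, "basis_spec")) bases <- list(bases)
  if (!all(vapply(bases, inherits, logical(1), "basis_spec")))
    stop("`bases` must be a list of basis_spec objects", call. = FALSE)
  y <- features$label
  if (is.null(y) || anyNA(y)) stop("features need a complete `label` column",
                                   call. = FALSE)
  labels_b <- vapply(bases, basis_label, character(1))
  seeds <- spawn_seeds(plan$seed, plan$repeats)
  auc <- matrix(NA_real_, plan$repeats, length(bases),
                dimnames = list(NULL, labels_b))
  for (r in seq_len(plan$repeats)) {
    fold <- stratified_folds(y, plan, seed = seeds[r])
    for (b in seq_along(bases)) {
      res <- tryCatch({
        if (plan$k == 2L) {
          fit <- fit_logistic(features[fold == 1L, , drop = FALSE],
                              basis = bases[[b]])
          if (!fit$converged) stop("training fit did not converge")
          test <- fold == 2L
          roc_auc(predict_prob(fit, features[test, , drop = FALSE]),
                  y[test])$auc
        } else {
          sc <- rep(NA_real_, length(y))
          per_fold <- numeric(plan$k)
          for (j in seq_len(plan$k)) {
            fit <- fit_logistic(features[fold != j, , drop = FALSE],
                                basis = bases[[b]])
            if (!fit$converged) stop("training fit did not converge")
            sc[fold == j] <-
              predict_prob(fit, features[fold == j, , drop = FALSE])
            if (!pool)
              per_fold[j] <- roc_auc(sc[fold == j], y[fold == j])$auc
          }
          if (pool) roc_auc(sc, y)$auc else mean(per_fold)
        }
      }, error = function(e) NA_real_)
      auc[r, b] <- res
    }
  }
  mean_auc <- colMeans(auc)
  n_terms <- vapply(bases, function(b) length(b$terms), integer(1))
  tab <- data.frame(basis = labels_b, n_terms = n_terms,
                    mean_auc = mean_auc, failed = is.na(mean_auc),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$failed, -ifelse(is.na(tab$mean_auc), -Inf,
                                       tab$mean_auc), tab$n_terms), ]
  rownames(tab) <- NULL
  structure(list(table = tab, auc = auc, plan = plan, seeds = seeds,
                 bases = bases[match(tab$basis, labels_b)]),
            class = "eis_cv")
}

#' @export
print.eis_cv <- function(x, ...) {
  cat(sprintf("Repeated stratified %d-fold CV (%d repetitions, master seed %d)\n",
              x$plan$k, x$plan$repeats, x$plan$seed))
  print(x$table, digits = 4)
  invisible(x)
}

#' Raw-spectrum baseline classifier scores
#'
#' Single-feature scores computed from each patient's mean spectrum,
#' used as comparison baselines for the Cole-feature classifiers:
#' `"z_152"` is the impedance magnitude at the grid frequency nearest
#' 152 Hz; `"slope"` is the slope of log |Z| versus log frequency
#' between the grid points nearest 1.22 and 2.44 kHz (a proxy for the
#' dispersion constant alpha).
#'
#' @param records list of [eis_patient()] objects, or a list of mean
#'   [eis_spectrum()] objects.
#' @param which `"z_152"` or `"slope"`.
#' @return Named numeric score vector, one per patient.
#' @export
baseline_single_feature <- function(records, which = c("z_152", "slope")) {
  which <- match.arg(which)
  stopifnot(is.list(records), length(records) >= 1)
  spectra <- lapply(records, function(r) {
    if (inherits(r, "eis_patient")) mean_spectrum(r$spectra)
    else if (inherits(r, "eis_spectrum")) r
    else stop("`records` must hold eis_patient or eis_spectrum objects",
              call. = FALSE)
  })
  f <- spectra[[1]]$freq
  score_one <- function(sp) {
    if (which == "z_152") {
      if (152 < min(f) || 152 > max(f))
        stop("152 Hz lies outside the frequency grid", call. = FALSE)
      Mod(sp$z)[which.min(abs(f - 152))]
    } else {
      if (1220 < min(f) || 2440 > max(f))
        stop("1.22-2.44 kHz lies outside the frequency grid", call. = FALSE)
      i1 <- which.min(abs(f - 1220)); i2 <- which.min(abs(f - 2440))
      if (i1 == i2) stop("grid cannot resolve 1.22 vs 2.44 kHz", call. = FALSE)
      (log(Mod(sp$z)[i2]) - log(Mod(sp$z)[i1])) / (log(f[i2]) - log(f[i1]))
    }
  }
  out <- vapply(spectra, score_one, numeric(1))
  names(out) <- vapply(records, function(r)
    if (inherits(r, "eis_patient")) r$patient_id else as.character(r$site),
    character(1))
  out
}
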