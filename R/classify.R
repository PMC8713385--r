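#' Specify a polynomial basis for logistic classification
#'
#' A basis is a set of monomial terms in the named features, each term
#' a named vector of positive integer exponents, e.g. `c(r0_mean = 3)`
#' for \eqn{\bar R_0^3} or `c(alpha_mean = 1, d_alpha = 1)` for the
#' cross term \eqn{\bar\alpha\,\Delta\alpha}.  The classifier's linear
#' predictor is then
#' \deqn{a(x) = \beta_0 + \sum_i \beta_i \varphi_i(x)
#'       \,[+\, \beta_{CI} CI + \beta_{Ref} Ref]}
#' with the optional binary clinical dummies appended.
#'
#' @param ... monomial terms (named numeric vectors, total degree <= 3).
#' @param include_ci,include_ref append the clinical dummy covariates.
#' @return Object of class `"basis_spec"`.
#' @examples
#' basis_spec(c(r0_mean = 3), c(alpha_mean = 3), c(d_r0 = 3),
#'            include_ci = TRUE, include_ref = TRUE)
#' @export
basis_spec <- function(..., include_ci = FALSE, include_ref = FALSE) {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1]]) &&
      !is.numeric(terms[[1]])) terms <- terms[[1]]
  if (length(terms) == 0L) stop("basis needs at least one term", call. = FALSE)
  labels <- vapply(terms, function(tm) {
    if (!is.numeric(tm) || is.null(names(tm)) || any(names(tm) == ""))
      stop("each term must be a named numeric vector of exponents",
           call. = FALSE)
    if (any(tm != round(tm)) || any(tm < 1))
      stop("exponents must be positive integers", call. = FALSE)
    if (sum(tm) > 3)
      stop("total degree of a term must not exceed 3", call. = FALSE)
    tm <- tm[order(names(tm))]
    paste(ifelse(tm == 1, names(tm), paste0(names(tm), "^", tm)),
          collapse = "*")
  }, character(1))
  if (anyDuplicated(labels))
    stop("duplicate monomial terms in basis", call. = FALSE)
  structure(list(terms = terms, labels = labels,
                 include_ci = isTRUE(include_ci),
                 include_ref = isTRUE(include_ref)),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("Logistic basis:", basis_label(x), "\n")
  invisible(x)
}

#' Human-readable label of a basis
#' @param basis a [basis_spec()].
#' @return Single string, e.g. `"r0_mean^3 + alpha_mean^3 + d_r0^3 + CI + Ref"`.
#' @export
basis_label <- function(basis) {
  stopifnot(inherits(basis, "basis_spec"))
  paste(c(basis$labels,
          if (basis$include_ci) "CI", if (basis$include_ref) "Ref"),
        collapse = " + ")
}

n_coef <- function(basis) {
  1L + length(basis$terms) + basis$include_ci + basis$include_ref
}

#' Evaluate the design matrix of a basis on a feature table
#'
#' One column per monomial term (product of the named features raised
#' to their exponents), then the intercept column, then the `ci`/`ref`
#' dummy columns when the basis includes them.
#'
#' @param features data.frame with the named feature columns (and
#'   `ci`/`ref` when used).
#' @param basis a [basis_spec()].
#' @return Numeric matrix, `nrow(features)` rows.
#' @export
design_matrix <- function(features, basis) {
  stopifnot(inherits(basis, "basis_spec"), is.data.frame(features))
  need <- unique(c(unlist(lapply(basis$terms, names)),
                   if (basis$include_ci) "ci", if (basis$include_ref) "ref"))
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cols <- lapply(basis$terms, function(tm) {
    v <- rep(1, nrow(features))
    for (nm in names(tm)) v <- v * features[[nm]]^tm[[nm]]
    v
  })
  X <- do.call(cbind, c(cols, list(rep(1, nrow(features)))))
  colnames(X) <- c(basis$labels, "(Intercept)")
  if (basis$include_ci) X <- cbind(X, CI = as.numeric(features$ci))
  if (basis$include_ref) X <- cbind(X, Ref = as.numeric(features$ref))
  if (any(!is.finite(X)))
    stop("design matrix contains non-finite values", call. = FALSE)
  X
}

#' Fit a polynomial-basis logistic regression classifier
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, no penalty) of a binary outcome on the basis-expanded
#' features, with Wald standard errors and p-values from the observed
#' information.  Raw-scale cubic resistance terms span ~10 orders of
#' magnitude, so columns are rescaled internally for the IRLS pass and
#' coefficients are reported back on the raw feature scale.
#'
#' Perfect separation is reported as `converged = FALSE` with a
#' diagnostic rather than an error, so cross-validation loops can skip
#' the offending fold.
#'
#' @param features data.frame of features (or a ready-made design
#'   matrix when `basis` is `NULL`).
#' @param y binary outcome; defaults to `features$label`.
#' @param basis a [basis_spec()] describing the terms.
#' @return Object of class `"eis_logit"` with `coefficients`, `se`,
#'   `p_values` (Wald), `converged`, `separation`, `basis`, deviances
#'   and the fit dimensions.
#' @examples
#' set.seed(1)
#' d <- data.frame(alpha_mean = runif(200), d_alpha = runif(200))
#' a <- -2 + 3 * d$alpha_mean^2 + 2 * d$d_alpha^2
#' d$label <- rbinom(200, 1, plogis(a))
#' fit <- fit_logistic(d, basis = basis_spec(c(alpha_mean = 2), c(d_alpha = 2)))
#' coef(fit)
#' @export
fit_logistic <- function(features, y = NULL, basis = NULL) {
  if (is.null(basis)) {
    X <- as.matrix(features)
    if (!"(Intercept)" %in% colnames(X))
      X <- cbind(X, `(Intercept)` = 1)
  } else {
    X <- design_matrix(features, basis)
  }
  y <- y %||% features$label
  if (is.null(y) || anyNA(y) || !is_binary(y) || length(y) != nrow(X))
    stop("`y` must be binary 0/1 with one entry per row", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome is constant; both classes must be present", call. = FALSE)
  # internal column scaling for IRLS conditioning; dummies/intercept
  # already O(1)
  s <- apply(abs(X), 2, max)
  s[s == 0] <- 1
  Xs <- sweep(X, 2, s, "/")
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs)) {
    bad <- colnames(Xs)[setdiff(seq_len(ncol(Xs)),
                                sort(qx$pivot[seq_len(qx$rank)]))]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(Xs, y, family = stats::binomial(),
                   control = list(maxit = 100, epsilon = 1e-10)))
  # perfect separation <=> the ML deviance is driven to 0 (all fitted
  # probabilities at their labels); coefficients are then meaningless
  separation <- fit$deviance < 1e-6
  converged <- fit$converged && !separation
  w <- fit$weights
  info <- crossprod(Xs * sqrt(w))
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(vc)) {
    se_s <- rep(NA_real_, ncol(Xs))
    converged <- FALSE
  } else se_s <- sqrt(diag(vc))
  beta <- fit$coefficients / s
  se <- se_s / s
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  names(beta) <- names(se) <- names(pval) <- colnames(X)
  structure(list(coefficients = beta, se = se, z = zval, p_values = pval,
                 converged = converged, separation = separation,
                 basis = basis, n = nrow(X),
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 column_names = colnames(X)),
            class = "eis_logit")
}

#' Construct a logistic classifier from fixed coefficients
#'
#' Builds an `eis_logit` object directly from externally given
#' coefficient values (for example a previously published model) so it
#' can be applied to new feature tables with [predict_prob()].
#'
#' @param basis a [basis_spec()].
#' @param coefficients numeric vector in design-matrix column order
#'   (terms, intercept, then CI/Ref when included); may be named.
#' @return An `eis_logit` with `se`/`p_values` set to `NA`.
#' @export
logistic_model <- function(basis, coefficients) {
  stopifnot(inherits(basis, "basis_spec"))
  k <- n_coef(basis)
  if (length(coefficients) != k)
    stop(sprintf("expected %d coefficients for this basis", k), call. = FALSE)
  nm <- c(basis$labels, "(Intercept)",
          if (basis$include_ci) "CI", if (basis$include_ref) "Ref")
  beta <- stats::setNames(as.numeric(coefficients), nm)
  structure(list(coefficients = beta, se = rep(NA_real_, k),
                 z = rep(NA_real_, k), p_values = rep(NA_real_, k),
                 converged = TRUE, separation = FALSE, basis = basis,
                 n = NA_integer_, deviance = NA_real_,
                 null_deviance = NA_real_, column_names = nm),
            class = "eis_logit")
}

#' @export
coef.eis_logit <- function(object, ...) object$coefficients

#' @export
print.eis_logit <- function(x, digits = 5, ...) {
  cat("Polynomial logistic regression",
      if (!is.null(x$basis)) paste0("(", basis_label(x$basis), ")"), "\n")
  print(signif(x$coefficients, digits))
  if (!x$converged)
    cat("WARNING: fit did not converge",
        if (x$separation) "(perfect separation suspected)", "\n")
  invisible(x)
}

#' @export
summary.eis_logit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    z = object$z, p_value = object$p_values)
  structure(list(model = object, table = tab), class = "summary.eis_logit")
}

#' @export
print.summary.eis_logit <- function(x, ...) {
  cat("Polynomial logistic regression",
      if (!is.null(x$model$basis)) paste0("(", basis_label(x$model$basis), ")"),
      "\n")
  stats::printCoefmat(as.matrix(x$table), digits = 5,
                      cs.ind = 1:2, tst.ind = 3, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (!is.na(x$model$deviance))
    cat(sprintf("deviance %.2f (null %.2f), n = %d\n",
                x$model$deviance, x$model$null_deviance, x$model$n))
  invisible(x)
}

#' Predict with a logistic classifier
#'
#' @param object an `eis_logit`.
#' @param features feature data.frame (or design matrix when the model
#'   was fitted without a basis).
#' @param type `"response"` for posterior probabilities
#'   `P = 1/(1 + exp(-a(x)))`, `"link"` for the linear predictor `a(x)`.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.eis_logit <- function(object, features,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (!object$converged)
    warning("predicting from a non-converged model", call. = FALSE)
  X <- if (is.null(object$basis)) {
    X0 <- as.matrix(features)
    if (!"(Intercept)" %in% colnames(X0)) X0 <- cbind(X0, `(Intercept)` = 1)
    X0[, object$column_names, drop = FALSE]
  } else design_matrix(features, object$basis)
  a <- drop(X %*% object$coefficients)
  if (type == "link") a
  else pmin(pmax(stats::plogis(a), 1e-300), 1 - 1e-16)
}

#' Posterior class probability of a logistic classifier
#'
#' Convenience wrapper for `predict(model, features, type = "response")`.
#'
#' @inheritParams predict.eis_logit
#' @param model an `eis_logit`.
#' @return Probabilities strictly inside (0, 1).
#' @export
predict_prob <- function(model, features) {
  predict(model, features, type = "response")
}
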