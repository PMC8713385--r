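#' Two-group MANOVA on a feature subset
#'
#' Tests whether two outcome groups share a common mean vector for the
#' given feature columns, using Wilks' lambda
#' \eqn{\Lambda = |W| / |W + B|} (within- over total-scatter
#' determinant ratio).  With two groups the standard Rao F
#' transformation is exact:
#' \deqn{F = \frac{1-\Lambda}{\Lambda}\,\frac{n-p-1}{p}
#'       \sim F_{p,\,n-p-1}}
#' which in one dimension reduces to the equal-variance two-sample
#' t-test (`F = t^2`).
#'
#' @param x numeric matrix or data.frame, one column per feature in the
#'   subset.
#' @param groups binary (0/1) group labels, one per row of `x`.
#' @return Object of class `"eis_manova"`: a list with `statistic`
#'   (Wilks' lambda), `approx_f`, `df` (numerator, denominator),
#'   `p_value`, `features`, and `dims` (group sizes).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2)
#' g <- rep(0:1, each = 50)
#' manova_test(x, g)$p_value
#' @export
manova_test <- function(x, groups) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  if (!is_binary(groups) || length(groups) != nrow(x))
    stop("`groups` must be binary 0/1 with one entry per row", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  n1 <- sum(groups == 1); n0 <- n - n1
  if (min(n0, n1) < 2) stop("need at least 2 samples per group", call. = FALSE)
  if (p > min(n0, n1) - 1)
    stop("subset dimension exceeds min(group size) - 1", call. = FALSE)
  cn <- colnames(x) %||% paste0("x", seq_len(p))
  # flag exactly collinear / zero-variance columns before forming determinants
  ctr <- scale(x, scale = FALSE)
  qx <- qr(ctr)
  if (qx$rank < p) {
    bad <- cn[setdiff(seq_len(p), sort(qx$pivot[seq_len(qx$rank)]))]
    stop(sprintf("singular pooled covariance; collinear or constant feature(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  w <- crossprod(scale(x[groups == 0, , drop = FALSE], scale = FALSE)) +
       crossprod(scale(x[groups == 1, , drop = FALSE], scale = FALSE))
  t_tot <- crossprod(ctr)
  lambda <- det(w) / det(t_tot)
  if (!is.finite(lambda) || lambda <= 0)
    stop(sprintf("singular pooled covariance over features: %s",
                 paste(cn, collapse = ", ")), call. = FALSE)
  f_stat <- (1 - lambda) / lambda * (n - p - 1) / p
  p_value <- stats::pf(f_stat, p, n - p - 1, lower.tail = FALSE)
  structure(list(statistic = lambda, approx_f = f_stat,
                 df = c(p, n - p - 1), p_value = p_value,
                 features = cn, dims = c(n0 = n0, n1 = n1)),
            class = "eis_manova")
}

#' @export
print.eis_manova <- function(x, ...) {
  cat(sprintf("Two-group MANOVA on {%s}: Wilks' lambda = %.5f, F(%d,%d) = %.4g, p = %.4g\n",
              paste(x$features, collapse = ", "), x$statistic,
              x$df[1], x$df[2], x$approx_f, x$p_value))
  invisible(x)
}

#' Rank feature subsets by MANOVA separation
#'
#' Exhaustively enumerates all non-empty subsets of the given feature
#' columns up to `max_size`, tests each with [manova_test()], and
#' returns them in ascending p-value order.  Raw p-values are reported
#' (no multiplicity correction); the number of subsets tested is
#' recorded so readers can judge the ranking accordingly.  Subsets
#' whose test fails (e.g. collinearity) are ranked last with the error
#' message as `note`.
#'
#' @param features data.frame containing the feature columns and a
#'   binary outcome column.
#' @param groups binary labels; defaults to `features$label`.
#' @param columns feature columns to search over (default: the 8
#'   standard EIS features present in `features`).
#' @param max_size largest subset size to enumerate (default 4).
#' @return `data.frame` of class `"eis_manova_ranking"` with columns
#'   `subset`, `size`, `wilks`, `approx_f`, `p_value`, `note`, ordered
#'   by `p_value`; attribute `n_tested` carries the number of subsets.
#' @export
rank_subsets <- function(features, groups = features$label,
                         columns = intersect(feature_names(), names(features)),
                         max_size = 4L) {
  stopifnot(is.data.frame(features), length(columns) >= 1)
  max_size <- min(as.integer(max_size), length(columns))
  if (max_size < 1L) stop("`max_size` must be at least 1", call. = FALSE)
  subsets <- unlist(lapply(seq_len(max_size), function(k)
    utils::combn(columns, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    res <- tryCatch(manova_test(features[, s, drop = FALSE], groups),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(subset = paste(s, collapse = ","), size = length(s),
                 wilks = NA_real_, approx_f = NA_real_, p_value = NA_real_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(subset = paste(s, collapse = ","), size = length(s),
                 wilks = res$statistic, approx_f = res$approx_f,
                 p_value = res$p_value, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$p_value), out$p_value, out$size), ]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(subsets)
  class(out) <- c("eis_manova_ranking", "data.frame")
  out
}

#' @export
print.eis_manova_ranking <- function(x, top = 10L, ...) {
  cat(sprintf("MANOVA feature-subset ranking (%d subsets tested, raw p-values)\n",
              attr(x, "n_tested")))
  print.data.frame(utils::head(x, top), digits = 4)
  invisible(x)
}
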