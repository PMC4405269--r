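#' Squared Mahalanobis distances from the multivariate mean
#'
#' \eqn{m_i^2 = (y_i - \hat\mu)' S^{-1} (y_i - \hat\mu)} with the sample mean
#' and the (n-1)-denominator sample covariance as plug-in estimates. The
#' distances are invariant under any invertible affine transformation of `Y`
#' and satisfy the exact trace identity \eqn{\sum_i m_i^2 = (n-1) d}.
#'
#' @param Y Numeric matrix, individuals x phenotypes, `n > d`.
#' @return Vector of squared distances, one per individual.
#' @export
mahalanobis_distances <- function(Y) {
  Y <- as_pheno_matrix(Y)
  n <- nrow(Y)
  d <- ncol(Y)
  if (n <= d) stop("need more individuals than phenotypes (n > d)", call. = FALSE)
  S <- stats::cov(Y)
  if (kappa(S, exact = FALSE) > 1e12) {
    stop("sample covariance is singular or near-singular; consider removing ",
         "collinear phenotypes", call. = FALSE)
  }
  stats::mahalanobis(Y, colMeans(Y), S)
}

#' Multivariate-normality outlier detection
#'
#' Under multivariate normality the squared Mahalanobis distance of each
#' individual is approximately chi-squared with `d` degrees of freedom; each
#' individual gets the upper-tail p-value and is flagged when `p < threshold`
#' (strict inequality). Estimation uses the full sample once, with no
#' iterative re-estimation after removal.
#'
#' @param Y Numeric matrix, individuals x phenotypes.
#' @param threshold Significance level for flagging (default 0.01).
#' @param ids Optional individual identifiers (default rownames or indices).
#' @return An object of class `"outlier_report"`: data frame with columns
#'   `id`, `m2`, `pvalue`, `flagged`, plus attributes `threshold` and `d`.
#' @examples
#' set.seed(2)
#' Y <- matrix(rnorm(600), 200, 3)
#' rep <- mahalanobis_outliers(Y)
#' sum(rep$flagged)  # about 1% of 200 under the null
#' @export
mahalanobis_outliers <- function(Y, threshold = 0.01, ids = NULL) {
  Y <- as_pheno_matrix(Y)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  m2 <- mahalanobis_distances(Y)
  d <- ncol(Y)
  p <- stats::pchisq(m2, df = d, lower.tail = FALSE)
  if (is.null(ids)) ids <- rownames(Y)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Y)))
  out <- data.frame(id = ids, m2 = m2, pvalue = p, flagged = p < threshold,
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "d") <- d
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Multivariate outlier report: %d of %d individuals flagged at p < %g (chi^2 df = %d)\n",
              sum(x$flagged), nrow(x), attr(x, "threshold"), attr(x, "d")))
  if (any(x$flagged)) {
    print.data.frame(x[x$flagged, , drop = FALSE], row.names = FALSE)
  }
  invisible(x)
}
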