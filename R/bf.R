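# Closed-form partition Bayes factors under the multivariate normal model.
#
# For a partition (U, D, I) the joint density factorizes as
# P(Y_U) P(Y_D | Y_U, g) P(Y_I | Y_U, Y_D), and only the middle term depends
# on g, so BF reduces to a Bayesian multivariate regression BF of Y_D on g
# with covariates W = [1, Y_U]. With prior b | Sigma ~ N(0, sigma_a^2 Sigma)
# on the genotype effect row and scale-invariant prior on Sigma,
#
#   log BF = -(|D|/2) log(1 + sigma_a^2 gg) - (nu/2) [log det R1 - log det R0]
#
# where gg = g'M_W g, R0 = Y_D' M_W Y_D, R1 = R0 - c u u', u = Y_D' M_W g,
# c = sigma_a^2 / (1 + sigma_a^2 gg), nu = n - ncol(W). Everything is a
# Schur complement of the cross-product matrix of [1, Y, g], so per-SNP cost
# is independent of n after an O(n d^2) precomputation.

# residual cross-products of columns r_idx given columns w_idx
schur_complement <- function(C, w_idx, r_idx) {
  Cww <- C[w_idx, w_idx, drop = FALSE]
  Cwr <- C[w_idx, r_idx, drop = FALSE]
  ch <- tryCatch(chol(Cww), error = function(e) {
    stop("covariate/conditioning block is singular (collinear phenotypes ",
         "or constant columns)", call. = FALSE)
  })
  C[r_idx, r_idx, drop = FALSE] - crossprod(backsolve(ch, Cwr, transpose = TRUE))
}

# natural-log BF for one (U, D) at each sigma_a, from the Schur complement S
# whose last row/column is the genotype; d_idx indexes Y_D within S
log_bf_from_schur <- function(S, d_idx, nu, sigma_a) {
  p <- nrow(S)
  sgg <- S[p, p]
  if (sgg <= 0) stop("genotype has zero residual variance", call. = FALSE)
  R0 <- S[d_idx, d_idx, drop = FALSE]
  u <- S[d_idx, p]
  ch <- tryCatch(chol(R0), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) <= 1e-7 * max(diag(ch))) {
    stop("residual phenotype cross-product matrix is singular; remove ",
         "collinear phenotypes", call. = FALSE)
  }
  quad <- sum(backsolve(ch, u, transpose = TRUE)^2)  # u' R0^-1 u <= sgg
  k <- length(d_idx)
  t2 <- sigma_a^2
  cc <- t2 / (1 + t2 * sgg)
  -(k / 2) * log1p(t2 * sgg) - (nu / 2) * log1p(-cc * quad)
}

#' Log Bayes factor of one phenotype partition
#'
#' Evidence for the alternative model indexed by `partition` against the null
#' of no association, from a multivariate normal model for the phenotypes.
#' Phenotypes in `"D"` are regressed on the (centered) dosage with phenotypes
#' in `"U"` as covariates; phenotypes in `"I"` do not enter the computation
#' (their conditional term cancels between numerator and denominator).
#'
#' @param Y Numeric matrix, individuals x phenotypes, complete cases.
#' @param g Dosage vector in `[0, 2]`, one entry per individual.
#' @param partition Character vector over `"U"`, `"D"`, `"I"` (one per
#'   phenotype); must contain at least one `"D"`.
#' @param sigma_a Prior scale(s) of the genetic effect, per allele copy in
#'   residual-SD units. May be a vector; one log BF is returned per value.
#' @return `log10` Bayes factor(s), one per `sigma_a` value.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(200), 100, 2)
#' g <- rbinom(100, 2, 0.3)
#' log_bf_partition(Y, g, c("D", "U"), sigma_a = 0.2)
#' @seealso [mvbf()], [log_bf_univariate()], [log_bf_all()]
#' @export
log_bf_partition <- function(Y, g, partition, sigma_a) {
  Y <- as_pheno_matrix(Y)
  n <- nrow(Y)
  d <- ncol(Y)
  g <- check_dosage(g, n)
  partition <- validate_partition(partition, d)
  if (any(sigma_a <= 0)) stop("`sigma_a` must be positive", call. = FALSE)
  U <- which(partition == "U")
  D <- which(partition == "D")
  if (n <= length(U) + length(D) + 2) {
    stop("too few individuals for this partition (need n > |U| + |D| + 2)",
         call. = FALSE)
  }
  C <- crossprod(cbind(1, Y, g - mean(g)))
  S <- schur_complement(C, c(1L, 1L + U), c(1L + D, d + 2L))
  nu <- n - 1L - length(U)
  vapply(sigma_a, function(s) log_bf_from_schur(S, seq_along(D), nu, s),
         numeric(1)) / log(10)
}

#' Univariate log Bayes factor
#'
#' The single-phenotype special case of [log_bf_partition()]: `d = 1`, the
#' phenotype directly associated, intercept-only covariate.
#'
#' @param y Numeric phenotype vector.
#' @inheritParams log_bf_partition
#' @return `log10` Bayes factor(s), one per `sigma_a` value.
#' @export
log_bf_univariate <- function(y, g, sigma_a) {
  log_bf_partition(matrix(as.numeric(y), ncol = 1), g, "D", sigma_a)
}

#' Log Bayes factor with all phenotypes directly associated
#'
#' The partition with every phenotype in `D` and `U` empty; the analogue of a
#' standard multivariate (MANOVA-like) test of association.
#'
#' @inheritParams log_bf_partition
#' @return `log10` Bayes factor(s), one per `sigma_a` value.
#' @export
log_bf_all <- function(Y, g, sigma_a) {
  Y <- as_pheno_matrix(Y)
  log_bf_partition(Y, g, rep("D", ncol(Y)), sigma_a)
}
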