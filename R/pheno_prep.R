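#' Quantile transform to standard normal scores
#'
#' Replaces each observation by the normal score of its rank:
#' \eqn{\Phi^{-1}(r / (n + 1))} with 1-based midranks (average ranks for
#' ties). The `r/(n+1)` convention avoids infinite scores at the extremes and
#' is symmetric, so the output has mean exactly 0 for tie-free input.
#'
#' @param x Numeric vector, length at least 2, no missing values.
#' @return Numeric vector of normal scores, a strictly increasing function of
#'   the ranks of `x`.
#' @examples
#' quantile_transform(c(5.1, 2.3, 9.9))  # 0, -0.674, 0.674
#' @export
quantile_transform <- function(x) {
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations to rank", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("all values identical: quantile transform is undefined", call. = FALSE)
  }
  stats::qnorm(rank(x, ties.method = "average") / (n + 1))
}

check_aligned <- function(pre, post) {
  if (!identical(dim(pre), dim(post)) ||
      !identical(colnames(pre), colnames(post))) {
    stop("pre and post matrices must have identical individuals and ",
         "phenotype labels", call. = FALSE)
  }
}

per_stratum <- function(stratum, n) {
  stratum <- as.character(stratum)
  if (length(stratum) != n) {
    stop("`stratum` must have one label per individual", call. = FALSE)
  }
  split(seq_len(n), stratum)
}

#' Average and difference phenotypes from a treatment pair
#'
#' Within each stratum and phenotype, the pre-treatment (`P`) and
#' post-treatment (`T`) measurements are independently quantile transformed
#' to standard normal scores; then the average `A = (T + P)/2` and the
#' difference `D = T - P` are formed elementwise. `A` targets associations
#' present in both visits; `D` targets treatment response (a genotype whose
#' standardized effect differs between visits).
#'
#' @param pre,post Numeric matrices (individuals x phenotypes), aligned on
#'   individuals and phenotype labels.
#' @param stratum Stratum label per individual; transforms are applied within
#'   stratum (each stratum needs at least 2 individuals).
#' @return A list with matrices `A` and `D`.
#' @export
build_average_difference <- function(pre, post, stratum) {
  pre <- as_pheno_matrix(pre, "pre")
  post <- as_pheno_matrix(post, "post")
  check_aligned(pre, post)
  idx <- per_stratum(stratum, nrow(pre))
  if (any(lengths(idx) < 2)) {
    stop("every stratum needs at least 2 individuals", call. = FALSE)
  }
  P <- pre
  T_ <- post
  for (ii in idx) {
    P[ii, ] <- apply(pre[ii, , drop = FALSE], 2, quantile_transform)
    T_[ii, ] <- apply(post[ii, , drop = FALSE], 2, quantile_transform)
  }
  list(A = (T_ + P) / 2, D = T_ - P)
}

#' Per-stratum covariate adjustment by linear regression
#'
#' Within each stratum, regresses the values on an intercept plus the given
#' covariates and returns the residuals. Residuals are orthogonal to the
#' intercept and every covariate column within each stratum.
#'
#' @param values Numeric vector or matrix (columns adjusted independently).
#' @param covariates Data frame or matrix of numeric covariates (e.g. age,
#'   log-BMI, sex and smoking coded 0/1). May have zero columns, in which
#'   case values are centered per stratum.
#' @param stratum Stratum label per individual.
#' @return Residuals with the same shape as `values`.
#' @export
covariate_adjust <- function(values, covariates, stratum) {
  vec_in <- is.null(dim(values))
  V <- if (vec_in) matrix(as.numeric(values), ncol = 1) else as.matrix(values)
  if (anyNA(V)) stop("missing phenotype values", call. = FALSE)
  X <- if (is.null(covariates) || NCOL(covariates) == 0) {
    matrix(numeric(0), nrow(V), 0)
  } else {
    as.matrix(as.data.frame(covariates))
  }
  if (anyNA(X)) {
    stop("missing covariate values are not allowed; supply complete cases",
         call. = FALSE)
  }
  idx <- per_stratum(stratum, nrow(V))
  out <- V
  for (s in names(idx)) {
    ii <- idx[[s]]
    Xs <- cbind(`(Intercept)` = 1, X[ii, , drop = FALSE])
    qr_s <- qr(Xs)
    if (qr_s$rank < ncol(Xs)) {
      stop(sprintf("rank-deficient covariate design in stratum '%s'", s),
           call. = FALSE)
    }
    out[ii, ] <- qr.resid(qr_s, V[ii, , drop = FALSE])
  }
  if (vec_in) drop(out) else out
}

#' Normalization pipeline for pre/post treatment phenotypes
#'
#' End-to-end preparation of analysis phenotypes from a raw trial table, in
#' exactly this order, each stage within stratum:
#' \enumerate{
#'   \item quantile transform the pre- and post-treatment measurements of
#'     each phenotype to standard normal scores;
#'   \item form the average `A = (T + P)/2` and difference `D = T - P`;
#'   \item regress `A` and `D` on the covariates (age, log(BMI), sex,
#'     smoking) and keep residuals `A'`, `D'`;
#'   \item quantile transform `A'` and `D'` again, yielding the final
#'     analysis phenotypes `A~` and `D~`.
#' }
#' Within each stratum every output column is therefore an exact permutation
#' of the normal-score set \eqn{\Phi^{-1}(r/(n_s+1))}, and the whole pipeline
#' is invariant to strictly increasing transformations of the raw inputs.
#'
#' @param raw Data frame with columns `id`, `stratum`, the covariates
#'   (default `age`, `bmi`, `sex`, `smoking`; BMI is log-transformed before
#'   regression), and one `<pheno>_pre` and `<pheno>_post` column per
#'   phenotype, as written by [simulate_trial()] / [write_phenotypes()].
#' @param phenotypes Optional character vector of phenotype labels; by
#'   default inferred from the `_pre`/`_post` column pairs.
#' @param covariates Character vector of covariate column names. `bmi`, if
#'   present, enters as `log(bmi)`.
#' @return An object of class `"prepped_phenotypes"`: list with matrices
#'   `A` and `D` (individuals x phenotypes, rownames = ids), plus `id`,
#'   `stratum`, `phenotypes` and a per-stratum `n` table.
#' @examples
#' tr <- simulate_trial(truth_spec(n = 120, d = 3, seed = 1))
#' pp <- prepare_phenotypes(tr$pheno)
#' sort(pp$A[pp$stratum == pp$stratum[1], 1])  # exact normal scores
#' @seealso [quantile_transform()], [covariate_adjust()]
#' @export
prepare_phenotypes <- function(raw, phenotypes = NULL,
                               covariates = c("age", "bmi", "sex", "smoking")) {
  raw <- as.data.frame(raw)
  need <- c("id", "stratum")
  if (!all(need %in% names(raw))) {
    stop("`raw` must contain columns 'id' and 'stratum'", call. = FALSE)
  }
  if (is.null(phenotypes)) {
    pre_cols <- grep("_pre$", names(raw), value = TRUE)
    phenotypes <- sub("_pre$", "", pre_cols)
    if (!length(phenotypes)) stop("no '<pheno>_pre' columns found", call. = FALSE)
  }
  miss <- setdiff(c(paste0(phenotypes, "_pre"), paste0(phenotypes, "_post")),
                  names(raw))
  if (length(miss)) {
    stop("missing phenotype columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  covariates <- intersect(covariates, names(raw))
  P <- as.matrix(raw[paste0(phenotypes, "_pre")])
  T_ <- as.matrix(raw[paste0(phenotypes, "_post")])
  colnames(P) <- colnames(T_) <- phenotypes
  if (anyNA(P) || anyNA(T_)) {
    stop("missing phenotype measurements; the pipeline requires complete cases",
         call. = FALSE)
  }
  X <- raw[covariates]
  if ("bmi" %in% names(X)) {
    if (any(X$bmi <= 0)) stop("BMI must be positive to log-transform", call. = FALSE)
    X$bmi <- log(X$bmi)
    names(X)[names(X) == "bmi"] <- "log_bmi"
  }
  stratum <- as.character(raw$stratum)

  ad <- build_average_difference(P, T_, stratum)              # stages 1-2
  A2 <- covariate_adjust(ad$A, X, stratum)                    # stage 3
  D2 <- covariate_adjust(ad$D, X, stratum)
  idx <- per_stratum(stratum, nrow(P))
  for (ii in idx) {                                           # stage 4
    A2[ii, ] <- apply(A2[ii, , drop = FALSE], 2, quantile_transform)
    D2[ii, ] <- apply(D2[ii, , drop = FALSE], 2, quantile_transform)
  }
  rownames(A2) <- rownames(D2) <- as.character(raw$id)
  structure(list(A = A2, D = D2, id = as.character(raw$id), stratum = stratum,
                 phenotypes = phenotypes,
                 n_stratum = vapply(idx, length, integer(1))),
            class = "prepped_phenotypes")
}

#' @export
print.prepped_phenotypes <- function(x, ...) {
  cat("Normalized analysis phenotypes (A~ = average, D~ = difference)\n")
  cat(sprintf("  %d individuals, %d phenotypes, %d strata\n",
              nrow(x$A), length(x$phenotypes), length(x$n_stratum)))
  cat("  per-stratum n:", paste(sprintf("%s=%d", names(x$n_stratum),
                                        x$n_stratum), collapse = ", "), "\n")
  invisible(x)
}
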