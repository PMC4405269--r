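# internal numerical and plumbing helpers

# log(sum(exp(x))) without overflow; returns -Inf for empty input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. seed = NULL runs in the
# current stream (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# coerce phenotype input (matrix or data.frame of numeric columns) to a
# numeric matrix with column names, refusing missing values
as_pheno_matrix <- function(Y, arg = "Y") {
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  if (!is.matrix(Y) || !is.numeric(Y)) {
    stop(sprintf("`%s` must be a numeric matrix (individuals x phenotypes)", arg),
         call. = FALSE)
  }
  if (anyNA(Y)) {
    stop(sprintf("`%s` contains missing values; phenotypes must be complete cases", arg),
         call. = FALSE)
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  Y
}

check_dosage <- function(g, n = NULL, arg = "g") {
  g <- as.numeric(g)
  if (anyNA(g)) {
    mu <- mean(g, na.rm = TRUE)
    g[is.na(g)] <- mu
    warning(sprintf("missing dosages in `%s` mean-imputed", arg), call. = FALSE)
  }
  if (any(g < -1e-8 | g > 2 + 1e-8)) {
    stop(sprintf("`%s` must contain dosages in [0, 2]", arg), call. = FALSE)
  }
  if (!is.null(n) && length(g) != n) {
    stop(sprintf("`%s` has length %d but %d individuals are expected",
                 arg, length(g), n), call. = FALSE)
  }
  if (stats::var(g) == 0) {
    stop(sprintf("`%s` is monomorphic (zero variance); cannot test association", arg),
         call. = FALSE)
  }
  g
}
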