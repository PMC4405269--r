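#' Ground-truth specification for a synthetic statin trial
#'
#' Collects every generating parameter of the synthetic-trial generator:
#' design (strata and sizes), a SNP (allele frequency), the generating
#' phenotype partition with its effects, the residual correlation among
#' phenotypes, raw-scale stratum means/SDs, treatment effects, covariate
#' effects and the RNG seed. [simulate_trial()] consumes this object; keeping
#' the truth alongside the data makes every downstream stage testable.
#'
#' Generative model (per individual, in standardized units):
#' phenotypes in `U` are pure residual noise, phenotypes in `D` receive
#' `(g - 2 maf) * beta_direct`, and phenotypes in `I` are built from the `D`
#' phenotypes through `indirect_loadings` plus residual noise, so they are
#' associated with the SNP but conditionally independent of it given the `D`
#' phenotypes. Pre- and post-treatment residuals share a between-visit
#' correlation `visit_cor`; the post-treatment visit additionally receives
#' the raw-scale `treatment_shift` and the standardized genotype-by-treatment
#' effect `response_beta`. Genetic and covariate contributions are centered,
#' so `mean_pre` / `mean_pre + treatment_shift` are exact raw-scale targets.
#'
#' @param n Total number of individuals (split equally over `strata` labels
#'   when `strata` is a character vector).
#' @param d Number of phenotypes (ignored when `phenotypes` given).
#' @param phenotypes Phenotype labels (default `Y1..Yd`).
#' @param strata Either a character vector of stratum labels (sizes split
#'   from `n`) or a data frame with columns `label` and `n`.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param partition Generating partition: character vector over
#'   `"U"`, `"D"`, `"I"` of length `d` (default all `"U"`, a null SNP).
#' @param beta_direct Effect per allele copy on each `D` phenotype, in
#'   residual-SD units (length = number of `D` phenotypes).
#' @param indirect_loadings Matrix (|D| x |I|) mapping `D` phenotypes to `I`
#'   phenotypes; scalar allowed when |D| = |I| = 1.
#' @param sigma d x d positive-definite residual correlation among the
#'   phenotypes; default AR(1) with lag correlation 0.4.
#' @param mean_pre,sd_pre Raw-scale pre-treatment mean/SD per phenotype:
#'   either length-d vectors (shared by strata) or d x S matrices.
#' @param treatment_shift Raw-scale mean change under treatment (post minus
#'   pre), length-d vector or d x S matrix; default 0.
#' @param sd_post Raw-scale post-treatment SD; default `sd_pre`.
#' @param response_beta Standardized genotype x treatment interaction effect
#'   per phenotype (length d, default 0): the post-treatment standardized
#'   effect is `beta + response_beta`.
#' @param covariate_effects Optional list with any of `age`, `log_bmi`,
#'   `sex`, `smoking`, each a length-d vector of effects (per SD of the
#'   continuous covariates, per unit of the 0/1 ones) on the standardized
#'   phenotypes.
#' @param covariate_params Optional data frame (one row per stratum) with
#'   columns `age_mean`, `age_sd`, `bmi_meanlog`, `bmi_sdlog`, `p_male`,
#'   `p_smoke` controlling the covariate distributions.
#' @param visit_cor Between-visit residual correlation in (-1, 1);
#'   default 0.7.
#' @param dosage_noise Half-width of uniform noise added to the integer
#'   dosages (then clamped to `[0, 2]`) to mimic imputed dosages; default 0.
#' @param seed Integer RNG seed stored with the truth.
#' @return An object of class `"truth_spec"`.
#' @examples
#' ts <- truth_spec(n = 500, d = 4, partition = c("D", "I", "U", "U"),
#'                  beta_direct = 0.3, indirect_loadings = 0.8, seed = 1)
#' tr <- simulate_trial(ts)
#' head(tr$pheno)
#' @seealso [simulate_trial()], [truth_spec_table1()]
#' @export
truth_spec <- function(n = 1000, d = 4, phenotypes = NULL, strata = "s1",
                       maf = 0.3, partition = NULL,
                       beta_direct = numeric(0), indirect_loadings = NULL,
                       sigma = NULL, mean_pre = NULL, sd_pre = NULL,
                       treatment_shift = NULL, sd_post = NULL,
                       response_beta = NULL, covariate_effects = NULL,
                       covariate_params = NULL, visit_cor = 0.7,
                       dosage_noise = 0, seed = NULL) {
  if (!is.null(phenotypes)) d <- length(phenotypes)
  else phenotypes <- paste0("Y", seq_len(d))
  if (is.data.frame(strata)) {
    if (!all(c("label", "n") %in% names(strata))) {
      stop("`strata` data frame needs columns 'label' and 'n'", call. = FALSE)
    }
    strata <- data.frame(label = as.character(strata$label),
                         n = as.integer(strata$n))
  } else {
    labs <- as.character(strata)
    sizes <- rep(floor(n / length(labs)), length(labs))
    sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1L
    strata <- data.frame(label = labs, n = sizes)
  }
  if (any(strata$n < 2)) stop("each stratum needs n >= 2", call. = FALSE)
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf > 0.5) {
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  }
  if (is.null(partition)) partition <- rep("U", d)
  partition <- as.character(partition)
  if (length(partition) != d || !all(partition %in% c("U", "D", "I"))) {
    stop('`partition` must be a length-d vector over "U", "D", "I"',
         call. = FALSE)
  }
  nD <- sum(partition == "D")
  nI <- sum(partition == "I")
  if (nI > 0 && nD == 0) {
    stop("indirect phenotypes require at least one direct phenotype",
         call. = FALSE)
  }
  if (length(beta_direct) == 1 && nD > 1) beta_direct <- rep(beta_direct, nD)
  if (length(beta_direct) != nD) {
    stop(sprintf("`beta_direct` must have one entry per D phenotype (%d)", nD),
         call. = FALSE)
  }
  if (nI > 0) {
    if (is.null(indirect_loadings)) {
      stop("`indirect_loadings` required when the partition has I phenotypes",
           call. = FALSE)
    }
    indirect_loadings <- matrix(as.numeric(indirect_loadings), nD, nI)
  } else indirect_loadings <- matrix(numeric(0), nD, 0)
  if (is.null(sigma)) sigma <- 0.4^abs(outer(seq_len(d), seq_len(d), "-"))
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma))) ||
      min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("`sigma` must be symmetric positive definite", call. = FALSE)
  }
  if (nrow(sigma) != d) stop("`sigma` must be d x d", call. = FALSE)

  S <- nrow(strata)
  expand_dS <- function(x, default, name) {
    if (is.null(x)) x <- default
    if (is.null(dim(x))) {
      if (length(x) == 1) x <- rep(x, d)
      if (length(x) != d) stop(sprintf("`%s` must have length d", name),
                               call. = FALSE)
      x <- matrix(x, d, S)
    }
    x <- as.matrix(x)
    if (!all(dim(x) == c(d, S))) {
      stop(sprintf("`%s` must be a d x n_strata matrix", name), call. = FALSE)
    }
    rownames(x) <- phenotypes
    colnames(x) <- strata$label
    x
  }
  mean_pre <- expand_dS(mean_pre, 0, "mean_pre")
  sd_pre <- expand_dS(sd_pre, 1, "sd_pre")
  if (any(sd_pre <= 0)) stop("`sd_pre` must be positive", call. = FALSE)
  treatment_shift <- expand_dS(treatment_shift, 0, "treatment_shift")
  sd_post <- expand_dS(sd_post, sd_pre, "sd_post")
  if (any(sd_post <= 0)) stop("`sd_post` must be positive", call. = FALSE)
  if (is.null(response_beta)) response_beta <- rep(0, d)
  if (length(response_beta) == 1) response_beta <- rep(response_beta, d)
  if (length(response_beta) != d) {
    stop("`response_beta` must have length d", call. = FALSE)
  }
  if (is.null(covariate_params)) {
    covariate_params <- data.frame(age_mean = rep(55, S), age_sd = 12,
                                   bmi_meanlog = log(28), bmi_sdlog = 0.18,
                                   p_male = 0.65, p_smoke = 0.135)
  }
  if (nrow(covariate_params) == 1 && S > 1) {
    covariate_params <- covariate_params[rep(1, S), , drop = FALSE]
  }
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects),
                   c("age", "log_bmi", "sex", "smoking"))
    if (length(bad)) stop("unknown covariate effects: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    covariate_effects <- lapply(covariate_effects, function(v) {
      if (length(v) == 1) v <- rep(v, d)
      if (length(v) != d) stop("covariate effect vectors must have length d",
                               call. = FALSE)
      v
    })
  }
  if (abs(visit_cor) >= 1) stop("`visit_cor` must be in (-1, 1)", call. = FALSE)
  structure(list(
    phenotypes = phenotypes, d = d, strata = strata, maf = maf,
    partition = partition, beta_direct = beta_direct,
    indirect_loadings = indirect_loadings, sigma = sigma,
    mean_pre = mean_pre, sd_pre = sd_pre, treatment_shift = treatment_shift,
    sd_post = sd_post, response_beta = response_beta,
    covariate_effects = covariate_effects, covariate_params = covariate_params,
    visit_cor = visit_cor, dosage_noise = dosage_noise, seed = seed
  ), class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat("Synthetic statin-trial truth specification\n")
  cat(sprintf("  %d individuals in %d strata, %d phenotypes, MAF %.3g\n",
              sum(x$strata$n), nrow(x$strata), x$d, x$maf))
  cat("  generating partition:", paste(x$partition, collapse = ""), "\n")
  if (length(x$beta_direct)) {
    cat("  beta_direct:", paste(format(x$beta_direct), collapse = ", "), "\n")
  }
  if (any(x$response_beta != 0)) {
    cat("  response effects present (genotype x treatment)\n")
  }
  invisible(x)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Independent draws with genotype class probabilities
#' `((1-maf)^2, 2 maf (1-maf), maf^2)`; dosage counts the minor allele.
#'
#' @param n Number of individuals (>= 1).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param seed Optional integer seed; the caller's RNG stream is preserved.
#' @return Integer dosage vector with values in `{0, 1, 2}`.
#' @examples
#' table(simulate_genotypes(1000, 0.2, seed = 1))
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf > 0.5) {
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  }
  with_seed(seed, {
    p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    sample(0:2, n, replace = TRUE, prob = p)
  })
}

# draw from MVN(0, sigma) given the upper Cholesky factor
rmvn_chol <- function(n, chol_upper) {
  d <- ncol(chol_upper)
  matrix(stats::rnorm(n * d), n, d) %*% chol_upper
}

#' Simulate a statin-trial dataset from a truth specification
#'
#' Generates one SNP and a complete-case raw phenotype table following the
#' generative recipe documented in [truth_spec()]. The returned table has
#' the layout expected by [prepare_phenotypes()]: `id`, `stratum`, `age`,
#' `bmi`, `sex`, `smoking`, then `<pheno>_pre` and `<pheno>_post` per
#' phenotype.
#'
#' @param truth A [truth_spec()] object.
#' @return An object of class `"sim_trial"`: list with `pheno` (data frame),
#'   `genotype` (dosage vector) and `truth`.
#' @export
simulate_trial <- function(truth) {
  if (!inherits(truth, "truth_spec")) {
    stop("`truth` must be a truth_spec object", call. = FALSE)
  }
  with_seed(truth$seed, {
    d <- truth$d
    strata <- truth$strata
    n <- sum(strata$n)
    stratum <- rep(strata$label, strata$n)
    g <- simulate_genotypes(n, truth$maf)
    gc <- g - 2 * truth$maf

    Dset <- which(truth$partition == "D")
    Iset <- which(truth$partition == "I")

    # Residuals of indirect phenotypes must be independent of the direct and
    # unassociated residuals for the conditional-independence structure to
    # hold exactly (their correlation with the rest arises through the
    # loadings), so the I block of sigma is decoupled before drawing E.
    sigma_e <- truth$sigma
    if (length(Iset)) {
      sigma_e[Iset, -Iset] <- 0
      sigma_e[-Iset, Iset] <- 0
    }
    ch <- chol(sigma_e)
    rho <- truth$visit_cor
    shared <- rmvn_chol(n, ch)
    EP <- sqrt(rho) * shared + sqrt(1 - rho) * rmvn_chol(n, ch)
    ET <- sqrt(rho) * shared + sqrt(1 - rho) * rmvn_chol(n, ch)

    build_z <- function(E, beta_extra) {
      Z <- E
      if (length(Dset)) {
        Z[, Dset] <- Z[, Dset] +
          outer(gc, truth$beta_direct + beta_extra[Dset])
        if (length(Iset)) {
          Z[, Iset] <- Z[, Iset] + Z[, Dset, drop = FALSE] %*%
            truth$indirect_loadings
        }
      }
      others <- setdiff(which(beta_extra != 0), Dset)
      if (length(others)) {
        Z[, others] <- Z[, others] + outer(gc, beta_extra[others])
      }
      Z
    }
    ZP <- build_z(EP, rep(0, d))
    ZT <- build_z(ET, truth$response_beta)

    # covariates, drawn per stratum, contributions centered so stratum
    # means stay on target
    cp <- truth$covariate_params
    age <- bmi <- numeric(n)
    sex <- smoking <- integer(n)
    Xc <- matrix(0, n, 4, dimnames = list(NULL, c("age", "log_bmi", "sex",
                                                  "smoking")))
    for (s in seq_len(nrow(strata))) {
      ii <- which(stratum == strata$label[s])
      age[ii] <- stats::rnorm(length(ii), cp$age_mean[s], cp$age_sd[s])
      bmi[ii] <- stats::rlnorm(length(ii), cp$bmi_meanlog[s], cp$bmi_sdlog[s])
      sex[ii] <- stats::rbinom(length(ii), 1, cp$p_male[s])
      smoking[ii] <- stats::rbinom(length(ii), 1, cp$p_smoke[s])
      Xc[ii, "age"] <- (age[ii] - cp$age_mean[s]) / cp$age_sd[s]
      Xc[ii, "log_bmi"] <- (log(bmi[ii]) - cp$bmi_meanlog[s]) / cp$bmi_sdlog[s]
      Xc[ii, "sex"] <- sex[ii] - cp$p_male[s]
      Xc[ii, "smoking"] <- smoking[ii] - cp$p_smoke[s]
    }
    if (!is.null(truth$covariate_effects)) {
      for (nm in names(truth$covariate_effects)) {
        eff <- truth$covariate_effects[[nm]]
        ZP <- ZP + Xc[, nm] %o% eff
        ZT <- ZT + Xc[, nm] %o% eff
      }
    }

    si <- match(stratum, strata$label)
    P <- t(truth$mean_pre)[si, , drop = FALSE] +
      t(truth$sd_pre)[si, , drop = FALSE] * ZP
    T_ <- t(truth$mean_pre + truth$treatment_shift)[si, , drop = FALSE] +
      t(truth$sd_post)[si, , drop = FALSE] * ZT
    colnames(P) <- paste0(truth$phenotypes, "_pre")
    colnames(T_) <- paste0(truth$phenotypes, "_post")

    g_obs <- g
    if (truth$dosage_noise > 0) {
      g_obs <- pmin(2, pmax(0, g + stats::runif(n, -truth$dosage_noise,
                                                truth$dosage_noise)))
    }
    pheno <- data.frame(id = sprintf("ind%05d", seq_len(n)), stratum = stratum,
                        age = age, bmi = bmi, sex = sex, smoking = smoking,
                        P, T_, check.names = FALSE)
    structure(list(pheno = pheno, genotype = g_obs, truth = truth),
              class = "sim_trial")
  })
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf("Simulated statin trial: %d individuals, %d phenotypes, MAF %.3g\n",
              nrow(x$pheno), x$truth$d, x$truth$maf))
  cat("  generating partition:", paste(x$truth$partition, collapse = ""), "\n")
  invisible(x)
}

#' Inject multivariate outliers into a phenotype matrix
#'
#' Displaces `k` randomly chosen individuals by `magnitude` along a random
#' direction drawn uniformly on the sphere in the space whitened by the
#' sample covariance, so `magnitude` maps directly onto the expected increase
#' in Mahalanobis distance (a displacement of magnitude `m` alone has
#' squared Mahalanobis length `m^2` in the original covariance metric).
#'
#' @param Y Numeric phenotype matrix (individuals x phenotypes).
#' @param k Number of individuals to displace (`k < nrow(Y)`).
#' @param magnitude Displacement length in whitened-SD units (> 0).
#' @param seed Optional integer seed.
#' @return List with `values` (the modified matrix) and `ids` (row indices,
#'   or rownames when present, of the modified individuals).
#' @seealso [mahalanobis_outliers()]
#' @export
inject_outliers <- function(Y, k, magnitude = 8, seed = NULL) {
  if (identical(k, 0) || identical(k, 0L)) {
    return(list(values = Y, ids = character(0)))  # identity, input untouched
  }
  Y <- as_pheno_matrix(Y)
  n <- nrow(Y)
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != round(k)) {
    stop("`k` must be a non-negative integer", call. = FALSE)
  }
  if (k >= n) stop("`k` must be smaller than the number of individuals",
                   call. = FALSE)
  if (k == 0) return(list(values = Y, ids = character(0)))
  if (magnitude <= 0) stop("`magnitude` must be positive", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(n, k)
    R <- chol(stats::cov(Y))  # sigma = R'R
    for (i in idx) {
      u <- stats::rnorm(ncol(Y))
      u <- u / sqrt(sum(u^2))
      Y[i, ] <- Y[i, ] + magnitude * drop(crossprod(R, u))
    }
    ids <- if (!is.null(rownames(Y))) rownames(Y)[idx] else idx
    list(values = Y, ids = ids)
  })
}

#' Simulate an independent-SNP genotype panel
#'
#' Draws `n_snps` independent SNPs under Hardy-Weinberg equilibrium (no
#' linkage disequilibrium is simulated) and packages them as a
#' [genotype_data] object with positions, for use with the scan functions.
#'
#' @param n_snps Number of SNPs.
#' @param n Number of individuals.
#' @param maf Single frequency or vector (recycled) in (0, 0.5].
#' @param chrom Chromosome label.
#' @param positions Optional base-pair positions (default every 5 kb).
#' @param samples Optional sample identifiers.
#' @param seed Optional integer seed.
#' @return A [genotype_data] object.
#' @export
simulate_genotype_matrix <- function(n_snps, n, maf = 0.3, chrom = "1",
                                     positions = NULL, samples = NULL,
                                     seed = NULL) {
  maf <- rep_len(maf, n_snps)
  if (is.null(positions)) positions <- 5000L * seq_len(n_snps)
  with_seed(seed, {
    dos <- t(vapply(maf, function(f) simulate_genotypes(n, f),
                    numeric(n)))
    info <- data.frame(rsid = sprintf("snp%04d", seq_len(n_snps)),
                       chrom = chrom, pos = as.integer(positions),
                       ref = "A", alt = "B", maf = rowMeans(dos) / 2,
                       quality = 1, flipped = FALSE)
    genotype_data(dos, info, samples)
  })
}
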