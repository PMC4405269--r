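# Per-phenotype effect estimation and summaries: genotype-class profiles,
# regression effect profiles, mediation adjustment, sequential two-SNP
# conditioning, statin-change summaries, treated/untreated contrasts, PVE.

#' Genotype-class means per phenotype
#'
#' Means and standard errors of each (normalized) phenotype within each
#' genotype class, with dosages rounded to the nearest class in `{0, 1, 2}`.
#' Classes whose sample proportion is at most 0.01 (including empty classes)
#' are flagged `omitted` for display.
#'
#' @param Y Phenotype matrix.
#' @param g Dosage vector (rounded to classes internally).
#' @return Data frame with columns `phenotype`, `class`, `n`, `proportion`,
#'   `mean`, `se`, `omitted`.
#' @export
genotype_class_profile <- function(Y, g) {
  Y <- as_pheno_matrix(Y)
  n <- nrow(Y)
  gcl <- pmin(2L, pmax(0L, as.integer(round(g))))
  out <- do.call(rbind, lapply(0:2, function(cl) {
    ii <- which(gcl == cl)
    nn <- length(ii)
    data.frame(
      phenotype = colnames(Y), class = cl, n = nn, proportion = nn / n,
      mean = if (nn) colMeans(Y[ii, , drop = FALSE]) else NA_real_,
      se = if (nn > 1) apply(Y[ii, , drop = FALSE], 2, stats::sd) / sqrt(nn)
           else NA_real_,
      omitted = nn / n <= 0.01, row.names = NULL)
  }))
  out[order(out$phenotype, out$class), ]
}

#' Per-phenotype additive effect profile of a SNP
#'
#' Simple linear regression (intercept + dosage) of each phenotype on the
#' unrounded dosage; the slope is the effect per allele copy on the
#' (typically normalized) phenotype.
#'
#' @param Y Phenotype matrix.
#' @param g Dosage vector; must be polymorphic.
#' @return An object of class `"effect_profile"`: data frame with columns
#'   `phenotype`, `beta`, `se`.
#' @examples
#' set.seed(3)
#' g <- rbinom(300, 2, 0.3)
#' Y <- cbind(a = 0.4 * g + rnorm(300), b = rnorm(300))
#' effect_profile(Y, g)
#' @export
effect_profile <- function(Y, g) {
  Y <- as_pheno_matrix(Y)
  n <- nrow(Y)
  g <- check_dosage(g, n)
  X <- cbind(1, g)
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  df <- n - 2
  s2 <- colSums(res^2) / df
  sxx <- sum((g - mean(g))^2)
  out <- data.frame(phenotype = colnames(Y),
                    beta = as.matrix(fit$coefficients)[2, ],
                    se = sqrt(s2 / sxx), row.names = NULL)
  class(out) <- c("effect_profile", "data.frame")
  out
}

#' @export
print.effect_profile <- function(x, ...) {
  cat("Per-phenotype effect per allele copy (simple regression):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot an effect profile
#'
#' Effect estimates across phenotypes in their column order (for
#' subfractions, lower to higher density) with dashed +/- 2 SE bands.
#'
#' @param x An `"effect_profile"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.effect_profile <- function(x, ...) {
  i <- seq_len(nrow(x))
  ylim <- range(x$beta + 2 * x$se, x$beta - 2 * x$se, 0)
  graphics::plot(i, x$beta, type = "b", xaxt = "n", xlab = "",
                 ylab = "effect per allele", ylim = ylim, ...)
  graphics::axis(1, at = i, labels = x$phenotype, las = 2)
  graphics::lines(i, x$beta + 2 * x$se, lty = 3)
  graphics::lines(i, x$beta - 2 * x$se, lty = 3)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Mediation adjustment of a SNP effect
#'
#' Compares the SNP effect on a phenotype before and after including a
#' candidate mediator (e.g. HDL-C) as a covariate in a standard multiple
#' linear regression, and reports the percentage change in effect size,
#' `100 * (beta_adjusted - beta_unadjusted) / beta_unadjusted`, so that
#' attenuation toward zero is negative.
#'
#' @param y Phenotype vector.
#' @param g Dosage vector.
#' @param mediator Mediator vector aligned with `y` and `g`.
#' @return List with `beta_unadjusted`, `beta_adjusted`, `percent_change`
#'   (`NA` with a warning when the unadjusted effect is exactly 0).
#' @export
mediation_adjust <- function(y, g, mediator) {
  y <- as.numeric(y)
  g <- check_dosage(g, length(y))
  if (length(mediator) != length(y)) {
    stop("`mediator` must align with `y` and `g`", call. = FALSE)
  }
  b0 <- stats::lm.fit(cbind(1, g), y)$coefficients[2]
  b1 <- stats::lm.fit(cbind(1, g, as.numeric(mediator)), y)$coefficients[2]
  pc <- if (b0 == 0) {
    warning("unadjusted effect is exactly 0; percent change undefined",
            call. = FALSE)
    NA_real_
  } else 100 * (b1 - b0) / b0
  list(beta_unadjusted = unname(b0), beta_adjusted = unname(b1),
       percent_change = unname(pc))
}

#' Sequential conditional effect profiles for two SNPs
#'
#' Effect profile of the top SNP on `Y`, and of the secondary SNP on the
#' residuals of `Y` after regressing out the top SNP — the two-SNP
#' replication procedure for independent signals at one locus.
#'
#' @param Y Phenotype matrix.
#' @param g_top,g_secondary Polymorphic dosage vectors.
#' @return List with `top` and `secondary` effect profiles.
#' @export
sequential_conditional_effects <- function(Y, g_top, g_secondary) {
  Y <- as_pheno_matrix(Y)
  g_top <- check_dosage(g_top, nrow(Y), "g_top")
  top <- effect_profile(Y, g_top)
  Yr <- stats::resid(stats::lm.fit(cbind(1, g_top), Y))
  colnames(Yr) <- colnames(Y)
  list(top = top, secondary = effect_profile(Yr, g_secondary))
}

#' Statin-change summary of raw measurements
#'
#' Per-group, per-phenotype mean and SD of the absolute change `T - P` (raw
#' units) and of the per-individual fractional change `(T - P)/P`.
#' Individuals with a non-positive pre-treatment value are excluded from the
#' fractional summary of that phenotype, with a message.
#'
#' @param raw Raw trial table as accepted by [prepare_phenotypes()].
#' @param by Grouping column (default `"stratum"`; any column of `raw`).
#' @param phenotypes Optional phenotype subset.
#' @return Data frame with columns `group`, `phenotype`, `n`,
#'   `mean_abs_change`, `sd_abs_change`, `n_frac`, `mean_frac_change`,
#'   `sd_frac_change`.
#' @export
treatment_change_summary <- function(raw, by = "stratum", phenotypes = NULL) {
  raw <- as.data.frame(raw)
  if (!by %in% names(raw)) stop("grouping column '", by, "' not found",
                                call. = FALSE)
  if (is.null(phenotypes)) {
    phenotypes <- sub("_pre$", "", grep("_pre$", names(raw), value = TRUE))
  }
  groups <- split(seq_len(nrow(raw)), as.character(raw[[by]]))
  dropped <- 0L
  out <- do.call(rbind, lapply(names(groups), function(gn) {
    ii <- groups[[gn]]
    do.call(rbind, lapply(phenotypes, function(ph) {
      P <- raw[[paste0(ph, "_pre")]][ii]
      T_ <- raw[[paste0(ph, "_post")]][ii]
      ab <- T_ - P
      okp <- P > 0
      dropped <<- dropped + sum(!okp)
      fr <- (T_[okp] - P[okp]) / P[okp]
      data.frame(group = gn, phenotype = ph, n = length(ii),
                 mean_abs_change = mean(ab), sd_abs_change = stats::sd(ab),
                 n_frac = sum(okp), mean_frac_change = mean(fr),
                 sd_frac_change = stats::sd(fr))
    }))
  }))
  if (dropped > 0) {
    message(dropped, " non-positive pre-treatment value(s) excluded from ",
            "fractional change")
  }
  rownames(out) <- NULL
  out
}

#' Treated vs untreated effect contrast
#'
#' Separate effect profiles of a SNP in the treated and untreated
#' (normalized) phenotypes, plus its profile on the difference phenotype; a
#' genotype-by-treatment (response) effect appears as a difference between
#' the treated and untreated profiles, and as a nonzero effect on the
#' difference.
#'
#' @param pre,post Normalized phenotype matrices aligned with `g`.
#' @param g Dosage vector.
#' @return List of effect profiles `untreated`, `treated`, `difference`.
#' @export
treated_untreated_contrast <- function(pre, post, g) {
  pre <- as_pheno_matrix(pre, "pre")
  post <- as_pheno_matrix(post, "post")
  check_aligned(pre, post)
  list(untreated = effect_profile(pre, g),
       treated = effect_profile(post, g),
       difference = effect_profile(post - pre, g))
}

#' Proportion of phenotypic variance explained by a biallelic SNP
#'
#' The standard additive formula `2 maf (1 - maf) beta^2 / var_y`.
#'
#' @param beta Effect per allele copy.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param var_y Phenotype variance (> 0); default 1 for standardized
#'   phenotypes.
#' @return PVE in `[0, 1)`; 0 iff `beta = 0`.
#' @examples
#' pve(1, 0.5)  # 0.5
#' @export
pve <- function(beta, maf, var_y = 1) {
  if (any(var_y <= 0)) stop("`var_y` must be positive", call. = FALSE)
  if (any(maf <= 0 | maf > 0.5)) stop("`maf` must lie in (0, 0.5]",
                                      call. = FALSE)
  2 * maf * (1 - maf) * beta^2 / var_y
}

#' Effect per allele needed for a target PVE
#'
#' Inverse of [pve()]: the absolute effect size on a phenotype of variance
#' `var_y` that makes a SNP of frequency `maf` explain `target` of the
#' variance. Useful for calibrating simulations.
#'
#' @param target Desired PVE in (0, 1).
#' @inheritParams pve
#' @return Positive effect size.
#' @export
beta_for_pve <- function(target, maf, var_y = 1) {
  if (any(target <= 0 | target >= 1)) stop("`target` must be in (0, 1)",
                                           call. = FALSE)
  sqrt(target * var_y / (2 * maf * (1 - maf)))
}
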