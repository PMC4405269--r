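# Trial-design presets: 12 LDL/IDL-related phenotypes measured before and
# during statin treatment in three cohorts (CAP on simvastatin, PRINCE
# secondary and primary prevention on pravastatin), each genotyped in two
# stages -> 6 strata.

#' Lipoprotein phenotype labels
#'
#' The 12 analysis phenotypes: total LDL cholesterol (`L`), LDL peak particle
#' diameter (`Ld`), and the 10 IDL/LDL subfraction cholesterol
#' concentrations ordered from lower to higher particle density
#' (`i1`..`l4b`).
#' @return Character vector of length 12.
#' @export
subfraction_labels <- function() {
  c("L", "Ld", "i1", "i2", "i3", "l1", "l2a", "l2b", "l3a", "l3b", "l4a", "l4b")
}

# per-cohort raw-scale summary parameters (rows = phenotypes, cols = cohorts
# CAP / PRINCE secondary prevention / PRINCE primary prevention); mg/dL for
# concentrations, Angstrom for peak diameter
cohort_parameters <- function() {
  ph <- subfraction_labels()
  m <- function(...) matrix(c(...), nrow = 12, ncol = 3, byrow = TRUE,
                            dimnames = list(ph, c("CAP", "PRINCE_sec",
                                                  "PRINCE_pri")))
  list(
    n = c(CAP = 581L, PRINCE_sec = 797L, PRINCE_pri = 490L),
    mean_pre = m(132, 125, 142.4,
                 266.9, 262.4, 262.9,
                 6.3, 5, 5.8,
                 6.8, 5.5, 6.4,
                 8.4, 6.7, 7.8,
                 34.1, 27.2, 31.4,
                 25.3, 23.5, 28.3,
                 22.9, 25.8, 30.7,
                 14.5, 17.6, 18.5,
                 3.9, 4.5, 4.4,
                 4.7, 4.6, 4.5,
                 5.1, 4.6, 4.7),
    sd_pre = m(33.2, 29.7, 24.9,
               8.9, 9.1, 8.3,
               2.6, 2.1, 2.1,
               2.5, 2.1, 2.1,
               3.4, 2.7, 2.9,
               17.3, 15.5, 16.4,
               12.9, 12.3, 13,
               12.3, 12.8, 14.5,
               12.1, 12.6, 13.6,
               3.2, 3.3, 3.4,
               1.9, 2.5, 2.3,
               2.1, 2.5, 2.2),
    mean_post = m(76.7, 91.8, 107.5,
                  267.6, 262.4, 262.8,
                  3.5, 3.4, 4.1,
                  3.7, 3.8, 4.6,
                  4.7, 4.7, 5.5,
                  17.9, 18.1, 21.8,
                  13.6, 16.5, 20.5,
                  13.8, 19.5, 23.4,
                  9.1, 13.7, 15,
                  2.8, 3.8, 3.8,
                  3.6, 4.1, 4.2,
                  3.9, 4.2, 4.6),
    sd_post = m(23.7, 26.3, 24.3,
                8.6, 8.7, 8.1,
                1.9, 1.6, 1.8,
                1.6, 1.6, 1.7,
                2.1, 2, 2.2,
                9.1, 9.6, 11.2,
                6.6, 8.6, 9.5,
                6.7, 9.6, 10.4,
                6.2, 8.9, 10.1,
                1.3, 2.4, 2.5,
                1.2, 1.8, 1.9,
                1.5, 1.9, 2.2),
    covariates = data.frame(
      cohort = c("CAP", "PRINCE_sec", "PRINCE_pri"),
      age_mean = c(54.5, 69.7, 56.8), age_sd = c(12.6, 10.7, 12.3),
      bmi_meanlog = log(c(27.7, 28.9, 29.1)) - 0.5 * log(1 + (c(5.5, 5.3, 5.3) / c(27.7, 28.9, 29.1))^2),
      bmi_sdlog = sqrt(log(1 + (c(5.5, 5.3, 5.3) / c(27.7, 28.9, 29.1))^2)),
      p_male = c(0.534, 0.792, 0.747), p_smoke = c(0.134, 0.138, 0.127))
  )
}

#' Default residual correlation among the 12 lipoprotein phenotypes
#'
#' A qualitative, configurable emulation of the observed correlation
#' structure, built from a two-factor model: a "total concentration" factor
#' loading on LDL-C and all subfraction concentrations, and a "particle
#' size" factor loading positively on the large low-density subfractions,
#' negatively on the small high-density ones, and strongly on peak diameter.
#' Adjacent subfractions are therefore positively correlated with decaying
#' strength, and the largest and smallest subfraction blocks are negatively
#' correlated. Positive definite by construction.
#'
#' @return A 12 x 12 correlation matrix with [subfraction_labels()] names.
#' @export
default_sigma_subfractions <- function() {
  ph <- subfraction_labels()
  size <- seq(0.7, -0.7, length.out = 10)        # i1 (largest) .. l4b (smallest)
  total <- c(0.9, 0,                             # L, Ld
             0.35, 0.35, 0.4, 0.6, 0.6, 0.6, 0.45, 0.35, 0.3, 0.3)
  sizef <- c(0.1, 0.8, size)
  B <- cbind(total, sizef)
  S <- tcrossprod(B)
  diag(S) <- diag(S) + pmax(0.2, 1 - rowSums(B^2))
  S <- stats::cov2cor(S)
  dimnames(S) <- list(ph, ph)
  S
}

#' Trial-calibrated truth specification (12 phenotypes, 6 strata)
#'
#' Builds a [truth_spec()] emulating the design of a two-cohort-stage statin
#' pharmacogenomics trial: 3 cohorts x 2 genotyping stages = 6 strata
#' (cohort sizes 581 / 797 / 490, split 60/40 over stages), the 12
#' lipoprotein phenotypes with per-cohort raw-scale pre/post means and SDs,
#' per-cohort covariate distributions, and the default subfraction residual
#' correlation ([default_sigma_subfractions()]).
#'
#' @param partition,beta_direct,indirect_loadings,response_beta,maf,seed,...
#'   Passed to [truth_spec()] to overlay genetic effects on the design.
#' @return A `"truth_spec"` object with `d = 12` and 6 strata.
#' @examples
#' ts <- truth_spec_table1(seed = 1)    # null SNP, full design
#' sum(ts$strata$n)                     # 1868 individuals
#' @export
truth_spec_table1 <- function(partition = NULL, beta_direct = numeric(0),
                              indirect_loadings = NULL, response_beta = NULL,
                              maf = 0.3, seed = NULL, ...) {
  cp <- cohort_parameters()
  cohorts <- names(cp$n)
  n1 <- round(0.6 * cp$n)
  strata <- data.frame(
    label = paste0(rep(cohorts, each = 2), c("_stage1", "_stage2")),
    n = as.integer(rbind(n1, cp$n - n1))
  )
  scoh <- rep(seq_along(cohorts), each = 2)  # stratum -> cohort
  covp <- cp$covariates[scoh, c("age_mean", "age_sd", "bmi_meanlog",
                                "bmi_sdlog", "p_male", "p_smoke")]
  truth_spec(
    phenotypes = subfraction_labels(), strata = strata, maf = maf,
    partition = partition, beta_direct = beta_direct,
    indirect_loadings = indirect_loadings,
    sigma = default_sigma_subfractions(),
    mean_pre = cp$mean_pre[, scoh], sd_pre = cp$sd_pre[, scoh],
    treatment_shift = (cp$mean_post - cp$mean_pre)[, scoh],
    sd_post = cp$sd_post[, scoh],
    response_beta = response_beta, covariate_params = covp,
    seed = seed, ...
  )
}

#' Sign-flipping ("CETP-like") effect profile over six subfractions
#'
#' An effect profile whose signs alternate across the subfraction range
#' (positive on the largest and smallest particles, negative in the middle)
#' and whose raw effects sum to zero, so the effect on the summed phenotype
#' cancels even though each subfraction is genuinely associated. This is the
#' regime where a multivariate analysis gains most over a univariate
#' analysis of the total: the effects are discordant with the positive
#' correlation among adjacent subfractions.
#'
#' @param scale Effect per allele copy, residual-SD units, for the unit
#'   entries of the pattern `(+1, +1, -2, -2, +1, +1)`.
#' @return Named effect vector over phenotypes `i1, i2, l1, l2a, l3a, l3b`.
#' @export
cetp_like_profile <- function(scale = 0.15) {
  stats::setNames(scale * c(1, 1, -2, -2, 1, 1),
                  c("i1", "i2", "l1", "l2a", "l3a", "l3b"))
}
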