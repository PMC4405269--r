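test_that("genotype-class profile handles degenerate and rare classes", {
  Y <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  prof0 <- genotype_class_profile(Y, rep(0, 30))
  expect_equal(prof0$proportion[prof0$class == 0], c(1, 1))
  expect_true(all(prof0$omitted[prof0$class != 0]))
  # a class at proportion 0.005 <= 0.01 is omitted
  g <- c(rep(0, 895), rep(1, 100), rep(2, 5))
  Y2 <- matrix(rnorm(2000), 1000, 2)
  prof <- genotype_class_profile(Y2, g)
  expect_true(all(prof$omitted[prof$class == 2]))
  expect_false(any(prof$omitted[prof$class %in% 0:1]))
})

test_that("additive simulated SNP gives collinear class means", {
  set.seed(61)
  n <- 4000
  g <- fixture_dosage(n, 0.4, seed = 62)
  Y <- matrix(0.3 * g + rnorm(n), n, 1, dimnames = list(NULL, "a"))
  prof <- genotype_class_profile(Y, g)
  m <- prof$mean
  se <- prof$se
  # heterozygote mean sits midway between homozygote means
  expect_lt(abs(m[2] - (m[1] + m[3]) / 2), 2 * sqrt(sum(se^2)))
})

test_that("effect profile recovers exact and noisy effects", {
  g <- fixture_dosage(200, 0.3, seed = 63)
  Y <- cbind(a = 2 * g, b = 1 - 0.5 * g)
  ep <- effect_profile(Y + 0, g)
  expect_equal(ep$beta, c(2, -0.5), tolerance = 1e-10)
  # null phenotype: |beta| < 3 SE almost always
  set.seed(64)
  cover <- replicate(200, {
    y <- matrix(rnorm(200), ncol = 1)
    e <- effect_profile(y, g)
    abs(e$beta) < 3 * e$se
  })
  expect_gt(mean(cover), 0.95)
  expect_error(effect_profile(Y, rep(2, 200)), "monomorphic")
})

test_that("mediation adjustment uses the stated percent-change convention", {
  # pure arithmetic of the convention
  expect_equal(100 * (0.273 - 1.0) / 1.0, -72.7, tolerance = 1e-9)
  # mediator unrelated to g leaves the effect essentially unchanged
  set.seed(65)
  n <- 4000
  g <- fixture_dosage(n, 0.3, seed = 66)
  y <- 0.5 * g + rnorm(n)
  m_indep <- rnorm(n)
  out <- mediation_adjust(y, g, m_indep)
  expect_lt(abs(out$percent_change), 5)
  # fully mediated chain g -> M -> y attenuates to ~ -100%
  M <- g + 0.2 * rnorm(n)
  y2 <- 2 * M + rnorm(n)
  out2 <- mediation_adjust(y2, g, M)
  expect_lt(abs(out2$beta_adjusted), 0.1)
  expect_lt(out2$percent_change, -90)
})

test_that("sequential conditioning is exact in its invariances", {
  set.seed(67)
  n <- 500
  g1 <- fixture_dosage(n, 0.3, seed = 68)
  g2 <- fixture_dosage(n, 0.2, seed = 69)
  Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  # conditioning a SNP on itself leaves nothing
  self <- sequential_conditional_effects(Y, g1, g1)
  expect_true(all(abs(self$secondary$beta) < 1e-10))
  # adding any multiple of g_top to every column leaves the secondary
  # profile exactly unchanged
  sc1 <- sequential_conditional_effects(Y, g1, g2)
  sc2 <- sequential_conditional_effects(Y + outer(g1, c(3, -1, 0.5)), g1, g2)
  expect_equal(sc1$secondary$beta, sc2$secondary$beta, tolerance = 1e-10)
  expect_equal(sc1$secondary$se, sc2$secondary$se, tolerance = 1e-10)
})

test_that("independent SNPs with distinct profiles are both recovered in sign", {
  set.seed(70)
  n <- 5000
  g1 <- fixture_dosage(n, 0.3, seed = 71)
  g2 <- fixture_dosage(n, 0.3, seed = 72)
  prof1 <- c(0.2, -0.15, 0.1)
  prof2 <- c(-0.2, 0.2, 0.15)
  Y <- outer(g1, prof1) + outer(g2, prof2) + matrix(rnorm(n * 3), n, 3)
  colnames(Y) <- c("a", "b", "c")
  sc <- sequential_conditional_effects(Y, g1, g2)
  expect_identical(sign(sc$top$beta), sign(prof1))
  expect_identical(sign(sc$secondary$beta), sign(prof2))
})

test_that("treatment change summaries follow their definitions", {
  tr <- fixture_trial(n = 80, d = 2)
  raw <- tr$pheno
  # T = P everywhere -> both summaries zero
  raw0 <- raw
  raw0$Y1_post <- raw0$Y1_pre
  raw0$Y2_post <- raw0$Y2_pre
  s0 <- treatment_change_summary(raw0)
  expect_true(all(abs(s0$mean_abs_change) < 1e-12))
  expect_true(all(abs(s0$mean_frac_change) < 1e-12))
  # T = P/2 with positive P -> fractional change exactly -0.5
  rawh <- raw
  rawh$Y1_pre <- abs(rawh$Y1_pre) + 1
  rawh$Y2_pre <- abs(rawh$Y2_pre) + 1
  rawh$Y1_post <- rawh$Y1_pre / 2
  rawh$Y2_post <- rawh$Y2_pre / 2
  sh <- treatment_change_summary(rawh)
  expect_true(all(abs(sh$mean_frac_change + 0.5) < 1e-12))
})

test_that("statin shift of the trial preset is recovered on the raw scale", {
  tr <- simulate_trial(truth_spec_table1(seed = 73))
  s <- treatment_change_summary(tr$pheno, by = "stratum", phenotypes = "L")
  cap <- s[s$group == "CAP_stage1", ]
  # configured LDL-C shift is 76.7 - 132 = -55.3 mg/dL
  expect_lt(abs(cap$mean_abs_change - (-55.3)), 2 * cap$sd_abs_change / sqrt(cap$n))
})

test_that("response SNPs separate treated and untreated profiles", {
  set.seed(74)
  ts <- truth_spec(n = 4000, d = 2, partition = c("U", "U"),
                   response_beta = c(0.3, 0), seed = 75)
  tr <- simulate_trial(ts)
  pre <- as.matrix(tr$pheno[c("Y1_pre", "Y2_pre")])
  post <- as.matrix(tr$pheno[c("Y1_post", "Y2_post")])
  colnames(pre) <- colnames(post) <- c("Y1", "Y2")
  ct <- treated_untreated_contrast(pre, post, tr$genotype)
  # untreated effect ~ 0, difference effect ~ response_beta
  expect_lt(abs(ct$untreated$beta[1]), 3 * ct$untreated$se[1])
  expect_gt(ct$difference$beta[1], 0.2)
  expect_lt(abs(ct$difference$beta[2]), 3 * ct$difference$se[2])
  # near-linear regime: beta on difference ~ beta_treated - beta_untreated
  expect_equal(ct$difference$beta, ct$treated$beta - ct$untreated$beta,
               tolerance = 1e-9)
})

test_that("PVE follows the additive biallelic formula", {
  expect_equal(pve(0, 0.3), 0)
  expect_equal(pve(1, 0.5, 1), 0.5)
  expect_equal(pve(beta_for_pve(0.02, 0.3), 0.3), 0.02, tolerance = 1e-12)
  expect_error(pve(1, 0.3, 0), "positive")
  expect_error(pve(1, 0.6), "0, 0.5")
  # simulated SNP at configured PVE 2%
  set.seed(76)
  n <- 1e4
  maf <- 0.3
  b <- beta_for_pve(0.02, maf)
  g <- simulate_genotypes(n, maf, seed = 77)
  y <- b * g + rnorm(n, sd = sqrt(1 - 0.02))
  ep <- effect_profile(matrix(y, ncol = 1), g)
  est <- pve(ep$beta, mean(g) / 2, var(y))
  expect_lt(abs(est - 0.02), 0.006)
})
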