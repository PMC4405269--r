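test_that("filter applies the strict either-statistic rule", {
  flt <- data.frame(log10_bf_uni = c(1.4, 1.3, 0.2, 1.31),
                    log10_bf_all = c(0.2, 1.3, 1.4, 1.29))
  pass <- flt$log10_bf_uni > 1.3 | flt$log10_bf_all > 1.3
  expect_identical(pass, c(TRUE, FALSE, TRUE, TRUE))
  # and through the real code path: boundary values do not pass
  set.seed(41)
  n <- 400
  Y <- matrix(rnorm(n * 3), n, 3)
  gd <- simulate_genotype_matrix(8, n, 0.3, seed = 42)
  out <- filter_scan(gd, Y, threshold = 1.3)
  expect_identical(out$candidate,
                   out$log10_bf_uni > 1.3 | out$log10_bf_all > 1.3)
})

test_that("filter statistics equal the per-SNP engine statistics", {
  set.seed(43)
  n <- 300
  g <- fixture_dosage(n, 0.25, seed = 9)
  Y <- cbind(0.3 * g + rnorm(n), rnorm(n), rnorm(n))
  colnames(Y) <- c("a", "b", "c")
  gd <- genotype_data(matrix(g, 1, n))
  flt <- filter_scan(gd, Y)
  f <- mvbf(Y, g)
  expect_equal(flt$log10_bf_uni, f$log10_bf_uni, tolerance = 1e-10)
  expect_equal(flt$log10_bf_all, f$log10_bf_all, tolerance = 1e-10)
})

test_that("two-stage scan equals the full scan restricted to candidates", {
  set.seed(44)
  n <- 500
  ts <- truth_spec(n = n, d = 3, partition = c("D", "U", "U"),
                   beta_direct = 0.35, seed = 45)
  tr <- simulate_trial(ts)
  pp <- prepare_phenotypes(tr$pheno)
  gd <- simulate_genotype_matrix(10, n, 0.3, seed = 46)
  gd$dosage[4, ] <- tr$genotype  # plant the causal SNP
  gd$info$maf[4] <- mean(tr$genotype) / 2
  res <- suppressMessages(mvbf_scan(gd, pp$A, filter_threshold = 1.3))
  flt <- attr(res, "filter")
  expect_true(any(flt$candidate))
  direct <- full_scan(subset_genotypes(gd, which(flt$candidate)), pp$A)
  expect_equal(res$log10_bf_av, direct$log10_bf_av, tolerance = 1e-12)
  expect_equal(res$rsid, direct$rsid)
})

test_that("scan output is invariant to SNP input order", {
  set.seed(47)
  n <- 250
  Y <- matrix(rnorm(n * 2), n, 2)
  gd <- simulate_genotype_matrix(6, n, 0.3, seed = 48)
  r1 <- full_scan(gd, Y)
  r2 <- full_scan(subset_genotypes(gd, 6:1), Y)
  expect_equal(r1$rsid, r2$rsid)
  expect_equal(r1$log10_bf_av, r2$log10_bf_av, tolerance = 1e-12)
})

test_that("single-phenotype scan collapses to the univariate column", {
  set.seed(49)
  n <- 200
  Y <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  gd <- simulate_genotype_matrix(4, n, 0.3, seed = 50)
  res <- full_scan(gd, Y)
  expect_equal(res$log10_bf_av, res$log10_bf_a, tolerance = 1e-12)
  expect_equal(res$log10_bf_av, res$log10_bf_uni, tolerance = 1e-12)
})

test_that("conditioning on the top SNP removes its own signal", {
  set.seed(51)
  n <- 800
  ts <- truth_spec(n = n, d = 3, partition = c("D", "D", "U"),
                   beta_direct = c(0.4, 0.3), seed = 52)
  tr <- simulate_trial(ts)
  pp <- prepare_phenotypes(tr$pheno)
  gd <- simulate_genotype_matrix(5, n, 0.3, seed = 53,
                                 positions = c(1e5, 2e5, 3e5, 4e5, 5e5))
  gd$dosage[3, ] <- tr$genotype
  res <- conditional_scan(pp$A, "snp0003", gd, window = 150000)
  # window keeps snps within 150kb of position 3e5
  expect_setequal(res$rsid, c("snp0002", "snp0003", "snp0004"))
  expect_lt(abs(res$log10_bf_av[res$rsid == "snp0003"]), 0.5)
})

test_that("gain decomposition is an exact identity", {
  got <- decompose_gain(30.3, 12.7, 3.1)
  expect_equal(got$measurement_gain + got$multivariate_gain, 30.3 - 3.1,
               tolerance = 1e-12)
  expect_equal(got$total_gain, 27.2, tolerance = 1e-12)
  # degenerate corners
  expect_equal(decompose_gain(5, 5, 2)$multivariate_gain, 0)
  expect_equal(decompose_gain(5, 2, 2)$measurement_gain, 0)
  expect_error(decompose_gain(Inf, 1, 0), "finite")
  # vectorized identity
  set.seed(54)
  av <- rnorm(20); un <- rnorm(20); rf <- rnorm(20)
  dd <- decompose_gain(av, un, rf)
  expect_equal(dd$measurement_gain + dd$multivariate_gain, av - rf,
               tolerance = 1e-12)
})

test_that("top_snp breaks ties toward lower position", {
  tab <- data.frame(rsid = c("a", "b"), chrom = c("1", "1"),
                    pos = c(200, 100), log10_bf_av = c(3, 3))
  expect_equal(top_snp(tab)$rsid, "b")
})
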