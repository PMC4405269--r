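test_that("closed-form log BF matches the numerical-integration oracle", {
  set.seed(42)
  n <- 20
  g <- fixture_dosage(n, 0.3, seed = 5)
  E <- matrix(rnorm(n * 3), n, 3)
  Y <- E
  Y[, 1] <- Y[, 1] + 0.8 * g
  Y[, 2] <- Y[, 2] + 0.5 * Y[, 1]
  colnames(Y) <- c("a", "b", "c")
  cases <- list(c("D", "U", "U"), c("D", "I", "U"), c("D", "D", "U"),
                c("D", "D", "I"), c("U", "D", "I"), c("D", "I", "I"))
  for (pt in cases) {
    for (s in c(0.05, 0.1, 0.2, 0.4)) {
      cf <- log_bf_partition(Y, g, pt, s)
      or <- log10_bf_oracle(Y, g, pt, s)
      expect_lt(abs(cf - or) / abs(or), 0.01,
                label = sprintf("rel err %s sigma=%g", paste(pt, collapse = ""), s))
    }
  }
})

test_that("BF collapses to 1 as the prior scale vanishes", {
  dat <- fixture_assoc(80)
  expect_lt(abs(log_bf_partition(dat$Y, dat$g, c("D", "D", "U", "U"), 1e-8)),
            1e-6)
  expect_lt(abs(log_bf_univariate(dat$Y[, 1], dat$g, 1e-8)), 1e-6)
})

test_that("orthogonal response gives the pure determinant penalty", {
  # construct Y exactly orthogonal to the centered dosage
  set.seed(9)
  n <- 60
  g <- fixture_dosage(n, 0.4, seed = 3)
  gt <- g - mean(g)
  Y <- qr.resid(qr(cbind(1, gt)), matrix(rnorm(n * 2), n, 2))
  colnames(Y) <- c("a", "b")
  s <- 0.3
  got <- log_bf_partition(Y, g, c("D", "U"), s)
  sgg <- sum(qr.resid(qr(cbind(1, Y[, 2])), gt)^2)
  expect_equal(got, -0.5 * log10(1 + s^2 * sgg), tolerance = 1e-6)
  expect_lt(got, 0)
})

test_that("indirect phenotypes do not enter the computation, unassociated ones do", {
  dat <- fixture_assoc(100, d = 3)
  s <- 0.2
  # moving Y3 between I and absent changes nothing
  expect_equal(log_bf_partition(dat$Y, dat$g, c("D", "U", "I"), s),
               log_bf_partition(dat$Y[, 1:2], dat$g, c("D", "U"), s),
               tolerance = 1e-12)
  # moving Y3 between U and I changes the conditioning, hence the BF
  expect_false(isTRUE(all.equal(
    log_bf_partition(dat$Y, dat$g, c("D", "U", "I"), s),
    log_bf_partition(dat$Y, dat$g, c("D", "U", "U"), s))))
})

test_that("perfect association yields overwhelming evidence", {
  g <- fixture_dosage(100, 0.4, seed = 7)
  expect_gt(log_bf_univariate(as.numeric(g), g, 0.4), 10)
})

test_that("permutation null keeps univariate BFs small", {
  set.seed(21)
  n <- 2000
  g <- fixture_dosage(n, 0.3, seed = 8)
  y <- rnorm(n)
  lb <- replicate(100, log_bf_univariate(sample(y), g, 0.1))
  expect_lt(stats::median(lb), 0)
})

test_that("monomorphic and degenerate inputs error clearly", {
  Y <- matrix(rnorm(40), 20, 2)
  expect_error(log_bf_partition(Y, rep(1, 20), c("D", "U"), 0.2), "monomorphic")
  Ybad <- cbind(Y[, 1], Y[, 1])
  expect_error(log_bf_partition(Ybad, fixture_dosage(20), c("D", "D"), 0.2),
               "singular|collinear")
})

test_that("mvbf reduces to the univariate BF when d = 1", {
  dat <- fixture_assoc(120, d = 1)
  f <- mvbf(dat$Y, dat$g)
  expect_equal(f$log10_bf_av, f$log10_bf_uni, tolerance = 1e-12)
  expect_equal(f$log10_bf_av, f$log10_bf_all, tolerance = 1e-12)
  grid <- c(0.05, 0.1, 0.2, 0.4)
  by_sigma <- vapply(grid, function(s) log_bf_univariate(dat$Y[, 1], dat$g, s),
                     numeric(1))
  manual <- log10(mean(10^by_sigma))
  expect_equal(f$log10_bf_av, manual, tolerance = 1e-10)
})

test_that("mvbf agrees with the direct per-partition path", {
  dat <- fixture_assoc(90, d = 3)
  f <- mvbf(dat$Y, dat$g, sigma_a = c(0.1, 0.3), keep_partitions = TRUE)
  p <- enumerate_partitions(3)
  lw <- log(apply(p, 1, partition_weight))
  lb <- apply(p, 1, function(pt) {
    log10(mean(10^log_bf_partition(dat$Y, dat$g, pt, c(0.1, 0.3))))
  })
  manual_av <- log10(sum(exp(lw) * 10^lb))
  expect_equal(f$log10_bf_av, manual_av, tolerance = 1e-9)
})

test_that("posterior triplets are probabilities summing to one", {
  dat <- fixture_assoc(150, d = 4)
  f <- mvbf(dat$Y, dat$g)
  expect_true(all(f$posterior >= 0 & f$posterior <= 1))
  expect_equal(unname(rowSums(f$posterior)), rep(1, 4), tolerance = 1e-12)
})

test_that("phenotype relabeling permutes the result without changing evidence", {
  dat <- fixture_assoc(130, d = 3)
  f1 <- mvbf(dat$Y, dat$g)
  perm <- c(3, 1, 2)
  f2 <- mvbf(dat$Y[, perm], dat$g)
  expect_equal(f1$log10_bf_av, f2$log10_bf_av, tolerance = 1e-10)
  expect_equal(f1$log10_bf_uni, f2$log10_bf_uni, tolerance = 1e-10)
  expect_equal(unname(f2$posterior), unname(f1$posterior[perm, ]),
               tolerance = 1e-10)
})

test_that("a dominating partition drives the posteriors", {
  set.seed(31)
  n <- 800
  g <- fixture_dosage(n, 0.3, seed = 12)
  Y <- cbind(a = 1.0 * g + rnorm(n), b = rnorm(n))
  f <- mvbf(Y, g)
  expect_gt(f$posterior["a", "direct"], 0.95)
  expect_gt(f$posterior["b", "unassociated"], 0.5)
})
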