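test_that("quantile transform gives the stated normal scores", {
  got <- quantile_transform(c(5.1, 2.3, 9.9))
  expect_equal(got, qnorm(c(0.5, 0.25, 0.75)), tolerance = 1e-12)
  expect_equal(got[2], -0.6744898, tolerance = 1e-6)
  x <- sort(runif(25))
  expect_equal(quantile_transform(x), qnorm((1:25) / 26), tolerance = 1e-12)
})

test_that("quantile transform is idempotent on ranks and handles ties", {
  set.seed(4)
  x <- rnorm(40)
  once <- quantile_transform(x)
  expect_equal(quantile_transform(once), once, tolerance = 1e-12)
  # midranks: tied values share the averaged-rank score
  xt <- c(1, 2, 2, 3)
  got <- quantile_transform(xt)
  expect_equal(got[2], got[3])
  expect_equal(got[2], qnorm(2.5 / 5), tolerance = 1e-12)
  expect_error(quantile_transform(rep(1, 5)), "identical")
  expect_error(quantile_transform(3), "at least 2")
})

test_that("average and difference follow the stated arithmetic", {
  # after per-stratum transformation, A = (T+P)/2 and D = T-P elementwise
  set.seed(5)
  n <- 30
  P <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  T_ <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  st <- rep("s1", n)
  ad <- build_average_difference(P, T_, st)
  Pq <- apply(P, 2, quantile_transform)
  Tq <- apply(T_, 2, quantile_transform)
  expect_equal(ad$A, (Tq + Pq) / 2, tolerance = 1e-12)
  expect_equal(ad$D, Tq - Pq, tolerance = 1e-12)
  # identical tables give D = 0 everywhere
  ad0 <- build_average_difference(P, P, st)
  expect_true(all(abs(ad0$D) < 1e-12))
})

test_that("covariate adjustment residuals are orthogonal to the design", {
  set.seed(6)
  n <- 80
  st <- rep(c("s1", "s2"), each = n / 2)
  X <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  y <- rnorm(n)
  r <- covariate_adjust(y, X, st)
  for (s in unique(st)) {
    ii <- st == s
    expect_lt(abs(sum(r[ii])), 1e-8)
    expect_lt(abs(sum(r[ii] * X$age[ii])), 1e-7)
    expect_lt(abs(sum(r[ii] * X$sex[ii])), 1e-8)
  }
  # values exactly linear in age leave zero residuals
  y2 <- 2 + 0.3 * X$age
  expect_true(all(abs(covariate_adjust(y2, X, st)) < 1e-10))
  # intercept-only regression is per-stratum centering
  r3 <- covariate_adjust(y, NULL, st)
  expect_equal(r3[st == "s1"], y[st == "s1"] - mean(y[st == "s1"]),
               tolerance = 1e-12)
})

test_that("rank-deficient designs are reported with the stratum name", {
  n <- 40
  st <- rep(c("good", "bad"), each = 20)
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  X$b[st == "bad"] <- X$a[st == "bad"]  # collinear only in one stratum
  expect_error(covariate_adjust(rnorm(n), X, st), "bad")
})

test_that("pipeline output marginals are exact normal-score sets per stratum", {
  tr <- fixture_trial(n = 140, d = 3)
  pp <- prepare_phenotypes(tr$pheno)
  for (s in unique(pp$stratum)) {
    ii <- pp$stratum == s
    ns <- sum(ii)
    ref <- qnorm(seq_len(ns) / (ns + 1))
    for (j in seq_along(pp$phenotypes)) {
      expect_equal(unname(sort(pp$A[ii, j])), ref, tolerance = 1e-12)
      expect_equal(unname(sort(pp$D[ii, j])), ref, tolerance = 1e-12)
    }
  }
})

test_that("pipeline is invariant to monotone transforms of the raw data", {
  tr <- fixture_trial(n = 100, d = 2)
  raw <- tr$pheno
  pp1 <- prepare_phenotypes(raw)
  raw2 <- raw
  raw2$Y1_pre <- exp(raw2$Y1_pre / 50)    # strictly increasing transform
  raw2$Y1_post <- 3 * raw2$Y1_post + 11
  pp2 <- prepare_phenotypes(raw2)
  expect_equal(pp1$A, pp2$A, tolerance = 1e-10)
  expect_equal(pp1$D, pp2$D, tolerance = 1e-10)
})

test_that("strata are processed independently", {
  tr <- fixture_trial(n = 120, d = 2)
  raw <- tr$pheno
  pp1 <- prepare_phenotypes(raw)
  other <- raw$stratum == "sB"
  raw2 <- raw
  raw2[other, "Y1_pre"] <- raw2[other, "Y1_pre"] * 2 + 5
  pp2 <- prepare_phenotypes(raw2)
  keep <- pp1$stratum == "sA"
  expect_equal(pp1$A[keep, ], pp2$A[keep, ], tolerance = 1e-12)
  expect_equal(pp1$D[keep, ], pp2$D[keep, ], tolerance = 1e-12)
})

test_that("incomplete data are refused", {
  tr <- fixture_trial(n = 60, d = 2)
  raw <- tr$pheno
  raw$Y1_pre[3] <- NA
  expect_error(prepare_phenotypes(raw), "complete")
})
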