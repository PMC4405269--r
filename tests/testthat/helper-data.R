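# small fixture builders shared across test files

# a polymorphic dosage vector (guaranteed all three classes for n >= 30)
fixture_dosage <- function(n, maf = 0.3, seed = 1) {
  g <- simulate_genotypes(n, maf, seed = seed)
  if (length(unique(g)) < 2) g[1:2] <- c(0L, 2L)
  g
}

# correlated phenotypes with a direct effect on column 1 and an indirect
# (mediated) effect on column 2
fixture_assoc <- function(n, beta = 0.5, loading = 0.8, d = 4, seed = 2) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    g <- fixture_dosage(n, 0.3, seed = seed + 100)
    E <- matrix(rnorm(n * d), n, d)
    Y <- E
    Y[, 1] <- Y[, 1] + beta * g
    if (d >= 2) Y[, 2] <- Y[, 2] + loading * Y[, 1]
    colnames(Y) <- paste0("Y", seq_len(d))
    list(Y = Y, g = g)
  })
}

# raw trial table for a small generic design
fixture_trial <- function(n = 150, d = 3, seed = 11, ...) {
  simulate_trial(truth_spec(n = n, d = d, strata = c("sA", "sB"),
                            seed = seed, ...))
}
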