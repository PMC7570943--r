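# Independent oracles, deliberately written with none of the package's
# internals: brute-force normal equations, a second Tanimoto implementation,
# and a from-scratch reimplementation of the linear table generator.

# OLS by explicit normal equations solve, no lm().
ols_oracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# Tanimoto by naive per-position loop.
tanimoto_oracle <- function(a, b) {
  m11 <- 0L
  m10 <- 0L
  m01 <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) m11 <- m11 + 1L
    if (a[i] == 1 && b[i] == 0) m10 <- m10 + 1L
    if (a[i] == 0 && b[i] == 1) m01 <- m01 + 1L
  }
  if (m11 + m10 + m01 == 0) return(0)
  m11 / (m11 + m10 + m01)
}

# Mean fitted R2 of the generating process, reimplemented from scratch:
# uniform integer descriptors, Gaussian noise, normal-equations fit.
mean_r2_oracle <- function(n, ranges, intercept, beta, noise_sd, reps, seed) {
  set.seed(seed)
  r2s <- replicate(reps, {
    X <- sapply(ranges, function(r) sample(seq(r[1], r[2]), n, replace = TRUE))
    y <- intercept + as.numeric(X[, names(beta)] %*% beta) +
      rnorm(n, 0, noise_sd)
    cf <- ols_oracle(X, y)
    fitted <- cbind(1, X) %*% cf
    1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  })
  mean(r2s)
}

# Small random compound table with exact or noisy linear response.
random_small_table <- function(n, descriptors, seed) {
  set.seed(seed)
  df <- data.frame(id = paste0("c", seq_len(n)))
  for (d in descriptors) df[[d]] <- sample(0:30, n, replace = TRUE)
  df$pic50 <- 5 + rowSums(df[descriptors] * 0.1) + rnorm(n, 0, 0.3)
  compound_table(df, descriptor_names = descriptors)
}

# External-validation table for celecoxib: descriptors from the candidate
# table, observed activity from the external validation table.
celecoxib_external <- function() {
  compound_table(data.frame(
    id = "Celecoxib", role = "external_validation",
    ATM = 40, ARO = 3, DONN = 1, ACC = 4, pic50 = 9.2839
  ))
}

# Absolute-difference comparison against a value printed at 4 decimals.
expect_printed <- function(actual, printed, tol = 1e-4) {
  testthat::expect_lt(max(abs(actual - printed)), tol)
}
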