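# shared fixtures built in code

# small three-cohort config used by pipeline-level tests
small_sim_config <- function(seed = 1L, beta = 0.3,
                             selector = "F>=1 & antennae>=3",
                             n_maldi = 300L, n_uhplc = 300L) {
  sim_config(
    cohorts = list(
      list(cohort_id = "M1", platform = "MALDI-MS", n_samples = n_maldi),
      list(cohort_id = "M2", platform = "MALDI-MS", n_samples = n_maldi),
      list(cohort_id = "U1", platform = "UHPLC-FD", n_samples = n_uhplc)),
    n_loci = 3, n_null_snps = 10,
    effect_map = if (beta != 0)
      list(list(locus = 1, selector = selector, beta = beta)) else list(),
    seed = seed)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

sample_excess_kurtosis <- function(x) mean((x - mean(x))^4) / stats::sd(x)^4 - 3

# brute-force normal-equations OLS oracle for y ~ 1 + x (independent of
# assoc_linear's computation path)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  coef <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% coef
  sigma2 <- sum(res^2) / (length(y) - 2)
  covb <- sigma2 * solve(t(X) %*% X)
  list(beta = unname(coef[2, 1]), se = unname(sqrt(covb[2, 2])))
}
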