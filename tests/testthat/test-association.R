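# single-variant association, harmonization, IVW meta-analysis, omnibus test

test_that("assoc_linear matches the closed form and flags degenerate input", {
  rec <- assoc_linear(c(0, 1, 2), c(1, 2, 2))
  expect_equal(rec$beta, 0.5)
  expect_equal(rec$se, sqrt((1 / 6) / 2), tolerance = 1e-12)  # 0.2887
  expect_equal(round(rec$se, 4), 0.2887)
  expect_equal(rec$p, 2 * pnorm(-abs(0.5 / rec$se)))

  mono <- assoc_linear(rep(1, 20), rnorm(20))
  expect_true(mono$untestable)
  expect_true(is.na(mono$beta))
  expect_error(assoc_linear(c(0, 1, 2), c(1, 2, 2), min_n = 10), "minimum sample")
})

test_that("assoc_linear agrees with a normal-equations oracle", {
  set.seed(100)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    x <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(x) == 0) next
    y <- rnorm(n)
    ora <- ols_oracle(x, y)
    rec <- assoc_linear(x, y)
    expect_equal(rec$beta, ora$beta, tolerance = 1e-10)
    expect_equal(rec$se, ora$se, tolerance = 1e-10)
    # matrix path agrees with the scalar path
    mat <- assoc_linear_matrix(x, cbind(t1 = y, t2 = 2 * y))
    expect_equal(mat$beta[1], rec$beta, tolerance = 1e-12)
    expect_equal(mat$se[1], rec$se, tolerance = 1e-12)
    expect_equal(mat$beta[2], 2 * rec$beta, tolerance = 1e-10)
  }
})

test_that("association p-values are calibrated under the null", {
  set.seed(200)
  g <- rbinom(2000, 2, 0.3)
  ps <- replicate(200, assoc_linear(g, rnorm(2000))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("harmonization aligns alleles, filters and logs every drop", {
  rec <- data.frame(
    variant_id = c("v1", "v1", "v1", "v1", "v2", "v2", "v2"),
    effect_allele = c("A", "T", "G", "A", "C", "C", "C"),
    other_allele  = c("T", "A", "C", "T", "T", "T", "T"),
    trait_id = "tr", cohort_id = c("c1", "c2", "c3", "c1", "c1", "c1", "c2"),
    beta = c(0.1, 0.2, 0.3, 0.1, 0.4, 0.4, 0.5),
    se = c(1, 1, 1, 1, 1, 1, 0),
    p = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    eaf = c(0.3, 0.7, 0.5, 0.3, 0.2, 0.2, 0.2),
    stringsAsFactors = FALSE)
  out <- harmonize_records(rec)
  log <- attr(out, "drop_log")
  # swapped alleles: sign flipped, eaf flipped
  c2 <- out[out$cohort_id == "c2" & out$variant_id == "v1", ]
  expect_equal(c2$beta, -0.2)
  expect_equal(c2$eaf, 0.3)
  expect_equal(c2$effect_allele, "A")
  expect_equal(unname(log["allele_mismatch"]), 1L)  # v1 c3 (G/C)
  expect_equal(unname(log["bad_se"]), 1L)           # v2 c2 se = 0
  expect_equal(unname(log["duplicate"]), 2L)        # v1 c1 and v2 c1 repeats
  # accounting: input = output + all drops
  expect_equal(nrow(rec), nrow(out) + sum(log))
  # MAF floor
  low <- rec[1, ]; low$eaf <- 0.001
  expect_equal(unname(attr(harmonize_records(low), "drop_log")["low_maf"]), 1L)
})

test_that("IVW meta-analysis pools with inverse-variance weights", {
  # equal weights: midpoint, se / sqrt(2)
  m <- ivw_meta(data.frame(beta = c(1, 3), se = c(1, 1)))
  expect_equal(m$beta, 2)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(m$se, 4), 0.7071)
  # single record unchanged
  one <- ivw_meta(data.frame(beta = 0.4, se = 0.2, n = 50))
  expect_equal(one$beta, 0.4)
  expect_equal(one$se, 0.2)
  expect_equal(one$k_cohorts, 1)
  # hand-computed unequal weights: w = (1, 4)
  m2 <- ivw_meta(data.frame(beta = c(1, 2), se = c(1, 0.5)))
  expect_equal(m2$beta, 1.8, tolerance = 1e-12)
  expect_equal(m2$se, 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(round(m2$se, 4), 0.4472)
  expect_error(ivw_meta(data.frame(beta = numeric(0), se = numeric(0))),
               "empty")
  expect_error(ivw_meta(data.frame(beta = 1, se = 0)), "positive")
})

test_that("meta of K identical cohorts shrinks se by exactly sqrt(K)", {
  for (K in c(2, 5, 10)) {
    recs <- data.frame(beta = rep(0.3, K), se = rep(0.12, K))
    m <- ivw_meta(recs)
    expect_equal(m$beta, 0.3, tolerance = 1e-12)
    expect_equal(m$se, 0.12 / sqrt(K), tolerance = 1e-12)
    expect_equal(m$Q, 0)
  }
})

test_that("omnibus test matches closed forms", {
  expect_equal(omnibus_multitrait(c(0, 0, 0), diag(3))$p, 1)
  om <- omnibus_multitrait(c(1, 1), diag(2))
  expect_equal(om$Q, 2, tolerance = 1e-12)
  expect_equal(om$p, exp(-1), tolerance = 1e-12)
  om2 <- omnibus_multitrait(c(1, 1), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(om2$Q, 4 / 3, tolerance = 1e-12)
  expect_equal(om2$p, exp(-2 / 3), tolerance = 1e-12)
  expect_equal(round(om2$p, 4), 0.5134)
  # identity correlation: exactly the sum-of-squares chi-square test
  set.seed(12)
  z <- rnorm(6)
  expect_equal(omnibus_multitrait(z, diag(6))$Q, sum(z^2), tolerance = 1e-12)
  expect_error(omnibus_multitrait(c(1, 1), matrix(c(1, 2, 3, 1), 2)),
               "symmetric")
  # rank-deficient beyond the ridge cap
  R_bad <- matrix(-1, 3, 3); diag(R_bad) <- 1
  expect_error(omnibus_multitrait(c(1, 1, 1), R_bad), "positive definite")
})

test_that("trait correlations are estimated from null variants with shrinkage", {
  set.seed(21)
  n_var <- 600
  z0 <- rnorm(n_var)
  Z <- cbind(a = sqrt(.6) * z0 + sqrt(.4) * rnorm(n_var),
             b = sqrt(.6) * z0 + sqrt(.4) * rnorm(n_var),
             c = rnorm(n_var))
  R <- estimate_trait_correlation(Z)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1), tolerance = 1e-12)
  expect_gt(R["a", "b"], 0.35)
  expect_lt(abs(R["a", "c"]), 0.2)
  # lambda = 1 collapses to identity
  expect_equal(estimate_trait_correlation(Z, lambda = 1), diag(3),
               ignore_attr = TRUE)
})

test_that("variance explained follows z^2 / (n - 2 + z^2)", {
  expect_equal(assoc_r2(0, 1, 100), 0)
  expect_equal(assoc_r2(3, 1, 100), 9 / 107, tolerance = 1e-12)
  expect_equal(round(assoc_r2(3, 1, 100), 4), 0.0841)
  # monotone in |z| at fixed n
  r2s <- assoc_r2(seq(0, 5, by = 0.5), 1, 50)
  expect_true(all(diff(r2s) > 0))
  expect_true(all(r2s >= 0 & r2s < 1))
  expect_error(assoc_r2(1, 1, 2), "exceed 2")
})

test_that("assoc_r2 recovers true variance explained at scale", {
  set.seed(77)
  n <- 10000; v <- 0.01; q <- 0.3
  r2hat <- replicate(200, {
    g <- rbinom(n, 2, q)
    b <- sqrt(v / (2 * q * (1 - q)))
    y <- b * g + rnorm(n, 0, sqrt(1 - v))
    rec <- assoc_linear(g, y)
    assoc_r2(rec$beta, rec$se, n)
  })
  se_mean <- sd(r2hat) / sqrt(length(r2hat))
  expect_lt(abs(mean(r2hat) - v), 3 * se_mean)
})
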