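# glycan composition parsing, classification, derived-trait algebra and
# phenotype preprocessing

test_that("composition codes parse, serialize and round-trip", {
  comp <- parse_composition("H5N4F1E1L1")
  expect_equal(unclass(comp),
               c(H = 5L, N = 4L, F = 1L, E = 1L, L = 1L, G = 0L))
  expect_equal(unclass(parse_composition("H9N2")),
               c(H = 9L, N = 2L, F = 0L, E = 0L, L = 0L, G = 0L))
  expect_equal(unclass(parse_composition("H5N4E1G1")),
               c(H = 5L, N = 4L, F = 0L, E = 1L, L = 0L, G = 1L))
  # letters in any order; canonical order on output, zeros omitted
  expect_identical(format(parse_composition("E2F1N4H5")), "H5N4F1E2")

  # property: parse . format = identity over random counts
  set.seed(41)
  for (i in 1:50) {
    counts <- c(H = sample(0:9, 1), N = sample(0:6, 1), F = sample(0:3, 1),
                E = sample(0:4, 1), L = sample(0:4, 1), G = sample(0:2, 1))
    if (counts["H"] == 0 && counts["N"] == 0) counts["H"] <- 1
    code <- paste0(names(counts)[counts > 0], counts[counts > 0], collapse = "")
    expect_identical(format(parse_composition(code)), code)
  }
})

test_that("malformed codes raise errors naming the offending token", {
  expect_error(parse_composition("H5X2"), "unknown letter 'X'")
  expect_error(parse_composition("H5H2"), "repeated letter 'H'")
  expect_error(parse_composition("H5N"), "missing integer after 'N'")
  expect_error(parse_composition("H5-N4"), "unparseable")
  expect_error(parse_composition("F1E2"), "at least one H or N")
})

test_that("structural classification follows the documented rule set", {
  f <- classify_glycan("H4N4F1E1")
  expect_equal(f$glycan_class, "complex")
  expect_equal(f$antennae, 2L)
  expect_true(f$core_fucosylated)
  expect_equal(f$sialyl_a26, 1L)
  expect_equal(f$sialyl_a23, 0L)

  m <- classify_glycan("H9N2")
  expect_equal(m$glycan_class, "oligomannose")
  expect_equal(m$antennae, 0L)
  expect_equal(m$sialyl_a26 + m$sialyl_a23, 0L)

  for (code in c("H3N5F1", "H4N5F1")) {
    b <- classify_glycan(code)
    expect_equal(b$glycan_class, "complex")
    expect_true(b$bisected)
    expect_equal(b$antennae, 2L)
  }
  # tri/tetra-antennary with antennary fucose
  t4 <- classify_glycan("H7N6F2E1L3")
  expect_equal(t4$antennae, 4L)
  expect_equal(t4$antennary_fucose, 1L)
  expect_equal(t4$sialyl_a23, 3L)
  # per-composition overrides beat the heuristic
  ov <- data.frame(composition = "H5N5E1", bisected = TRUE)
  expect_true(classify_glycan("H5N5E1", overrides = ov)$bisected)
})

test_that("derived-trait evaluation matches hand arithmetic", {
  peaks <- matrix(c(10, 30, 60), 1,
                  dimnames = list("s1", c("H5N4", "H5N4E1", "H5N4E2")))
  a2e <- trait_definition("A2E", "MALDI-MS", "derived",
                          numerator = "antennae=2 : E",
                          denominator = "antennae=2", scale = 2)
  expect_equal(as.numeric(evaluate_derived_trait(a2e, peaks)),
               (1 * 30 + 2 * 60) / (2 * (10 + 30 + 60)))  # 0.75

  # numerator selector matching no peak -> empty sum -> 0
  a4 <- trait_definition("A4", "MALDI-MS", "derived",
                         numerator = "antennae=4", denominator = "total")
  expect_equal(as.numeric(evaluate_derived_trait(a4, peaks)), 0)

  # total-area normalization
  two <- matrix(c(25, 75), 1, dimnames = list("s", c("H5N4", "H5N4E1")))
  norm <- normalize_total_area(two)
  expect_equal(as.numeric(norm), c(0.25, 0.75))
  expect_equal(rowSums(norm), c(s = 1))

  # zero denominator -> NA with warning, never zero
  z <- rbind(a = c(0, 0, 5), b = c(1, 2, 3))
  colnames(z) <- c("H5N4", "H5N4E1", "H9N2")
  expect_warning(v <- evaluate_derived_trait(a2e, z), "zero denominator")
  expect_true(is.na(v[["a"]]))
  expect_equal(attr(v, "n_zero_denominator"), 1L)

  # referencing an absent peak is a configuration error in strict mode
  direct <- trait_definition("H7N6E4", "UHPLC-FD", "direct",
                             numerator = "H7N6E4")
  expect_error(evaluate_derived_trait(direct, peaks), "absent from the panel")
})

test_that("direct traits sum to one per sample after normalization", {
  set.seed(7)
  raw <- matrix(rexp(5 * 8), 5, 8,
                dimnames = list(NULL, names(glyrep:::.MALDI_PANEL)[1:8]))
  defs <- lapply(colnames(raw), function(cd)
    trait_definition(cd, "MALDI-MS", "direct", numerator = cd))
  vals <- evaluate_trait_panel(defs, normalize_total_area(raw))
  expect_equal(unname(rowSums(vals)), rep(1, 5), tolerance = 1e-12)
})

test_that("covariate residualization is exact OLS", {
  # exact fit -> zero residuals
  X <- cbind(age = c(50, 60, 70, 80), sex = c(0, 1, 0, 1))
  y <- 2 + 0.1 * X[, 1] - 3 * X[, 2]
  expect_equal(residualize_covariates(y, X), rep(0, 4), tolerance = 1e-12)
  # intercept only -> centering
  y2 <- c(4, 8, 12)
  expect_equal(residualize_covariates(y2, matrix(1, 3, 1)), y2 - mean(y2))
  # closed-form small case
  expect_equal(residualize_covariates(c(1, 2, 2), cbind(x = 0:2)),
               c(-1 / 6, 1 / 3, -1 / 6), tolerance = 1e-12)
  # orthogonality to every covariate column
  set.seed(5)
  Xr <- cbind(rnorm(30), rbinom(30, 1, .5))
  r <- residualize_covariates(rnorm(30), Xr)
  expect_lt(max(abs(crossprod(cbind(1, Xr), r))), 1e-10)
  expect_error(residualize_covariates(rnorm(4), cbind(1:4, 2 * (1:4))),
               "rank-deficient")
})

test_that("rank inverse normal transform uses Blom offsets and handles ties", {
  # frozen high-precision oracle: qnorm(0.625 / 3.25)
  expect_equal(rank_inverse_normal(c(10, 20, 30)),
               c(-0.86942377328888598, 0, 0.86942377328888598),
               tolerance = 1e-12)
  # symmetric input -> output symmetric about 0
  y <- c(-3, -1, 0, 1, 3)
  out <- rank_inverse_normal(y)
  expect_equal(out, -rev(out))
  expect_equal(mean(out), 0, tolerance = 1e-12)
  # ties get averaged ranks (equal values -> equal transforms)
  tied <- rank_inverse_normal(c(1, 2, 2, 3))
  expect_equal(tied[2], tied[3])
  # monotone in ranks
  set.seed(11)
  x <- rnorm(100)
  expect_identical(order(x), order(rank_inverse_normal(x)))
  expect_error(rank_inverse_normal(rep(1, 5)), "constant")
  expect_error(rank_inverse_normal(c(1, 2)), "at least 3")
})

test_that("transformed traits are near-normal at scale", {
  set.seed(2024)
  out <- rank_inverse_normal(runif(10000))
  expect_lt(abs(sample_skewness(out)), 0.05)
  expect_lt(abs(sample_excess_kurtosis(out)), 0.1)
})

test_that("residualize + transform is invariant to affine rescaling", {
  set.seed(9)
  X <- cbind(age = rnorm(50, 60, 8), sex = rbinom(50, 1, .5))
  y <- rnorm(50)
  ref <- rank_inverse_normal(residualize_covariates(y, X))
  scaled <- rank_inverse_normal(residualize_covariates(7.3 * y - 2.1, X))
  expect_equal(scaled, ref, tolerance = 1e-12)
})

test_that("batch centering removes batch means only", {
  set.seed(3)
  batch <- rep(1:3, each = 10)
  y <- rnorm(30) + batch * 2
  out <- center_batches(y, batch)
  expect_equal(as.numeric(tapply(out, batch, mean)), rep(0, 3),
               tolerance = 1e-12)
  # within-batch variation untouched
  expect_equal(as.numeric(tapply(out, batch, stats::var)),
               as.numeric(tapply(y, batch, stats::var)))
})

test_that("trait definitions round-trip through TSV", {
  defs <- list(
    trait_definition("H5N4E2", "MALDI-MS", "direct", "H5N4E2"),
    trait_definition("A3L", "MALDI-MS", "derived",
                     "antennae=3 : L", "antennae=3", scale = 3))
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(
    trait_id = vapply(defs, `[[`, "", "trait_id"),
    platform = vapply(defs, `[[`, "", "platform"),
    kind = vapply(defs, `[[`, "", "kind"),
    numerator = vapply(defs, function(d) paste(d$numerator, collapse = ";"), ""),
    denominator = vapply(defs, function(d) paste(d$denominator, collapse = ";"), ""),
    scale = vapply(defs, `[[`, 1, "scale"))
  glyrep:::write_tsv_plain(tab, path)
  back <- read_trait_definitions(path)
  expect_equal(back, defs)
})
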