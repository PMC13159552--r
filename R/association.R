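# Per-variant, per-trait association and summary-statistic machinery:
# linear model on dosage, harmonization across cohorts, fixed-effects
# inverse-variance-weighted meta-analysis, multivariate omnibus test, and
# R^2 of association.

#' Single-variant linear association
#'
#' OLS slope of a (residualized, rank-transformed) trait on genotype dosage
#' under the additive model, with a two-sided p-value from the standard
#' normal reference for `beta/se` (the GWAS convention at the sample sizes
#' involved; at n in the thousands it is indistinguishable from the t
#' reference).
#'
#' @param dosage numeric vector of allele dosages in `[0, 2]`.
#' @param y numeric trait vector, already residualized and transformed.
#' @param variant_id,trait_id,cohort_id identifiers carried into the record.
#' @param min_n minimum sample count; below it an error is raised. The
#'   closed-form arithmetic is valid from n = 3 (the default), the pipeline
#'   applies a stricter production floor of 10.
#' @return one-row data frame (an association record): `variant_id`,
#'   `trait_id`, `cohort_id`, `beta`, `se`, `p`, `n`, `eaf`, `untestable`.
#'   A monomorphic dosage yields `untestable = TRUE` with NA estimates
#'   rather than an error.
#' @examples
#' assoc_linear(c(0, 1, 2) , c(1, 2, 2) * 1, variant_id = "v")  # beta 0.5, se 0.2887
#' @export
assoc_linear <- function(dosage, y, variant_id = NA_character_,
                         trait_id = NA_character_, cohort_id = NA_character_,
                         min_n = 3) {
  dosage <- as.numeric(dosage); y <- as.numeric(y)
  n <- length(y)
  stopifnot(length(dosage) == n)
  if (n < min_n)
    stop("n = ", n, " below minimum sample count (min_n = ", min_n, ")")
  eaf <- mean(dosage) / 2
  sxx <- sum((dosage - mean(dosage))^2)
  if (sxx == 0) {
    return(data.frame(variant_id = variant_id, trait_id = trait_id,
                      cohort_id = cohort_id, beta = NA_real_, se = NA_real_,
                      p = NA_real_, n = n, eaf = eaf, untestable = TRUE,
                      stringsAsFactors = FALSE))
  }
  beta <- sum((dosage - mean(dosage)) * y) / sxx
  resid <- y - mean(y) - beta * (dosage - mean(dosage))
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  p <- if (se == 0) .P_CLAMP_LO else 2 * stats::pnorm(-abs(beta / se))
  p <- max(p, .P_CLAMP_LO)
  data.frame(variant_id = variant_id, trait_id = trait_id,
             cohort_id = cohort_id, beta = beta, se = se, p = p, n = n,
             eaf = eaf, untestable = FALSE, stringsAsFactors = FALSE)
}

#' Vectorized association of one variant against a trait matrix
#'
#' Same model as [assoc_linear()] run against every column of `Y` at once;
#' used by the pipeline where per-trait loops would dominate runtime.
#'
#' @param dosage numeric dosage vector.
#' @param Y samples x traits numeric matrix.
#' @param variant_id,cohort_id identifiers carried into the records.
#' @return data frame with one row per trait.
#' @export
assoc_linear_matrix <- function(dosage, Y, variant_id = NA_character_,
                                cohort_id = NA_character_) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(length(dosage) == n, n >= 3)
  d <- dosage - mean(dosage)
  sxx <- sum(d^2)
  if (sxx == 0) stop("monomorphic dosage")
  beta <- as.numeric(crossprod(d, scale(Y, scale = FALSE))) / sxx
  fitted_ss <- beta^2 * sxx
  tot_ss <- colSums(scale(Y, scale = FALSE)^2)
  sigma2 <- pmax(tot_ss - fitted_ss, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  p <- pmax(2 * stats::pnorm(-abs(beta / se)), .P_CLAMP_LO)
  data.frame(variant_id = variant_id, trait_id = colnames(Y),
             cohort_id = cohort_id, beta = beta, se = se, p = p, n = n,
             eaf = mean(dosage) / 2, untestable = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harmonize association records across cohorts
#'
#' Aligns effect/other alleles to a per-variant reference (taken from the
#' first record seen), flipping `beta` signs and effect-allele frequencies
#' for swapped records, dropping irreconcilable allele pairs, deduplicating,
#' and applying summary-statistic QC filters.
#'
#' @param records data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `trait_id`, `cohort_id`, `beta`, `se`, `p`, and
#'   optionally `eaf`, `n`.
#' @param maf_floor minimum eaf-implied minor-allele frequency (default 0.01).
#' @return the aligned, filtered data frame; a named integer vector of drop
#'   reasons is attached as attribute `drop_log`
#'   (`allele_mismatch`, `bad_se`, `bad_p`, `low_maf`, `duplicate`).
#' @export
harmonize_records <- function(records, maf_floor = 0.01) {
  need <- c("variant_id", "effect_allele", "other_allele", "trait_id",
            "cohort_id", "beta", "se", "p")
  stopifnot(all(need %in% names(records)))
  rec <- records
  drop <- c(allele_mismatch = 0L, bad_se = 0L, bad_p = 0L, low_maf = 0L,
            duplicate = 0L)

  # fix reference alleles per variant from the first record
  refs <- rec[!duplicated(rec$variant_id),
              c("variant_id", "effect_allele", "other_allele")]
  names(refs)[2:3] <- c("ref_ea", "ref_oa")
  rec <- merge(rec, refs, by = "variant_id", sort = FALSE)

  match_ok <- rec$effect_allele == rec$ref_ea & rec$other_allele == rec$ref_oa
  swapped <- rec$effect_allele == rec$ref_oa & rec$other_allele == rec$ref_ea
  bad <- !(match_ok | swapped)
  drop["allele_mismatch"] <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]
  swapped <- swapped[!bad]

  rec$beta[swapped] <- -rec$beta[swapped]
  if ("eaf" %in% names(rec)) rec$eaf[swapped] <- 1 - rec$eaf[swapped]
  rec$effect_allele <- rec$ref_ea
  rec$other_allele <- rec$ref_oa
  rec$ref_ea <- rec$ref_oa <- NULL

  ok_se <- !is.na(rec$se) & rec$se > 0
  drop["bad_se"] <- sum(!ok_se)
  rec <- rec[ok_se, , drop = FALSE]
  ok_p <- !is.na(rec$p) & rec$p > 0 & rec$p <= 1
  drop["bad_p"] <- sum(!ok_p)
  rec <- rec[ok_p, , drop = FALSE]
  if ("eaf" %in% names(rec)) {
    maf <- pmin(rec$eaf, 1 - rec$eaf)
    ok_maf <- is.na(maf) | maf >= maf_floor
    drop["low_maf"] <- sum(!ok_maf)
    rec <- rec[ok_maf, , drop = FALSE]
  }
  key <- paste(rec$variant_id, rec$trait_id, rec$cohort_id, sep = "\r")
  dup <- duplicated(key)
  drop["duplicate"] <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "drop_log") <- drop
  rec
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools per-cohort effect estimates for one variant-trait pair with weights
#' `w_i = 1 / se_i^2`: pooled `beta = sum(w b) / sum(w)`,
#' `se = 1 / sqrt(sum(w))`, two-sided normal p, and Cochran heterogeneity
#' `Q = sum(w (b - beta)^2)`.
#'
#' @param records data frame of aligned association records (`beta`, `se`
#'   required; `n` summed if present).
#' @return one-row data frame: `beta`, `se`, `p`, `n`, `k_cohorts`, `Q`,
#'   plus `variant_id`/`trait_id` when unique in the input.
#' @examples
#' ivw_meta(data.frame(beta = c(1, 2), se = c(1, 0.5)))  # beta 1.8, se 0.4472
#' @export
ivw_meta <- function(records) {
  stopifnot(is.data.frame(records), all(c("beta", "se") %in% names(records)))
  if (nrow(records) == 0) stop("empty input to ivw_meta")
  if (any(records$se <= 0)) stop("all standard errors must be positive")
  w <- 1 / records$se^2
  beta <- sum(w * records$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (records$beta - beta)^2)
  out <- data.frame(beta = beta, se = se,
                    p = max(2 * stats::pnorm(-abs(beta / se)), .P_CLAMP_LO),
                    n = if ("n" %in% names(records)) sum(records$n) else NA_integer_,
                    k_cohorts = nrow(records), Q = Q)
  for (id in c("variant_id", "trait_id")) {
    if (id %in% names(records) && length(unique(records[[id]])) == 1L)
      out[[id]] <- records[[id]][1]
  }
  out
}

#' Multivariate omnibus test from single-trait summary statistics
#'
#' Tests the joint association of a variant with a group of traits from
#' their z-scores and the trait correlation matrix:
#' `Q = z' R^{-1} z ~ chi-squared(m)`. This is the standard
#' summary-statistic omnibus (asymptotically equivalent to the MANOVA-based
#' multi-trait test); output is labeled accordingly.
#'
#' @param z numeric vector of per-trait z-scores.
#' @param R trait correlation matrix; if `NULL`, estimated with
#'   [estimate_trait_correlation()] from `null_z`.
#' @param null_z optional matrix of z-scores at null variants (rows =
#'   variants) used to estimate `R`.
#' @param ridge ridge added to the diagonal (repeatedly, up to `max_ridge`)
#'   if `R` is not positive definite; additions are reported via attribute.
#' @param max_ridge cap on total ridge regularization; beyond it, error.
#' @return list with `Q`, `df`, `p`, `method`.
#' @examples
#' omnibus_multitrait(c(1, 1), diag(2))  # Q = 2, p = exp(-1)
#' @export
omnibus_multitrait <- function(z, R = NULL, null_z = NULL, ridge = 1e-6,
                               max_ridge = 0.1) {
  z <- as.numeric(z)
  m <- length(z)
  if (is.null(R)) {
    if (is.null(null_z)) stop("supply R or null_z to estimate it from")
    R <- estimate_trait_correlation(null_z)
  }
  R <- as.matrix(R)
  stopifnot(nrow(R) == m, ncol(R) == m)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  added <- 0
  repeat {
    ch <- tryCatch(chol(R + diag(added, m)), error = function(e) NULL)
    if (!is.null(ch)) break
    added <- if (added == 0) ridge else added * 10
    if (added > max_ridge)
      stop("correlation matrix not positive definite after ridge cap")
  }
  zr <- backsolve(ch, z, transpose = TRUE)
  Q <- sum(zr^2)
  structure(list(Q = Q, df = m,
                 p = stats::pchisq(Q, df = m, lower.tail = FALSE),
                 method = "chi-squared omnibus on z' R^-1 z (MANOVA-equivalent)"),
            ridge_added = added)
}

#' Estimate the trait correlation matrix from null-variant z-scores
#'
#' Correlation of per-trait z-scores across variants with no (strong)
#' association, shrunk toward the identity: `(1 - lambda) * C + lambda * I`.
#' By default only variants whose per-trait p-values all exceed `p_null` are
#' used.
#'
#' @param null_z variants x traits z-score matrix.
#' @param lambda shrinkage weight toward identity (default 0.05).
#' @param p_null variants with any per-trait `|z| > qnorm(1 - p_null/2)` are
#'   excluded (default 0.1); set to `NULL` to use all rows.
#' @return traits x traits correlation matrix.
#' @export
estimate_trait_correlation <- function(null_z, lambda = 0.05, p_null = 0.1) {
  null_z <- as.matrix(null_z)
  if (!is.null(p_null)) {
    zcut <- stats::qnorm(1 - p_null / 2)
    keep <- apply(abs(null_z) <= zcut, 1, all)
    if (sum(keep) >= max(10, ncol(null_z))) null_z <- null_z[keep, , drop = FALSE]
  }
  if (nrow(null_z) < 3) stop("too few null variants to estimate correlations")
  C <- stats::cor(null_z)
  (1 - lambda) * C + lambda * diag(ncol(null_z))
}

#' Variance explained by a single variant
#'
#' Coefficient of determination of the association implied by the test
#' statistic: with `z = beta / se`, `R^2 = z^2 / (n - 2 + z^2)`, in `[0, 1)`.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param n sample size (`n > 2`).
#' @return numeric R-squared.
#' @examples
#' assoc_r2(3, 1, 100)  # 9/107
#' @export
assoc_r2 <- function(beta, se, n) {
  stopifnot(all(se > 0))
  if (any(n <= 2)) stop("n must exceed 2")
  z2 <- (beta / se)^2
  z2 / (n - 2 + z2)
}
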