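# Phenotype preprocessing: covariate residualization, rank-based inverse
# normal transform, and a simple batch-centering stand-in.

#' Residualize a trait on covariates
#'
#' Ordinary-least-squares residuals of `y` on the covariate matrix. Standard
#' GWAS preprocessing: glycan traits are adjusted for sex and age before
#' rank transformation.
#'
#' @param y numeric vector.
#' @param covars numeric matrix of covariates, one row per sample. An
#'   intercept column is added unless one is already present.
#' @return numeric vector of residuals (orthogonal to every covariate column).
#' @examples
#' residualize_covariates(c(1, 2, 2), cbind(x = 0:2))
#' @export
residualize_covariates <- function(y, covars) {
  y <- as.numeric(y)
  covars <- as.matrix(covars)
  stopifnot(length(y) == nrow(covars))
  has_intercept <- any(apply(covars, 2, function(col) all(col == col[1] & col[1] != 0)))
  X <- if (has_intercept) covars else cbind(`(Intercept)` = 1, covars)
  if (length(y) <= ncol(X))
    stop("need more samples than covariates (n = ", length(y),
         ", covariates = ", ncol(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient covariate matrix")
  as.numeric(qr.resid(qrX, y))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their (Blom-offset) fractional ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with `c = 3/8`, ties receiving averaged
#' ranks. This is the conventional "quantile transformation to normality"
#' used on glycan traits before association testing.
#'
#' @param y numeric vector, `n >= 3`, no NAs.
#' @param offset rank offset `c`; default Blom `3/8`.
#' @return transformed vector, monotone in the ranks of `y`.
#' @examples
#' rank_inverse_normal(c(10, 20, 30))
#' @export
rank_inverse_normal <- function(y, offset = 3 / 8) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("NA values not allowed; filter first")
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  if (max(y) == min(y)) stop("constant trait cannot be rank-transformed")
  r <- rank(y, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Per-batch mean centering
#'
#' A deliberately simple stand-in for proper empirical-Bayes batch correction
#' (ComBat): subtracts each batch's mean so batch-level location shifts are
#' removed. It does not adjust batch-specific variances and is labeled as a
#' stand-in in all outputs.
#'
#' @param y numeric vector.
#' @param batch factor or vector of batch labels.
#' @return centered vector.
#' @export
center_batches <- function(y, batch) {
  y <- as.numeric(y)
  batch <- as.factor(batch)
  stopifnot(length(y) == length(batch))
  y - stats::ave(y, batch)
}
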