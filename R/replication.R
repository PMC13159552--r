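# The replication cascade: Cauchy (ACAT) aggregation of per-trait p-values
# within each platform group, Fisher product combination of the two platform
# p-values, Bonferroni decision.

.P_CLAMP_LO <- 1e-300
.P_CLAMP_HI <- 1 - 1e-16

#' Cauchy (ACAT) combination of p-values
#'
#' Aggregates a panel of p-values into one via the Cauchy combination
#' statistic `T = sum(w_i * tan((0.5 - p_i) * pi))`, whose null distribution
#' is standard Cauchy for any weights summing to one, under arbitrary
#' dependence among the tests. The combined p-value is
#' `0.5 - atan(T) / pi`. Numerical guards: the tangent term is evaluated via
#' the argument-reduced cotangent identity `1 / tanpi(p)` and replaced by the
#' pole expansion `1 / (p * pi)` for `p < 1e-15`; the combined p switches to
#' the Cauchy tail `1 / (pi * T)` once `T > 1e7` (where the arctangent form
#' starts losing relative precision); inputs are clamped into
#' `[1e-300, 1 - 1e-16]` (clamp count reported).
#'
#' @param pvalues numeric vector of p-values in (0, 1]; NAs are dropped
#'   (panel traits missing for a locus), tracked via `n_traits_used`.
#' @param weights optional non-negative weights; default equal `1/n` over the
#'   p-values actually used. Renormalized to sum to one.
#' @param strict if `TRUE`, missing (NA) p-values are an error instead of
#'   being dropped.
#' @return object of class `cauchy_result`: list with `T`, `p`,
#'   `n_traits_used`, `n_clamped`.
#' @examples
#' cauchy_combine(c(0.01, 0.2, 0.9))
#' @references Liu, Y. & Xie, J. (2020) JASA 115:393-402 (the ACAT statistic).
#' @export
cauchy_combine <- function(pvalues, weights = NULL, strict = FALSE) {
  if (length(pvalues) == 0) stop("empty p-value panel")
  keep <- !is.na(pvalues)
  if (strict && !all(keep)) stop(sum(!keep), " missing p-value(s) in strict mode")
  p <- as.numeric(pvalues[keep])
  if (length(p) == 0) stop("no non-missing p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(weights)) {
    w <- rep(1 / length(p), length(p))
  } else {
    stopifnot(length(weights) == length(pvalues))
    w <- as.numeric(weights[keep])
    if (any(w < 0)) stop("weights must be non-negative")
    if (sum(w) <= 0) stop("weights sum to zero")
    w <- w / sum(w)
  }
  n_clamped <- sum(p < .P_CLAMP_LO | p > .P_CLAMP_HI)
  p <- pmin(pmax(p, .P_CLAMP_LO), .P_CLAMP_HI)
  # tan((0.5 - p) * pi) via the cotangent identity 1 / tanpi(p): tanpi is
  # argument-reduced, so this stays accurate near the p -> 0 pole where the
  # naive form loses ~p digits; at p = 0.5 the term is exactly 0
  small <- p < 1e-15
  terms <- numeric(length(p))
  at_half <- !small & p == 0.5
  terms[!small & !at_half] <- 1 / tanpi(p[!small & !at_half])
  terms[small] <- 1 / (p[small] * pi)
  T_stat <- sum(w * terms)
  # switch to the Cauchy tail expansion well before 0.5 - atan(T)/pi loses
  # relative precision (its absolute error ~1e-16 swamps p ~ 1/(pi T) for
  # large T; at the 1e7 handover both forms are good to ~1e-9)
  p_comb <- if (T_stat > 1e7) 1 / (pi * T_stat) else 0.5 - atan(T_stat) / pi
  p_comb <- min(max(p_comb, .P_CLAMP_LO), .P_CLAMP_HI)
  structure(list(T = T_stat, p = p_comb, n_traits_used = length(p),
                 n_clamped = n_clamped),
            class = "cauchy_result")
}

#' @export
print.cauchy_result <- function(x, ...) {
  cat(sprintf("<cauchy> T = %.6g  p = %.6g  (traits used: %d)\n",
              x$T, x$p, x$n_traits_used))
  invisible(x)
}

#' Fisher product combination of two platform p-values
#'
#' Combines the two per-platform Cauchy-aggregated p-values with Fisher's
#' product test: `X2 = -2 * (log(p1) + log(p2))`, referred to chi-squared
#' with 4 degrees of freedom (2k, k = 2 independent platform groups). The
#' survival function is evaluated in the closed form
#' `exp(-X2/2) * (1 + X2/2)`, computed in log space so the result stays
#' finite and nonzero for inputs down to ~1e-300.
#'
#' @param p_groups numeric vector of exactly two p-values in (0, 1].
#' @return object of class `fisher_result`: list with `X2`, `df` (4), `p`,
#'   `log_p` (natural log, exact even when `p` underflows).
#' @examples
#' fisher_combine(c(4.25e-2, 4.59e-8))  # ~4.11e-8
#' @export
fisher_combine <- function(p_groups) {
  if (length(p_groups) != 2) stop("exactly two group p-values required")
  p <- as.numeric(p_groups)
  if (anyNA(p)) stop("NA group p-value")
  if (any(p <= 0)) stop("p = 0 input: clamp upstream (e.g. in cauchy_combine)")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  X2 <- -2 * (log(p[1]) + log(p[2]))
  log_p <- -X2 / 2 + log1p(X2 / 2)
  p_comb <- exp(log_p)
  if (p_comb == 0) p_comb <- .Machine$double.xmin  # keep nonzero; log_p is exact
  structure(list(X2 = X2, df = 4L, p = min(p_comb, 1), log_p = min(log_p, 0)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher> X2 = %.4f (df = %d)  p = %.6g\n", x$X2, x$df, x$p))
  invisible(x)
}

#' Run the full locus replication cascade
#'
#' For each locus, aggregates per-trait p-values within each platform group
#' with [cauchy_combine()], combines the two group p-values with
#' [fisher_combine()], and flags the locus replicated when the Fisher p-value
#' falls below the Bonferroni threshold `alpha / <number of loci tested>`.
#'
#' @param x either a pre-aggregated data frame with columns `locus_id`,
#'   `p_cauchy_uhplc`, `p_cauchy_maldi` (e.g. [table1_fixture()]), or a long
#'   panel data frame with columns `locus_id`, `group`, `trait_id`, `p` from
#'   which the Cauchy step is computed (group labels `"UHPLC-FD"` /
#'   `"MALDI-MS"`).
#' @param alpha family-wise error target; default 0.05.
#' @param n_loci number of loci in the Bonferroni correction; defaults to the
#'   number of loci present in `x`.
#' @param strict_traits passed to [cauchy_combine()] as `strict`.
#' @return data frame of class `replication_table`, one row per locus, sorted
#'   by genomic position when `chr`/`pos` are available (input order
#'   otherwise): `locus_id`, (any carried annotation columns), `T_uhplc`,
#'   `T_maldi` (NA for pre-aggregated input), `p_cauchy_uhplc`,
#'   `p_cauchy_maldi`, `X2`, `p_fisher`, `threshold`, `replicated`. The
#'   number of replicated loci is attached as attribute `n_replicated`.
#' @examples
#' rep_tab <- replicate_loci(table1_fixture())
#' attr(rep_tab, "n_replicated")  # 10
#' @export
replicate_loci <- function(x, alpha = 0.05, n_loci = NULL,
                           strict_traits = FALSE) {
  stopifnot(is.data.frame(x), alpha > 0, alpha < 1)
  pre_aggregated <- all(c("p_cauchy_uhplc", "p_cauchy_maldi") %in% names(x))

  if (pre_aggregated) {
    tab <- x
    tab$T_uhplc <- NA_real_
    tab$T_maldi <- NA_real_
  } else {
    need <- c("locus_id", "group", "trait_id", "p")
    if (!all(need %in% names(x)))
      stop("panel input needs columns: ", paste(need, collapse = ", "))
    groups <- unique(x$group)
    if (!setequal(groups, c("UHPLC-FD", "MALDI-MS")))
      stop("panel input must contain exactly the groups 'UHPLC-FD' and 'MALDI-MS'")
    loci <- unique(x$locus_id)
    rows <- lapply(loci, function(lc) {
      sub <- x[x$locus_id == lc, , drop = FALSE]
      per_group <- lapply(c("UHPLC-FD", "MALDI-MS"), function(g) {
        ps <- sub$p[sub$group == g]
        if (length(ps) == 0)
          stop("locus '", lc, "' has no p-values for group '", g, "'")
        cauchy_combine(ps, strict = strict_traits)
      })
      data.frame(locus_id = lc,
                 T_uhplc = per_group[[1]]$T, T_maldi = per_group[[2]]$T,
                 p_cauchy_uhplc = per_group[[1]]$p,
                 p_cauchy_maldi = per_group[[2]]$p,
                 n_traits_uhplc = per_group[[1]]$n_traits_used,
                 n_traits_maldi = per_group[[2]]$n_traits_used,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  }

  if (is.null(n_loci)) n_loci <- nrow(tab)
  stopifnot(n_loci >= nrow(tab))
  threshold <- alpha / n_loci

  fish <- lapply(seq_len(nrow(tab)), function(i)
    fisher_combine(c(tab$p_cauchy_uhplc[i], tab$p_cauchy_maldi[i])))
  tab$X2 <- vapply(fish, `[[`, numeric(1), "X2")
  tab$p_fisher <- vapply(fish, `[[`, numeric(1), "p")
  tab$threshold <- threshold
  tab$replicated <- tab$p_fisher < threshold

  if (all(c("chr", "pos") %in% names(tab)))
    tab <- tab[order(tab$chr, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_replicated") <- sum(tab$replicated)
  attr(tab, "alpha") <- alpha
  attr(tab, "n_loci_tested") <- n_loci
  class(tab) <- c("replication_table", "data.frame")
  tab
}

#' @export
print.replication_table <- function(x, ...) {
  NextMethod()
  cat(sprintf("replicated %d of %d loci at threshold %.3g (alpha = %.3g)\n",
              attr(x, "n_replicated"), attr(x, "n_loci_tested"),
              x$threshold[1], attr(x, "alpha")))
  invisible(x)
}
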