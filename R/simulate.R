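# Synthetic multi-cohort, multi-platform glycomics GWAS data with known
# ground truth.
#
# Generative model, per cohort: genotype dosages are Binomial(2, MAF) under
# Hardy-Weinberg equilibrium; each glycan peak has a latent log-abundance
#   log a_ij = baseline_j + sum_l beta_l sigma_j (g_il - 2 MAF_l) [selector l
#              matches peak j] + factor loadings + age/sex/batch terms + noise
# and observed peaks are the per-sample closure a_ij / sum_j a_ij, so direct
# traits are compositional: raising one peak necessarily lowers the others,
# as in real total-area-normalized glycomics data. Effects are scaled by the
# latent residual SD sigma_j so that configured betas are in phenotype SD
# units after rank transformation.

# default direct-peak panels: composition code -> typical relative abundance
# in total plasma N-glycome (order of magnitude realism, not calibration).
# MALDI codes carry the alpha2,6 (E) / alpha2,3 (L) distinction; UHPLC codes
# collapse all sialic acids into E.
.MALDI_PANEL <- c(
  H5N4E2 = 0.26, H5N4E1 = 0.09, H5N4E1L1 = 0.04, H5N4F1E2 = 0.05,
  H5N4F1E1 = 0.05, H4N4F1 = 0.07, H3N4F1 = 0.05, H5N4F1 = 0.03,
  H5N4 = 0.02, H4N4F1E1 = 0.02, H3N5F1 = 0.010, H4N5F1 = 0.015,
  H5N5F1E1 = 0.010, H5N5E1 = 0.010, H6N5E3 = 0.030, H6N5E2L1 = 0.025,
  H6N5E1L2 = 0.015, H6N5F1E1L2 = 0.010, H6N5F1E2L1 = 0.010,
  H7N6E2L2 = 0.008, H7N6F1E1L3 = 0.005, H7N6E1L3 = 0.004,
  H9N2 = 0.015, H8N2 = 0.010, H7N2 = 0.010, H6N2 = 0.008, H5N2 = 0.006,
  H6N3E1 = 0.008)
.UHPLC_PANEL <- c(
  H3N4F1 = 0.08, H4N4F1 = 0.10, H5N4 = 0.03, H5N4F1 = 0.04, H5N4E1 = 0.10,
  H5N4F1E1 = 0.06, H5N4E2 = 0.26, H5N4F1E2 = 0.06, H4N5F1 = 0.02,
  H3N5F1 = 0.01, H6N5E2 = 0.04, H6N5E3 = 0.05, H6N5F1E3 = 0.02,
  H7N6E4 = 0.015, H7N6F1E4 = 0.010, H9N2 = 0.015, H8N2 = 0.010,
  H7N2 = 0.010, H6N3E1 = 0.010, H5N5E1 = 0.010)

#' Default glycan trait panel for a platform
#'
#' One direct trait per panel peak (total-area-normalized relative
#' abundance) plus a set of derived traits covering the biochemically
#' coherent families the replication analysis relies on: per-antenna
#' sialylation split by linkage (MALDI only), fucosylation, antennarity
#' fractions within complex glycans, and oligomannose summaries. The panels
#' are deliberately non-identical between platforms and smaller than
#' production panels; panel-size-sensitive calibration uses
#' [simulate_null_pvalue_panels()] at full size instead.
#'
#' @param platform `"MALDI-MS"` or `"UHPLC-FD"`.
#' @return named list of [trait_definition()] objects.
#' @export
default_trait_panel <- function(platform = c("MALDI-MS", "UHPLC-FD")) {
  platform <- match.arg(platform)
  peaks <- if (platform == "MALDI-MS") .MALDI_PANEL else .UHPLC_PANEL
  defs <- lapply(names(peaks), function(cd)
    trait_definition(cd, platform, "direct", numerator = cd))
  derived <- list(
    trait_definition("CA2", platform, "derived",
                     "antennae=2", "glycan_class=='complex'"),
    trait_definition("CA3", platform, "derived",
                     "antennae=3", "glycan_class=='complex'"),
    trait_definition("CA4", platform, "derived",
                     "antennae=4", "glycan_class=='complex'"),
    trait_definition("TFuc", platform, "derived", "F>=1", "total"),
    trait_definition("TA2FS0", platform, "derived",
                     "antennae=2 & F>=1 & S==0", "total"),
    trait_definition("MM", platform, "derived",
                     "glycan_class=='oligomannose' : H",
                     "glycan_class=='oligomannose'"),
    trait_definition("A2S", platform, "derived",
                     "antennae=2 : S", "antennae=2", scale = 2),
    trait_definition("A3S", platform, "derived",
                     "antennae=3 : S", "antennae=3", scale = 3))
  if (platform == "MALDI-MS") {
    derived <- c(derived, list(
      trait_definition("A2E", platform, "derived",
                       "antennae=2 : E", "antennae=2", scale = 2),
      trait_definition("A2L", platform, "derived",
                       "antennae=2 : L", "antennae=2", scale = 2),
      trait_definition("A3E", platform, "derived",
                       "antennae=3 : E", "antennae=3", scale = 3),
      trait_definition("A3L", platform, "derived",
                       "antennae=3 : L", "antennae=3", scale = 3),
      trait_definition("A4L", platform, "derived",
                       "antennae=4 : L", "antennae=4", scale = 4)))
  }
  defs <- c(defs, derived)
  names(defs) <- vapply(defs, `[[`, "", "trait_id")
  defs
}

#' Simulation configuration
#'
#' Captures the full generative specification for synthetic glycomics GWAS
#' cohorts. Defaults emulate the replication setting: two MALDI-MS cohorts
#' totaling 3385 samples and one pooled UHPLC-FD group of 3224 samples, a
#' handful of causal loci whose effects concentrate on biochemically
#' coherent trait families, latent factors inducing compositional
#' correlation, and age/sex/batch structure.
#'
#' @param cohorts list of lists with `cohort_id`, `platform`, `n_samples`.
#' @param n_loci number of causal-candidate loci.
#' @param maf minor-allele frequency per locus, recycled, each in (0, 0.5].
#' @param n_null_snps extra unassociated SNPs (for null calibration and
#'   trait-correlation estimation).
#' @param n_factors,factor_sd latent-factor count and loading scale
#'   (loadings ~ N(0, factor_sd)).
#' @param effect_map list of lists with `locus` (index), `selector` (feature
#'   expression over [classify_glycan()] fields, see [trait_definition()]),
#'   `beta` (effect in phenotype SD units).
#' @param age_sd,sex_sd per-peak age (per year) and sex loading scales.
#' @param noise_sd residual log-abundance noise SD.
#' @param n_batches,batch_sd batch count and batch shift SD.
#' @param case_interaction multiplier on effects in type-2-diabetes cases
#'   (default 0: case status does not modify genetic effects).
#' @param seed master seed; per-cohort streams are derived at fixed offsets
#'   so adding a cohort never changes existing ones.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(cohorts = list(
                         list(cohort_id = "DiaGene", platform = "MALDI-MS",
                              n_samples = 2034L),
                         list(cohort_id = "HoornDCS", platform = "MALDI-MS",
                              n_samples = 1351L),
                         list(cohort_id = "UHPLC_pool", platform = "UHPLC-FD",
                              n_samples = 3224L)),
                       n_loci = 5, maf = c(0.30, 0.22, 0.41, 0.15, 0.35),
                       n_null_snps = 50, n_factors = 3, factor_sd = 0.35,
                       effect_map = list(
                         list(locus = 1, selector = "F>=1", beta = 0.20),
                         list(locus = 2, selector = "sialyl_a23>=1", beta = 0.15)),
                       age_sd = 0.005, sex_sd = 0.05, noise_sd = 0.8,
                       n_batches = 4, batch_sd = 0.05,
                       case_interaction = 0, seed = 1L) {
  maf <- rep_len(maf, n_loci)
  stopifnot(all(maf > 0 & maf <= 0.5),
            all(vapply(cohorts, function(co) co$n_samples >= 50, logical(1))),
            n_loci >= length(effect_map) || length(effect_map) == 0)
  for (eff in effect_map) {
    stopifnot(eff$locus >= 1, eff$locus <= n_loci)
    platforms <- unique(vapply(cohorts, `[[`, "", "platform"))
    hits <- vapply(platforms, function(pl) {
      codes <- names(if (pl == "MALDI-MS") .MALDI_PANEL else .UHPLC_PANEL)
      any(.term_weights(eff$selector, codes) != 0)
    }, logical(1))
    if (!any(hits))
      stop("effect selector '", eff$selector, "' matches no peak on any platform")
  }
  structure(list(cohorts = cohorts, n_loci = n_loci, maf = maf,
                 n_null_snps = n_null_snps, n_factors = n_factors,
                 factor_sd = factor_sd, effect_map = effect_map,
                 age_sd = age_sd, sex_sd = sex_sd, noise_sd = noise_sd,
                 n_batches = n_batches, batch_sd = batch_sd,
                 case_interaction = case_interaction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one cohort
#'
#' Draws genotypes, covariates and compositional glycan-peak abundances for
#' one configured cohort. Deterministic given the config seed; each cohort
#' uses its own derived random stream.
#'
#' @param config a [sim_config()].
#' @param cohort_id which cohort to simulate (must be in the config).
#' @return list of class `cohort_data`: `cohort_id`, `platform`, `genotypes`
#'   (samples x SNPs dosage matrix, causal loci named `locus_*`, null SNPs
#'   `null_*`), `peaks` (samples x compositions, rows summing to 1),
#'   `covariates` (data frame: `age`, `sex`, `batch`, `case_status`),
#'   `maf` (configured frequencies).
#' @export
simulate_cohort <- function(config, cohort_id) {
  stopifnot(inherits(config, "sim_config"))
  idx <- which(vapply(config$cohorts, `[[`, "", "cohort_id") == cohort_id)
  if (length(idx) != 1) stop("unknown cohort_id '", cohort_id, "'")
  co <- config$cohorts[[idx]]
  n <- co$n_samples
  panel <- if (co$platform == "MALDI-MS") .MALDI_PANEL else .UHPLC_PANEL
  codes <- names(panel)
  J <- length(codes)

  # independent stream per cohort: fixed offset on the master seed
  set.seed((config$seed + 104729L * idx) %% .Machine$integer.max)

  # genotypes under HWE
  G_loci <- vapply(config$maf, function(q) stats::rbinom(n, 2, q), numeric(n))
  G_null <- matrix(stats::rbinom(n * config$n_null_snps, 2, 0.3),
                   nrow = n)
  G <- cbind(G_loci, G_null)
  colnames(G) <- c(sprintf("locus_%d", seq_len(config$n_loci)),
                   sprintf("null_%d", seq_len(config$n_null_snps)))

  # covariates
  age <- stats::rnorm(n, 62, 9)
  sex <- stats::rbinom(n, 1, 0.5)
  batch <- sample(seq_len(config$n_batches), n, replace = TRUE)
  case_status <- stats::rbinom(n, 1, 0.7)  # T2D-enriched cohorts

  # per-peak loadings (cohort-specific realizations of shared structure)
  age_load <- stats::rnorm(J, 0, config$age_sd)
  sex_load <- stats::rnorm(J, 0, config$sex_sd)
  fac_load <- matrix(stats::rnorm(J * config$n_factors, 0, config$factor_sd),
                     nrow = J)
  batch_shift <- matrix(stats::rnorm(config$n_batches * J, 0, config$batch_sd),
                        nrow = config$n_batches)
  factors <- matrix(stats::rnorm(n * config$n_factors), nrow = n)

  # latent residual SD per peak: converts configured betas (phenotype SD
  # units) to log-abundance units
  sigma_j <- sqrt(config$noise_sd^2 + rowSums(fac_load^2))

  latent <- matrix(log(panel), n, J, byrow = TRUE)
  latent <- latent + factors %*% t(fac_load)
  latent <- latent + outer(age - mean(age), age_load) + outer(sex, sex_load)
  latent <- latent + batch_shift[batch, , drop = FALSE]
  for (eff in config$effect_map) {
    w <- .term_weights(eff$selector, codes)
    hit <- w != 0
    if (!any(hit)) next
    g <- G[, eff$locus]
    scale_mult <- 1 + config$case_interaction * case_status
    dose_c <- (g - 2 * config$maf[eff$locus]) * scale_mult
    latent[, hit] <- latent[, hit] +
      outer(dose_c, eff$beta * sigma_j[hit])
  }
  latent <- latent + matrix(stats::rnorm(n * J, 0, config$noise_sd), n, J)

  peaks <- exp(latent)
  peaks <- peaks / rowSums(peaks)
  colnames(peaks) <- codes
  sample_ids <- sprintf("%s_%05d", cohort_id, seq_len(n))
  rownames(peaks) <- rownames(G) <- sample_ids

  structure(list(cohort_id = cohort_id, platform = co$platform,
                 genotypes = G, peaks = peaks,
                 covariates = data.frame(sample_id = sample_ids, age = age,
                                         sex = sex, batch = batch,
                                         case_status = case_status,
                                         stringsAsFactors = FALSE),
                 maf = config$maf),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort %s> platform %s: %d samples, %d SNPs, %d peaks\n",
              x$cohort_id, x$platform, nrow(x$peaks), ncol(x$genotypes),
              ncol(x$peaks)))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' @param cohort a `cohort_data` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written: `genotypes.tsv`, `peaks.tsv`,
#'   `covariates.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("genotypes.tsv", "peaks.tsv", "covariates.tsv"))
  g <- data.frame(sample_id = rownames(cohort$genotypes), cohort$genotypes,
                  check.names = FALSE)
  p <- data.frame(sample_id = rownames(cohort$peaks), cohort$peaks,
                  check.names = FALSE)
  write_tsv_plain(g, paths[1])
  write_tsv_plain(p, paths[2])
  write_tsv_plain(cohort$covariates, paths[3])
  invisible(paths)
}

#' Simulate replicate panels of correlated null p-values
#'
#' For validating the Cauchy/Fisher cascade under dependence: each replicate
#' draws an equicorrelated multivariate-normal z-vector
#' (`z = sqrt(rho) z0 + sqrt(1 - rho) e`) and converts it to two-sided
#' p-values, which are marginally Uniform(0, 1) but correlated across the
#' panel.
#'
#' @param n_traits panel size per replicate.
#' @param rho equicorrelation in `[0, 1)`.
#' @param n_reps number of replicate panels.
#' @param seed RNG seed.
#' @return `n_reps` x `n_traits` matrix of p-values (0 rows when
#'   `n_reps = 0`).
#' @export
simulate_null_pvalue_panels <- function(n_traits, rho, n_reps, seed = 1L) {
  stopifnot(rho >= 0, n_traits >= 1, n_reps >= 0)
  if (rho >= 1) stop("rho must be < 1")
  set.seed(seed)
  if (n_reps == 0) return(matrix(numeric(0), 0, n_traits))
  z0 <- stats::rnorm(n_reps)
  e <- matrix(stats::rnorm(n_reps * n_traits), n_reps, n_traits)
  z <- sqrt(rho) * z0 + sqrt(1 - rho) * e
  2 * stats::pnorm(-abs(z))
}
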