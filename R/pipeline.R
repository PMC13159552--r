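# Pipeline orchestration: simulate -> derive traits -> preprocess -> per-trait
# GWAS -> meta-analysis -> Cauchy/Fisher replication cascade -> report.

#' Pipeline configuration
#'
#' @param out_dir output directory for intermediate and final TSVs.
#' @param alpha family-wise error target for the replication decision.
#' @param n_loci_tested Bonferroni denominator; default: loci present.
#' @param maf_floor QC floor on eaf-implied MAF (see [harmonize_records()]).
#' @param rint_offset rank offset for [rank_inverse_normal()].
#' @param min_n minimum per-cohort sample count for association (production
#'   floor, default 10).
#' @param strict_traits error (rather than drop) on missing panel traits.
#' @param seed master seed.
#' @param sim a [sim_config()] describing the synthetic cohorts (used by
#'   [run_pipeline()] when no external inputs are given).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("glyrep_"), alpha = 0.05,
                            n_loci_tested = NULL, maf_floor = 0.01,
                            rint_offset = 3 / 8, min_n = 10,
                            strict_traits = FALSE, seed = 1L,
                            sim = sim_config(seed = seed)) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must lie strictly between 0 and 1")
  stopifnot(maf_floor >= 0, maf_floor < 0.5, min_n >= 3,
            inherits(sim, "sim_config"))
  structure(list(out_dir = out_dir, alpha = alpha,
                 n_loci_tested = n_loci_tested, maf_floor = maf_floor,
                 rint_offset = rint_offset, min_n = min_n,
                 strict_traits = strict_traits, seed = as.integer(seed),
                 fisher_df = 4L,  # 2k with k = 2 platform groups; read-only
                 sim = sim),
            class = "pipeline_config")
}

#' Preprocess a trait matrix for association
#'
#' Residualizes every trait on the covariates (age, sex by default) and
#' applies the rank-based inverse normal transform, the standard glycomics
#' GWAS preprocessing.
#'
#' @param traits samples x traits matrix.
#' @param covariates data frame with at least `age` and `sex`.
#' @param covariate_cols covariate columns to adjust for.
#' @param offset RINT rank offset.
#' @return transformed matrix of the same shape.
#' @export
preprocess_traits <- function(traits, covariates,
                              covariate_cols = c("age", "sex"),
                              offset = 3 / 8) {
  traits <- as.matrix(traits)
  X <- as.matrix(covariates[, covariate_cols, drop = FALSE])
  stopifnot(nrow(X) == nrow(traits))
  out <- apply(traits, 2, function(y)
    rank_inverse_normal(residualize_covariates(y, X), offset = offset))
  rownames(out) <- rownames(traits)
  out
}

#' Per-cohort GWAS of all variants against all traits
#'
#' @param cohort a `cohort_data` object from [simulate_cohort()], or a list
#'   with `genotypes`, `peaks`, `covariates`, `platform`, `cohort_id`.
#' @param panel trait panel (list of [trait_definition()]); default the
#'   platform's [default_trait_panel()].
#' @param config a [pipeline_config()].
#' @return data frame of association records (one per variant x trait) with
#'   `platform` attached.
#' @export
cohort_gwas <- function(cohort, panel = NULL, config = pipeline_config()) {
  if (is.null(panel)) panel <- default_trait_panel(cohort$platform)
  traits <- evaluate_trait_panel(panel, cohort$peaks,
                                 strict = config$strict_traits)
  keep <- apply(traits, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
  traits <- traits[, keep, drop = FALSE]
  pheno <- preprocess_traits(traits, cohort$covariates,
                             offset = config$rint_offset)
  if (nrow(pheno) < config$min_n)
    stop("cohort below minimum sample count")
  recs <- lapply(colnames(cohort$genotypes), function(v) {
    g <- cohort$genotypes[, v]
    if (stats::var(g) == 0) return(NULL)  # monomorphic: untestable
    assoc_linear_matrix(g, pheno, variant_id = v,
                        cohort_id = cohort$cohort_id)
  })
  out <- do.call(rbind, recs)
  out$platform <- cohort$platform
  out
}

#' Meta-analyze association records within platform groups
#'
#' Fixed-effects IVW meta-analysis per variant x trait within each platform
#' group (cohorts measured with the same technology).
#'
#' @param records stacked association records from [cohort_gwas()] with a
#'   `platform` column.
#' @return data frame of meta records (`variant_id`, `trait_id`, `platform`,
#'   `beta`, `se`, `p`, `n`, `k_cohorts`, `Q`).
#' @export
meta_by_platform <- function(records) {
  stopifnot(all(c("variant_id", "trait_id", "platform") %in% names(records)))
  records <- records[!records$untestable, , drop = FALSE]
  key <- interaction(records$variant_id, records$trait_id, records$platform,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(sub) {
    m <- ivw_meta(sub)
    m$platform <- sub$platform[1]
    m
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble per-locus p-value panels from meta records
#'
#' @param meta output of [meta_by_platform()].
#' @param variants which variants become loci (default: those named
#'   `locus_*`; pass explicitly for real data).
#' @return long data frame (`locus_id`, `group`, `trait_id`, `p`) suitable
#'   for [replicate_loci()].
#' @export
build_panels <- function(meta, variants = NULL) {
  if (is.null(variants))
    variants <- unique(grep("^locus_", meta$variant_id, value = TRUE))
  sub <- meta[meta$variant_id %in% variants, , drop = FALSE]
  data.frame(locus_id = sub$variant_id, group = sub$platform,
             trait_id = sub$trait_id, p = sub$p, stringsAsFactors = FALSE)
}

#' Run the full synthetic replication pipeline
#'
#' Simulates every configured cohort, derives the trait panels, preprocesses,
#' runs per-cohort GWAS, meta-analyzes within platform groups, applies the
#' Cauchy/Fisher replication cascade to the configured loci, and writes the
#' report bundle plus intermediate TSVs under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the `replication_table`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohorts <- lapply(config$sim$cohorts, function(co)
    simulate_cohort(config$sim, co$cohort_id))
  records <- do.call(rbind, lapply(cohorts, function(ch) {
    write_cohort(ch, file.path(config$out_dir, ch$cohort_id))
    cohort_gwas(ch, config = config)
  }))
  write_tsv_plain(records, file.path(config$out_dir, "assoc.tsv"))

  meta <- meta_by_platform(records)
  write_tsv_plain(meta, file.path(config$out_dir, "meta.tsv"))

  panels <- build_panels(meta)
  # both platform groups must be present for the cascade
  panels$group <- ifelse(panels$group == "MALDI-MS", "MALDI-MS", "UHPLC-FD")
  write_tsv_plain(panels, file.path(config$out_dir, "panels.tsv"))

  rep_tab <- replicate_loci(panels, alpha = config$alpha,
                            n_loci = config$n_loci_tested,
                            strict_traits = config$strict_traits)
  write_report(rep_tab, config$out_dir, config = unclass(config)[
    c("alpha", "maf_floor", "rint_offset", "min_n", "seed")])
  invisible(rep_tab)
}
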