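---
title: "Cross-platform replication of plasma N-glycome QTLs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform replication of plasma N-glycome QTLs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyrep)
```

## The replication problem

A glycosylation quantitative trait locus (glyQTL) is a genomic region whose
variants associate with the abundance of N-glycan species in blood plasma.
Two analytical platforms dominate plasma glycomics: UHPLC-FD, which
quantifies chromatographic peaks, and MALDI-MS with linkage-specific sialic
acid derivatization, which quantifies monosaccharide compositions and
distinguishes α2,6-linked (ethyl-esterified, letter `E`) from α2,3-linked
(lactonized, letter `L`) sialic acids. Their trait panels overlap only
partially and cannot be matched trait-for-trait, so replicating a locus
across platforms requires aggregating evidence over each panel as a whole.

`glyrep` implements that cascade:

1. per-trait linear association of the rank-transformed trait on genotype
   dosage (additive model);
2. fixed-effects inverse-variance-weighted (IVW) meta-analysis across
   cohorts within a platform group;
3. Cauchy (ACAT) aggregation of the per-trait p-values into one p-value per
   locus per platform, $T = \sum_i w_i \tan\{(0.5 - p_i)\pi\}$ with equal
   weights $w_i = 1/n$, combined $p = 0.5 - \arctan(T)/\pi$;
4. Fisher product combination of the two platform p-values,
   $X^2 = -2(\ln p_1 + \ln p_2) \sim \chi^2_4$;
5. Bonferroni decision at $\alpha / n_\text{loci}$.

The Cauchy statistic is the linchpin: it remains (asymptotically, for small
significance levels) valid under arbitrary dependence among the aggregated
tests, which matters because glycan traits are closed compositional
quantities with strong mutual correlation.

### Why 4 degrees of freedom for Fisher's test

Fisher's product of $k$ independent p-values follows $\chi^2_{2k}$; with two
platform groups, $k = 2$ gives 4 df and the closed-form survival
$\exp(-X^2/2)(1 + X^2/2)$. Published write-ups of this cascade sometimes
typeset the statistic with a subscript 2 (the number of combined p-values);
we verified on the embedded 19-locus table that every published combined
p-value matches the 4-df closed form and none matches the 2-df form, so the
implementation fixes `df = 4` and exposes it read-only.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `alpha` | 0.05 | — | family-wise error target of the decision |
| `n_loci_tested` | number of input loci | loci | Bonferroni denominator |
| Cauchy weights | $1/n$ over available traits | — | mirrors the equal-weight aggregation; a `strict_traits` mode errors on missing traits instead of reweighting |
| RINT offset | 3/8 (Blom) | — | the GWAS-community default for "quantile transformation to normality"; ties get averaged ranks |
| `maf_floor` | 0.01 | allele frequency | summary-statistic QC floor |
| `min_n` | 10 (pipeline), 3 (function) | samples | the closed form is defined from n = 3; the pipeline applies a production floor |
| shrinkage `lambda` | 0.05 | — | shrink the null-SNP z-score correlation matrix toward identity before inversion in the omnibus test |

## Numerical choices

* **Tangent terms.** $\tan\{(0.5-p)\pi\}$ is evaluated as the
  argument-reduced cotangent `1/tanpi(p)`. The naive form loses roughly
  $16 - |\log_{10} p|$ significant digits near the pole and cannot meet a
  $10^{-6}$ accuracy target below $p \approx 5\times10^{-11}$; the cotangent
  form is accurate to machine precision for all $p$. Below $p = 10^{-15}$
  the pole expansion $1/(p\pi)$ is used (the two agree to
  $\mathcal{O}((p\pi)^2)$).
* **Combined-p tail.** $0.5 - \arctan(T)/\pi$ suffers catastrophic
  cancellation for large $T$; the implementation switches to the Cauchy tail
  $1/(\pi T)$ at $T > 10^7$, where both branches agree to about $10^{-9}$.
* **Fisher survival in log space.** $\log p = -X^2/2 + \log(1 + X^2/2)$ is
  computed first; the returned `p` stays finite and nonzero for inputs down
  to the smallest normalized doubles, and `log_p` remains exact beyond that.
* **Clamping.** p-value inputs are clamped to $[10^{-300}, 1-10^{-16}]$
  before log/tan transforms; clamp counts are reported, and a zero p-value
  input to the Fisher step is an error directing the caller to clamp
  upstream.
* **Zero denominators** in derived-trait evaluation produce missing values,
  never zeros — a fabricated zero would inject signal into compositional
  data.

## Glycan classification heuristics

MALDI compositions do not resolve isomers, so structural features are
inferred by deterministic rules: oligomannose iff `N = 2` and `H >= 4`;
bisecting GlcNAc flagged when `N >= 5` and the hexose count is too low for
all extra GlcNAcs to be galactosylated antennae (`H + 1 <= N`), matching the
canonical bisected compositions H3N5F1 and H4N5F1; antennae
`= N - 2 - bisected`, capped at 4; hybrid when antennae coexist with
`H >= N + 2`; first fucose core, further fucoses antennary on tri- and
tetra-antennary species. These defaults are overridable per composition via
an annotation table, so a curated panel can replace the heuristics without
code changes. Whether hybrid-type glycans form a separate class in
production panels is genuinely open; the classifier exposes the class but no
default trait depends on it.

## The synthetic-data generator

The generator exists to make every downstream stage testable with known
ground truth. It emulates:

* two platform groups with non-identical trait panels — by default two
  MALDI-MS cohorts (2034 + 1351 samples, the sizes of the two
  diabetes-cohort groups the MALDI analyses draw on) and one pooled UHPLC-FD
  cohort (3224 samples; per-cohort sizes of that group are not public);
* Hardy-Weinberg genotypes at configured MAFs plus unassociated null SNPs;
* genetic effects applied to **latent log-abundances** of peaks selected by
  a biochemical feature expression (e.g. `F>=1 & antennae>=3`), then closed
  compositionally (exponentiate, normalize per sample). A positive effect on
  one peak therefore induces small negative effects on all others, as in
  real total-area-normalized data;
* effect sizes in phenotype SD units: the configured β is multiplied by the
  latent residual SD (noise + factor loadings) so that the regression slope
  of the rank-transformed trait on dosage recovers β up to closure
  attenuation (a few percent when target peaks are minor species);
* latent factors inducing trait-trait correlation, age/sex/batch structure,
  and an optional case-status interaction defaulting to zero (the source
  cohorts are diabetes-enriched, but no case-modified genetic effects are
  assumed).

What it does **not** emulate: linkage disequilibrium (loci are independent),
imputation uncertainty, platform-specific measurement error models, batch
effects beyond location shifts, and full production panel sizes. The default
panels carry ~28 direct + ~13 derived MALDI-MS traits and ~20 + 8 UHPLC-FD
traits, an order of magnitude below the 167/138 production panels; the
panel-size-sensitive calibration of the cascade is therefore run on
`simulate_null_pvalue_panels()` at the full 138/167 sizes instead. A green
pipeline test establishes that the machinery is correct on data with the
stated structure — not that the generator reproduces any real cohort.

Determinism: one master seed; each cohort draws from a stream at a fixed
offset from it, so appending a cohort never changes existing ones.

## Design decisions taken where the design was open

* **Omnibus multivariate test.** The published multi-trait analyses use a
  MANOVA-based method on summary statistics whose exact statistic is not
  printed. The implementation uses the asymptotically equivalent
  $z^\top R^{-1} z \sim \chi^2_m$ omnibus with $R$ estimated from null-SNP
  z-scores (per-trait $p > 0.1$), shrunk toward identity with
  $\lambda = 0.05$, and labels its output accordingly.
* **Platform comparison.** "On average $x$ times stronger" admits at least
  three conventions — ratio of sums, mean of per-pair ratios, geometric mean
  of ratios — which differ by an order of magnitude on sparse R² tables
  (the embedded sialyltransferase table gives 12.3 by ratio of sums).
  `platform_ratio()` reports all three, excludes zero-denominator pairs with
  a count, and asserts none of them as "the" published average.
* **Batch correction.** Proper empirical-Bayes batch correction is a
  published method in its own right and is not reimplemented;
  `center_batches()` is a clearly labeled location-shift stand-in.
* **Parameter-recovery acceptance margin.** The "null loci do not replicate
  at a 10× Bonferroni margin" requirement is interpreted as: the causal
  locus must beat threshold/10 in at least 49 of 50 replicates, while null
  loci may not replicate more than 10× their nominal expectation at the
  threshold.

## Known limitations

* **Cauchy aggregation at moderate significance levels.** The ACAT validity
  guarantee is asymptotic in small α. At α = 0.05 under exchangeable
  correlation ρ ≈ 0.5 the aggregated test is measurably anti-conservative
  (the calibration suite computes panel-level rejection rates around 0.07,
  and full-cascade rates a few MC standard errors above 0.05), while ρ = 0
  and ρ = 0.9 are well calibrated. This does not affect the replication
  use-case, where decisions happen at Bonferroni-corrected thresholds deep
  in the small-α regime, but it is why one calibration expectation in the
  acceptance suite is marginal with respect to the Monte-Carlo seed.
* Derived-trait formulas follow the semantic descriptions of the trait
  families (per-antenna sialylation by linkage, antennarity fractions,
  fucosylation, oligomannose summaries); production panels defined in
  unpublished supplementary tables can be supplied via
  `read_trait_definitions()` for exact replication.
* The structural classifier is heuristic on compositions; 3-arm/6-arm
  isomers are not resolvable from MALDI codes, and no claim is made
  otherwise.
* Real-data R² tables, the published cross-platform strength ratio, and
  mass-spectrometric findings (e.g. hexuronic-acid-bearing glycans) require
  cohort-level data and instruments; they are out of desk-scale scope and
  only their printed values are used as fixtures.
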