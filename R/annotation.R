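# Locus annotation by associated glycan spectrum, platform comparison,
# evidence-tally gene prioritization, and report generation.

#' Rank the top associated traits per locus
#'
#' Sorts annotation records within each locus by descending variance
#' explained, breaking ties by ascending p-value and then lexical trait id,
#' and returns the top `k` per locus.
#'
#' @param annotations data frame with columns `locus`, `trait_id`, `r2`, and
#'   optionally `p`, `platform` and glycan feature columns (carried through).
#' @param loci loci to report; default all present. Unknown loci produce an
#'   empty block with a warning.
#' @param k traits per locus (default 3).
#' @return data frame with an added `rank` column.
#' @export
top_trait_table <- function(annotations, loci = NULL, k = 3) {
  stopifnot(all(c("locus", "trait_id", "r2") %in% names(annotations)), k >= 1)
  if (is.null(loci)) loci <- unique(annotations$locus)
  unknown <- setdiff(loci, annotations$locus)
  if (length(unknown))
    warning("no annotations for loci: ", paste(unknown, collapse = ", "))
  p <- if ("p" %in% names(annotations)) annotations$p else rep(0, nrow(annotations))
  blocks <- lapply(intersect(loci, annotations$locus), function(lc) {
    sub <- annotations[annotations$locus == lc, , drop = FALSE]
    psub <- p[annotations$locus == lc]
    ord <- order(-sub$r2, psub, sub$trait_id)
    sub <- sub[ord, , drop = FALSE][seq_len(min(k, nrow(sub))), , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    sub
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Compare association strength between platforms
#'
#' Summarizes how much stronger (or weaker) the per-locus variance explained
#' is on one platform than the other, across matched trait pairs. Because
#' "x times higher on average" admits several conventions that can differ by
#' an order of magnitude on sparse R^2 tables, all three are returned and
#' none is privileged: ratio of sums, arithmetic mean of per-pair ratios
#' (pairs with a zero denominator excluded and counted), and geometric mean
#' of ratios (pairs with a zero on either side excluded and counted).
#'
#' @param pairs data frame with numeric columns `r2_a` (numerator platform)
#'   and `r2_b` (denominator platform), one row per matched trait pair.
#' @return list with `ratio_of_sums`, `mean_of_ratios`, `geometric_mean`,
#'   `n_pairs`, `n_excluded_mean`, `n_excluded_geom`.
#' @examples
#' t2 <- table2_fixture()
#' a <- t2$r2_times_100[t2$platform == "MALDI-MS"]
#' b <- t2$r2_times_100[t2$platform == "UHPLC-FD"]
#' platform_ratio(data.frame(r2_a = a, r2_b = b))$ratio_of_sums  # ~12.3
#' @export
platform_ratio <- function(pairs) {
  stopifnot(all(c("r2_a", "r2_b") %in% names(pairs)), nrow(pairs) >= 1)
  a <- pairs$r2_a; b <- pairs$r2_b
  if (sum(b) == 0) stop("denominator platform has zero total R^2")
  ok_mean <- b > 0
  ok_geom <- a > 0 & b > 0
  if (!any(ok_mean)) stop("no pairs with nonzero denominator")
  list(ratio_of_sums = sum(a) / sum(b),
       mean_of_ratios = mean(a[ok_mean] / b[ok_mean]),
       geometric_mean = if (any(ok_geom))
         exp(mean(log(a[ok_geom] / b[ok_geom]))) else NA_real_,
       n_pairs = nrow(pairs),
       n_excluded_mean = sum(!ok_mean),
       n_excluded_geom = sum(!ok_geom))
}

#' Prioritize candidate genes from an evidence tally
#'
#' A gene is called high-confidence causal when it is expressed in at least
#' one glycoprotein-producing tissue (hepatocytes or plasma cells) and at
#' least `min_evidence` independent lines of evidence support it.
#'
#' @param evidence data frame with a `gene` column, logical (or 0/1)
#'   expression columns `hepatocytes` and `plasma_cells`, and one logical
#'   column per evidence type (all remaining columns by default).
#' @param evidence_cols names of the evidence columns; default: every column
#'   other than `gene`, `hepatocytes`, `plasma_cells`.
#' @param min_evidence required number of supporting evidence lines
#'   (default 2).
#' @return data frame of prioritized genes with their evidence counts,
#'   sorted by count (descending), then gene name.
#' @export
prioritize_genes <- function(evidence, evidence_cols = NULL, min_evidence = 2) {
  stopifnot(all(c("gene", "hepatocytes", "plasma_cells") %in% names(evidence)))
  if (is.null(evidence_cols))
    evidence_cols <- setdiff(names(evidence),
                             c("gene", "hepatocytes", "plasma_cells"))
  stopifnot(length(evidence_cols) >= 1)
  ev <- as.matrix(evidence[, evidence_cols, drop = FALSE])
  storage.mode(ev) <- "logical"
  expressed <- as.logical(evidence$hepatocytes) | as.logical(evidence$plasma_cells)
  count <- rowSums(ev)
  keep <- expressed & count >= min_evidence
  out <- data.frame(gene = evidence$gene[keep],
                    n_evidence = count[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_evidence, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the replication report bundle
#'
#' Emits the replication table, optional annotations and gene prioritization
#' as TSVs plus a human-readable Markdown summary with counts, the
#' Bonferroni threshold and per-locus verdicts. Output is deterministic for
#' identical inputs (no timestamps in the body); a tool version and a
#' configuration fingerprint are recorded.
#'
#' @param replication a `replication_table` from [replicate_loci()].
#' @param dir output directory.
#' @param annotations optional annotation data frame (written as is).
#' @param prioritization optional output of [prioritize_genes()].
#' @param config optional configuration object echoed into the fingerprint.
#' @return invisibly, the paths written.
#' @export
write_report <- function(replication, dir, annotations = NULL,
                         prioritization = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)

  rep_path <- file.path(dir, "replication.tsv")
  write_tsv_plain(as.data.frame(replication), rep_path)
  paths <- c(paths, rep_path)
  if (!is.null(annotations)) {
    p <- file.path(dir, "annotations.tsv")
    write_tsv_plain(annotations, p); paths <- c(paths, p)
  }
  if (!is.null(prioritization)) {
    p <- file.path(dir, "prioritized_genes.tsv")
    write_tsv_plain(prioritization, p); paths <- c(paths, p)
  }

  n_loci <- nrow(replication)
  n_rep <- if (n_loci > 0) sum(replication$replicated) else 0L
  fingerprint <- fnv1a32(paste(
    jsonlite::toJSON(config %||% list(), auto_unbox = TRUE, digits = NA),
    paste(capture_table(replication), collapse = "\n")))
  lines <- c(
    "# glyQTL replication report",
    "",
    sprintf("- tool: glyrep %s",
            as.character(utils::packageVersion("glyrep"))),
    sprintf("- config fingerprint: %s", fingerprint),
    sprintf("- loci tested: %d", n_loci),
    if (n_loci > 0)
      sprintf("- Bonferroni threshold: %.6g (alpha = %.3g)",
              replication$threshold[1], attr(replication, "alpha") %||% NA)
    else "- Bonferroni threshold: not applicable (zero loci)",
    sprintf("- replicated %d of %d loci", n_rep, n_loci),
    "",
    "## Per-locus verdicts", "")
  if (n_loci > 0) {
    lines <- c(lines, sprintf(
      "- %s: Fisher p = %.3g -> %s", replication$locus_id,
      replication$p_fisher,
      ifelse(replication$replicated, "REPLICATED", "not replicated")))
  } else {
    lines <- c(lines, "- zero loci in input")
  }
  md_path <- file.path(dir, "summary.md")
  writeLines(lines, md_path)
  paths <- c(paths, md_path)
  invisible(paths)
}

capture_table <- function(x) {
  utils::capture.output(utils::write.table(as.data.frame(x), sep = "\t",
                                           quote = FALSE, row.names = FALSE))
}
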