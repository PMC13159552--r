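# Trait definitions and derived-trait algebra.
#
# A direct trait is the total-area-normalized relative abundance of a single
# glycan peak. A derived trait is a weighted ratio over peaks selected by
# structural features, e.g. "alpha-2,6-sialylation per antenna within
# di-antennary glycans" = sum(E_i * peak_i over antennae==2) /
# (2 * sum(peak_i over antennae==2)).

.COMPOSITION_CODE_RE <- "^([HNFELG][0-9]+)+$"

# fields exposed to selector / weight expressions (cached per code: the same
# panel compositions are classified once, not once per trait)
.selector_field_cache <- new.env(parent = emptyenv())

.selector_env_fields <- function(code) {
  hit <- get0(code, envir = .selector_field_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- .selector_env_fields_impl(code)
  assign(code, out, envir = .selector_field_cache)
  out
}

.selector_env_fields_impl <- function(code) {
  comp <- parse_composition(code)
  feat <- classify_glycan(comp)
  list(H = comp[["H"]], N = comp[["N"]], F = comp[["F"]],
       E = comp[["E"]], L = comp[["L"]], G = comp[["G"]],
       S = comp[["E"]] + comp[["L"]],   # total sialic acids
       antennae = feat$antennae,
       bisected = feat$bisected,
       core_fucosylated = feat$core_fucosylated,
       antennary_fucose = feat$antennary_fucose,
       sialyl_a26 = feat$sialyl_a26,
       sialyl_a23 = feat$sialyl_a23,
       galactoses_on_antennae = feat$galactoses_on_antennae,
       glycan_class = feat$glycan_class)
}

# "antennae=2 & F>=1" -> "antennae==2 & F>=1": lone '=' becomes '=='
.normalize_selector <- function(sel) {
  gsub("(?<![<>=!])=(?!=)", "==", sel, perl = TRUE)
}

# Evaluate one term string over the peak panel. Returns a numeric weight per
# peak (0 where the selector does not match). Term syntax:
#   "H5N4E1"                  exact composition, weight 1
#   "H5N4E1:2"                exact composition, weight 2
#   "antennae=2 & F>=1"       feature selector, weight 1
#   "antennae=2 : E"          feature selector, per-glycan weight expression
#   "total"                   every peak, weight 1
.term_weights <- function(term, codes, strict = TRUE) {
  stopifnot(is.character(term), length(term) == 1L)
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  selector <- trimws(parts[1])
  weight_expr <- if (length(parts) >= 2) trimws(paste(parts[-1], collapse = ":")) else "1"
  w <- numeric(length(codes))

  if (identical(selector, "total")) {
    matched <- rep(TRUE, length(codes))
  } else if (grepl(.COMPOSITION_CODE_RE, selector)) {
    canon <- format(parse_composition(selector))
    matched <- vapply(codes, function(cd) format(parse_composition(cd)) == canon,
                      logical(1))
    if (strict && !any(matched))
      stop("trait definition references peak '", selector,
           "' absent from the panel")
  } else {
    sel_expr <- parse(text = .normalize_selector(selector))[[1]]
    matched <- vapply(codes, function(cd) {
      env <- list2env(.selector_env_fields(cd), parent = baseenv())
      isTRUE(eval(sel_expr, env))
    }, logical(1))
  }
  if (any(matched)) {
    w_expr <- parse(text = weight_expr)[[1]]
    w[matched] <- vapply(codes[matched], function(cd) {
      env <- list2env(.selector_env_fields(cd), parent = baseenv())
      as.numeric(eval(w_expr, env))
    }, numeric(1))
  }
  w
}

#' Define a glycan trait
#'
#' @param trait_id trait name.
#' @param platform `"UHPLC-FD"` or `"MALDI-MS"`.
#' @param kind `"direct"` or `"derived"`.
#' @param numerator,denominator character vectors of term strings (see
#'   Details). Direct traits take a single composition code numerator and the
#'   implicit `"total"` denominator.
#' @param scale positive divisor applied to the denominator, e.g. the number
#'   of antennae for per-antenna traits. Default 1.
#' @details Each term is `"selector"` or `"selector : weight"`. The selector
#'   is a composition code (exact peak), the keyword `total`, or a logical
#'   expression over structural fields (`H`, `N`, `F`, `E`, `L`, `G`, `S`,
#'   `antennae`, `bisected`, `core_fucosylated`, `antennary_fucose`,
#'   `sialyl_a26`, `sialyl_a23`, `galactoses_on_antennae`, `glycan_class`);
#'   a single `=` is accepted as equality. The weight is a number or an
#'   expression over the same fields (e.g. `E` weights each peak by its
#'   count of alpha-2,6-linked sialic acids).
#' @return a `trait_definition` object.
#' @examples
#' # alpha-2,6-sialylation per antenna within di-antennary glycans
#' trait_definition("A2E", "MALDI-MS", "derived",
#'                  numerator = "antennae=2 : E",
#'                  denominator = "antennae=2", scale = 2)
#' @export
trait_definition <- function(trait_id, platform = c("MALDI-MS", "UHPLC-FD"),
                             kind = c("derived", "direct"),
                             numerator, denominator = "total", scale = 1) {
  platform <- match.arg(platform)
  kind <- match.arg(kind)
  stopifnot(is.character(numerator), length(numerator) >= 1,
            is.character(denominator), length(denominator) >= 1,
            is.numeric(scale), length(scale) == 1L, scale > 0)
  if (kind == "direct" &&
      !(length(numerator) == 1L && grepl(.COMPOSITION_CODE_RE, numerator)))
    stop("a direct trait needs a single composition-code numerator")
  structure(list(trait_id = trait_id, platform = platform, kind = kind,
                 numerator = numerator, denominator = denominator,
                 scale = scale),
            class = "trait_definition")
}

#' Evaluate a trait over a peak-abundance matrix
#'
#' Computes `sum(numerator weights * peaks) / (scale * sum(denominator
#' weights * peaks))` per sample. Samples with a zero denominator get `NA`
#' (never a fabricated zero); the number of such samples is attached as
#' attribute `n_zero_denominator`.
#'
#' @param defn a [trait_definition()].
#' @param peaks numeric matrix or data frame, samples in rows, glycan peaks in
#'   columns named by composition code.
#' @param strict if `TRUE` (default), a composition-code term that matches no
#'   column is a configuration error; feature selectors matching nothing
#'   contribute an empty (zero) sum either way.
#' @return numeric vector, one value per sample.
#' @examples
#' peaks <- matrix(c(10, 30, 60), 1, dimnames = list("s1", c("H5N4", "H5N4E1", "H5N4E2")))
#' a2e <- trait_definition("A2E", "MALDI-MS", "derived",
#'                         "antennae=2 : E", "antennae=2", scale = 2)
#' evaluate_derived_trait(a2e, peaks)  # 0.75
#' @export
evaluate_derived_trait <- function(defn, peaks, strict = TRUE) {
  stopifnot(inherits(defn, "trait_definition"))
  peaks <- as.matrix(peaks)
  codes <- colnames(peaks)
  if (is.null(codes)) stop("peak matrix must have composition-code column names")
  w_num <- Reduce(`+`, lapply(defn$numerator, .term_weights, codes = codes,
                              strict = strict))
  w_den <- Reduce(`+`, lapply(defn$denominator, .term_weights, codes = codes,
                              strict = strict))
  num <- as.numeric(peaks %*% w_num)
  den <- defn$scale * as.numeric(peaks %*% w_den)
  zero <- den == 0
  out <- ifelse(zero, NA_real_, num / den)
  # a numerator matching nothing is an empty sum: 0, not NA
  if (all(w_num == 0)) out[!zero] <- 0
  if (any(zero))
    warning(sum(zero), " sample(s) with zero denominator for trait '",
            defn$trait_id, "' set to NA")
  attr(out, "n_zero_denominator") <- sum(zero)
  names(out) <- rownames(peaks)
  out
}

#' Total-area normalization of direct glycan peaks
#'
#' Divides each peak by the per-sample sum over the panel, yielding relative
#' abundances that sum to one (the direct traits). Samples whose total is
#' zero become `NA` rows.
#'
#' @param peaks samples x peaks matrix of non-negative abundances.
#' @return matrix of the same shape with unit row sums.
#' @export
normalize_total_area <- function(peaks) {
  peaks <- as.matrix(peaks)
  if (any(peaks < 0, na.rm = TRUE)) stop("peak abundances must be non-negative")
  tot <- rowSums(peaks)
  out <- sweep(peaks, 1, tot, "/")
  out[tot == 0, ] <- NA_real_
  out
}

#' Evaluate a panel of trait definitions
#'
#' @param defns list of [trait_definition()] objects.
#' @param peaks samples x peaks abundance matrix.
#' @param strict passed to [evaluate_derived_trait()].
#' @return samples x traits numeric matrix. Direct traits are evaluated on the
#'   total-area-normalized panel (equivalently, with the `total` denominator).
#' @export
evaluate_trait_panel <- function(defns, peaks, strict = TRUE) {
  stopifnot(length(defns) >= 1)
  vals <- vapply(defns, function(d)
    as.numeric(evaluate_derived_trait(d, peaks, strict = strict)),
    numeric(nrow(as.matrix(peaks))))
  vals <- matrix(vals, nrow = nrow(as.matrix(peaks)),
                 dimnames = list(rownames(peaks),
                                 vapply(defns, `[[`, "", "trait_id")))
  vals
}

#' Read trait definitions from TSV or JSON
#'
#' TSV columns: `trait_id`, `platform`, `kind`, `numerator`, `denominator`,
#' `scale`; multiple terms within `numerator`/`denominator` separated by `;`.
#' JSON: an array of objects with the same keys (terms as arrays).
#'
#' @param path file path.
#' @return list of [trait_definition()] objects.
#' @export
read_trait_definitions <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(raw, function(r)
      trait_definition(r$trait_id, r$platform, r$kind,
                       numerator = unlist(r$numerator),
                       denominator = unlist(r$denominator %||% "total"),
                       scale = r$scale %||% 1)))
  }
  tab <- read_tsv_plain(path)
  need <- c("trait_id", "platform", "kind", "numerator")
  if (!all(need %in% names(tab)))
    stop("trait definition table needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    trait_definition(tab$trait_id[i], tab$platform[i], tab$kind[i],
                     numerator = strsplit(tab$numerator[i], ";", fixed = TRUE)[[1]],
                     denominator = if ("denominator" %in% names(tab) &&
                                       nzchar(tab$denominator[i]))
                       strsplit(tab$denominator[i], ";", fixed = TRUE)[[1]]
                     else "total",
                     scale = if ("scale" %in% names(tab)) tab$scale[i] else 1))
}
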