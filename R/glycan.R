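# Glycan composition codes and structural classification.
#
# Composition codes are strings such as "H5N4F1E1L1": each letter is a
# monosaccharide class followed by its count. Letters:
#   H  hexose (mannose/galactose)
#   N  N-acetylhexosamine (GlcNAc)
#   F  deoxyhexose (fucose)
#   E  ethyl-esterified N-acetylneuraminic acid (alpha-2,6-linked sialic acid)
#   L  lactonized N-acetylneuraminic acid (alpha-2,3-linked sialic acid)
#   G  hexuronic acid (e.g. glucuronic acid)
# The E/L distinction arises from linkage-specific derivatization prior to
# MALDI-MS and is what lets the pipeline separate alpha-2,3- from
# alpha-2,6-sialylation genetics.

.GLYCAN_LETTERS <- c("H", "N", "F", "E", "L", "G")

#' Parse a glycan composition code
#'
#' Parses codes such as `"H5N4F1E1L1"` into monosaccharide counts. Letters may
#' appear in any order but at most once each; absent letters count zero.
#'
#' @param code character scalar, e.g. `"H5N4F1E2"`.
#' @return An object of class `glycan_composition`: a named integer vector
#'   with elements `H`, `N`, `F`, `E`, `L`, `G`.
#' @examples
#' parse_composition("H5N4F1E1L1")
#' parse_composition("H9N2")
#' @seealso [format.glycan_composition()] for the canonical serialization,
#'   [classify_glycan()] for structural features.
#' @export
parse_composition <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, !is.na(code))
  code <- trimws(code)
  if (!nzchar(code)) stop("empty composition code")
  tokens <- regmatches(code, gregexpr("[A-Za-z][0-9]*", code))[[1]]
  leftover <- gsub("[A-Za-z][0-9]*", "", code)
  if (nzchar(leftover))
    stop("malformed composition code '", code, "': unparseable token '",
         leftover, "'")
  counts <- stats::setNames(integer(length(.GLYCAN_LETTERS)), .GLYCAN_LETTERS)
  seen <- character(0)
  for (tok in tokens) {
    letter <- substr(tok, 1, 1)
    digits <- substr(tok, 2, nchar(tok))
    if (!(letter %in% .GLYCAN_LETTERS))
      stop("malformed composition code '", code, "': unknown letter '",
           letter, "'")
    if (letter %in% seen)
      stop("malformed composition code '", code, "': repeated letter '",
           letter, "'")
    if (!nzchar(digits))
      stop("malformed composition code '", code, "': missing integer after '",
           letter, "'")
    seen <- c(seen, letter)
    counts[[letter]] <- as.integer(digits)
  }
  if (counts[["H"]] <= 0 && counts[["N"]] <= 0)
    stop("invalid composition '", code, "': needs at least one H or N")
  structure(counts, class = "glycan_composition")
}

#' Canonical serialization of a glycan composition
#'
#' Letters are emitted in the fixed order H, N, F, E, L, G and zero counts are
#' omitted, so `parse_composition(format(x))` round-trips.
#'
#' @param x a `glycan_composition`.
#' @param ... ignored.
#' @return character scalar.
#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  paste0(names(nz), unname(nz), collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition>", format(x), "\n")
  invisible(x)
}

#' Classify a glycan composition into structural features
#'
#' Applies a deterministic rule set to infer structural features from a bare
#' monosaccharide composition. MALDI compositions do not resolve isomers, so
#' these are field-standard heuristics, overridable per composition:
#'
#' * oligomannose iff `N == 2` and `H >= 4` (two core GlcNAcs only);
#' * bisecting GlcNAc flagged when `N >= 5` and the hexose count is too low
#'   for all extra GlcNAcs to be galactosylated antennae (`H + 1 <= N`), e.g.
#'   H3N5F1 and H4N5F1; the bisecting GlcNAc is then not counted as an antenna;
#' * antennae `= N - 2 - bisected`, capped at 4;
#' * hybrid when antennae are present but hexoses exceed the fully
#'   galactosylated complex count (`H >= N + 2`);
#' * core fucosylation when `F >= 1`; fucoses beyond the first on tri- and
#'   tetra-antennary species are counted as antennary fucose;
#' * sialic acid counts are copied from the composition.
#'
#' @param comp a `glycan_composition` or a code string.
#' @param overrides optional data frame with a `composition` column plus any
#'   of the feature columns; matching rows replace the heuristic values,
#'   allowing exact panel-specific annotation when curated tables exist.
#' @return An object of class `glycan_features`: a list with elements
#'   `glycan_class` (`"oligomannose"`, `"hybrid"` or `"complex"`), `antennae`,
#'   `bisected`, `core_fucosylated`, `antennary_fucose`, `sialyl_a26`,
#'   `sialyl_a23`, `galactoses_on_antennae`, `hexuronic`.
#' @examples
#' classify_glycan("H4N4F1E1")   # di-antennary, core-fucosylated, a2,6-sialylated
#' classify_glycan("H9N2")       # oligomannose
#' classify_glycan("H4N5F1")     # bisected di-antennary
#' @export
classify_glycan <- function(comp, overrides = NULL) {
  if (is.character(comp)) comp <- parse_composition(comp)
  stopifnot(inherits(comp, "glycan_composition"))
  H <- comp[["H"]]; N <- comp[["N"]]; Fu <- comp[["F"]]
  E <- comp[["E"]]; L <- comp[["L"]]; G <- comp[["G"]]

  if (N == 2 && H >= 4) {
    feat <- list(
      glycan_class = "oligomannose", antennae = 0L, bisected = FALSE,
      core_fucosylated = Fu >= 1, antennary_fucose = 0L,
      sialyl_a26 = 0L, sialyl_a23 = 0L,
      galactoses_on_antennae = 0L, hexuronic = G)
  } else {
    bisected <- N >= 5 && (H + 1) <= N
    antennae <- max(min(N - 2L - as.integer(bisected), 4L), 0L)
    glycan_class <- if (antennae >= 1 && H >= N + 2) "hybrid" else "complex"
    feat <- list(
      glycan_class = glycan_class,
      antennae = antennae,
      bisected = bisected,
      core_fucosylated = Fu >= 1,
      antennary_fucose = if (antennae >= 3) max(Fu - 1L, 0L) else 0L,
      sialyl_a26 = E,
      sialyl_a23 = L,
      galactoses_on_antennae = max(min(H - 3L, antennae), 0L),
      hexuronic = G)
  }
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "composition" %in% names(overrides))
    hit <- which(overrides$composition == format(comp))
    if (length(hit) == 1L) {
      for (col in intersect(names(overrides), names(feat))) {
        v <- overrides[[col]][hit]
        if (!is.na(v)) feat[[col]] <- v
      }
    }
  }
  feat$composition <- comp
  class(feat) <- "glycan_features"
  feat
}

#' @export
print.glycan_features <- function(x, ...) {
  cat("<glycan features>", format(x$composition), "--", x$glycan_class,
      sprintf("antennae=%d%s%s F=%d E=%d L=%d\n", x$antennae,
              if (x$bisected) " bisected" else "",
              if (x$core_fucosylated) " coreF" else "",
              x$antennary_fucose, x$sialyl_a26, x$sialyl_a23))
  invisible(x)
}
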