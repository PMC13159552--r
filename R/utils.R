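# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse numbers written with a decimal comma
#'
#' Converts strings such as `"4,25E-02"` (the dialect used in some European
#' summary tables) to numeric, independently of the session locale. Plain
#' decimal-point numbers pass through unchanged.
#'
#' @param x character vector of numbers, possibly with decimal commas.
#' @return numeric vector.
#' @examples
#' parse_decimal_comma(c("4,25E-02", "0,55", "1.3"))
#' @export
parse_decimal_comma <- function(x) {
  out <- suppressWarnings(as.numeric(gsub(",", ".", trimws(x), fixed = TRUE)))
  if (anyNA(out) && !anyNA(x)) {
    bad <- x[is.na(out)]
    stop("cannot parse as number: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  out
}

# stable 32-bit FNV-1a hash of a character scalar, as 8 hex digits.
# Used to stamp reports with a configuration fingerprint without adding a
# dependency; not cryptographic.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor affects only the low byte; split into 16-bit halves to stay exact
    lo <- h %% 2^16
    h <- (h - lo) + bitwXor(as.integer(lo), b)
    # 32-bit multiply by the FNV prime, in halves within double precision
    lo <- h %% 2^16
    hi <- h %/% 2^16
    h <- (lo * prime + ((hi * prime) %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
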