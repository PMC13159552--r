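# Published replication inputs, embedded as fixtures so the downstream
# cascade is testable without downloads. Cells that were printed with a
# decimal comma are stored verbatim and parsed locale-independently.

#' The 19-locus replication input table
#'
#' Index SNPs of the 19 previously reported but unreplicated plasma N-glycome
#' QTLs, together with the per-platform Cauchy-aggregated p-values (one from
#' the UHPLC-FD cohort group, one from the MALDI-MS cohort group) and the
#' published Fisher combined p-value for reference.
#'
#' @return data frame with 19 rows and columns `locus_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `gene`, `p_cauchy_uhplc`,
#'   `p_cauchy_maldi`, `p_fisher_published`.
#' @examples
#' tab <- table1_fixture()
#' nrow(tab)  # 19
#' @export
table1_fixture <- function() {
  raw <- c(
    "rs34881159|1|161590503|A|T|FCGR2B|4,25E-02|4,59E-08|4,11E-08",
    "rs10188206|2|26142632|A|T|NDUFB4P4|6,79E-03|1,62E-02|1,11E-03",
    "rs523118|3|135965888|G|T|PCCB|1,84E-06|3,11E-04|1,27E-08",
    "rs7647487|3|196206175|C|T|RNF168|1,42E-03|4,80E-02|7,21E-04",
    "rs76360119|5|179183793|A|G|MGAT4B|2,84E-05|2,34E-05|1,47E-08",
    "rs9352006|6|74238815|A|G|MBD4|1,19E-01|1,77E-01|1,03E-01",
    "rs2881699|7|6544886|C|G|GRID2IP|1,67E-05|2,15E-02|5,68E-06",
    "rs2511737|8|103580527|A|C|ODF1|4,76E-02|1,73E-04|1,05E-04",
    "rs7866188|9|94681588|A|C|ROR2|3,89E-01|1,03E-01|1,69E-01",
    "rs2497318|10|94432000|C|T|EIF2S2P3|1,13E-01|8,07E-03|7,32E-03",
    "rs10896045|11|65555524|A|G|OVOL1|1,87E-02|3,80E-03|7,48E-04",
    "rs667633|11|114366732|C|T|NXPE2|4,10E-01|2,30E-01|3,17E-01",
    "rs1150975|12|32052422|A|C|RPLP2P4|1,68E-02|1,18E-03|2,34E-04",
    "rs7402780|15|44336044|A|G|FRMD5|6,15E-01|1,79E-02|6,07E-02",
    "rs11071549|15|60941324|G|T|RORA|9,12E-01|8,91E-01|9,81E-01",
    "rs2305479|17|38062217|C|T|GSDMB|7,22E-03|8,46E-02|5,13E-03",
    "rs56214516|17|43836953|A|C|CRHR1|2,38E-01|1,09E-02|1,81E-02",
    "rs11085197|19|6713175|C|G|C3|5,54E-02|2,64E-25|8,85E-25",
    "rs7412|19|45412079|C|T|APOE4|5,73E-01|2,10E-03|9,30E-03")
  parts <- do.call(rbind, strsplit(raw, "|", fixed = TRUE))
  data.frame(
    locus_id = parts[, 1],
    chr = as.integer(parts[, 2]),
    pos = as.integer(parts[, 3]),
    effect_allele = parts[, 4],
    other_allele = parts[, 5],
    gene = parts[, 6],
    p_cauchy_uhplc = parse_decimal_comma(parts[, 7]),
    p_cauchy_maldi = parse_decimal_comma(parts[, 8]),
    p_fisher_published = parse_decimal_comma(parts[, 9]),
    stringsAsFactors = FALSE)
}

#' Sialyltransferase-locus annotation fixture
#'
#' Published variance explained (R^2 x 100) of association between three
#' sialyltransferase loci (ST3GAL6, ST3GAL4, ST6GAL1) and seven matched
#' sialylation traits, measured on both platforms. Long format: one row per
#' trait x platform x locus cell (7 x 2 x 3 = 42 cells, 21 matched pairs).
#'
#' @return data frame with columns `trait`, `platform`, `locus`,
#'   `r2_times_100`.
#' @export
table2_fixture <- function() {
  traits <- c(
    "sialylation per antenna within all complex glycans",
    "a2,6-sialylation per antenna within diantennary glycans",
    "a2,6-sialylation per antenna within tri-antennary glycans",
    "a2,6-sialylation per antenna within tetra-antennary glycans",
    "a2,3-sialylation per antenna within diantennary glycans",
    "a2,3-sialylation per antenna within tri-antennary glycans",
    "a2,3-sialylation per antenna within tetra-antennary glycans")
  # cells per trait: uhplc (ST3GAL6, ST3GAL4, ST6GAL1) then maldi (same order)
  cells <- list(
    c("0,00", "0,55", "0,02", "0,00", "0,11", "0,03"),
    c("0,00", "0,49", "0,01", "0,05", "0,18", "0,00"),
    c("0,01", "0,04", "0,16", "0,45", "7,82", "0,15"),
    c("0,10", "1,05", "0,02", "0,61", "8,76", "0,18"),
    c("0,00", "0,49", "0,01", "0,23", "6,80", "0,01"),
    c("0,01", "0,04", "0,16", "0,64", "13,99", "0,07"),
    c("0,10", "1,05", "0,02", "0,92", "12,17", "0,11"))
  loci <- c("ST3GAL6", "ST3GAL4", "ST6GAL1")
  rows <- lapply(seq_along(traits), function(i) {
    v <- parse_decimal_comma(cells[[i]])
    data.frame(trait = traits[i],
               platform = rep(c("UHPLC-FD", "MALDI-MS"), each = 3),
               locus = rep(loci, 2),
               r2_times_100 = v,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
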