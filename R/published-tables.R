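# Reference site tables from the MirTarget analysis of gastric-cancer
# candidate genes, as printed: per-site start (or start range), free
# energy, dG/dGm ratio and length, for genes whose mRNAs carry clusters of
# binding sites in the 5'UTR, CDS and 3'UTR. These rows are the worked
# inputs for the cluster reproduction and the claim-consistency checker.

.published_rows <- function() {
  # columns: gene, nx, mirna_id, starts (printed), dG (printed),
  #          ratio (printed), length, region
  r <- function(...) list(...)
  rows <- list(
    # --- 5'UTR table -----------------------------------------------------
    r("ARID1A", 19.5, "ID02106.3p-miR", "136", "-123", "89", 23, "5UTR"),
    r("ARID1A", 19.5, "ID01778.3p-miR", "140", "-134", "90", 24, "5UTR"),
    r("ARID1A", 19.5, "ID00296.3p-miR", "141, 166", "-138", "88", 25, "5UTR"),
    r("ARID1A", 19.5, "miR-6081", "143", "-125", "89", 24, "5UTR"),
    r("ARID1A", 19.5, "ID01702.3p-miR", "147", "-134", "89", 24, "5UTR"),
    r("ARID1A", 19.5, "ID00465.5p-miR", "148", "-113", "93", 20, "5UTR"),
    r("ARID1A", 19.5, "ID01377.3p-miR", "152", "-117", "92", 20, "5UTR"),
    r("ARID1A", 19.5, "ID02592.5p-miR", "164, 167", "-123", "89", 23, "5UTR"),
    r("ARID1A", 19.5, "miR-3960", "167", "-115", "92", 20, "5UTR"),
    r("ARID1A", 19.5, "ID03065.3p-miR", "172", "-115", "92", 21, "5UTR"),
    r("E2F1", 3.4, "ID02574.3p-miR", "84", "-115", "93", 20, "5UTR"),
    r("E2F1", 3.4, "ID02052.5p-miR", "85", "-149", "100", 24, "5UTR"),
    r("E2F1", 3.4, "ID01873.3p-miR", "87", "-123", "94", 21, "5UTR"),
    r("E2F1", 3.4, "miR-3960", "90", "-115", "92", 20, "5UTR"),
    r("E2F1", 3.4, "ID00071.3p-miR", "90", "-117", "92", 20, "5UTR"),
    r("E2F1", 3.4, "ID00722.5p-miR", "90", "-113", "93", 20, "5UTR"),
    r("E2F1", 3.4, "ID02064.5p-miR", "95", "-132", "91", 23, "5UTR"),
    r("ODC1", 19.2, "ID00756.3p-miR", "9", "-129", "94", 23, "5UTR"),
    r("ODC1", 19.2, "ID01804.3p-miR", "13", "-132", "90", 23, "5UTR"),
    r("ODC1", 19.2, "ID02187.5p-miR", "14", "-123", "89", 23, "5UTR"),
    r("ODC1", 19.2, "ID00457.3p-miR", "15, 21", "-123, -125", "91, 92", 22,
      "5UTR"),
    r("ODC1", 19.2, "ID02084.3p-miR", "17", "-140", "93", 24, "5UTR"),
    r("ODC1", 19.2, "ID02064.5p-miR", "17 ÷ 23 (3)",
      "-129 ÷ -140", "90 ÷ 97", 23, "5UTR"),
    r("ODC1", 19.2, "miR-3960", "18 ÷ 21 (3)", "-115", "92", 20, "5UTR"),
    r("ODC1", 19.2, "ID01652.3p-miR", "19", "-125", "89", 23, "5UTR"),
    r("ODC1", 19.2, "ID02538.3p-miR", "19", "-123", "92", 22, "5UTR"),
    r("ODC1", 19.2, "ID01702.3p-miR", "19, 22", "-134, -142", "89, 94", 24,
      "5UTR"),
    r("ODC1", 19.2, "ID02229.3p-miR", "21", "-121", "92", 21, "5UTR"),
    r("ODC1", 19.2, "ID02499.3p-miR", "21", "-119", "92", 21, "5UTR"),
    r("ODC1", 19.2, "ID01157.5p-miR", "22", "-117", "93", 20, "5UTR"),
    r("ODC1", 19.2, "ID01377.3p-miR", "23", "-121", "95", 20, "5UTR"),
    r("ODC1", 19.2, "ID00061.3p-miR", "24", "-125", "91", 22, "5UTR"),
    r("PIK3CA", 10.6, "ID00296.3p-miR", "1", "-134", "85", 25, "5UTR"),
    r("PIK3CA", 10.6, "ID01190.5p-miR", "4", "-140", "92", 24, "5UTR"),
    r("PIK3CA", 10.6, "ID01702.3p-miR", "4", "-140", "93", 24, "5UTR"),
    r("PIK3CA", 10.6, "ID01895.5p-miR", "4", "-132", "89", 24, "5UTR"),
    r("PIK3CA", 10.6, "ID01641.3p-miR", "5", "-127", "86", 24, "5UTR"),
    r("PIK3CA", 10.6, "ID00966.5p-miR", "6", "-136", "90", 24, "5UTR"),
    r("PIK3CA", 10.6, "ID00030.3p-miR", "7", "-121", "90", 22, "5UTR"),
    r("PIK3CA", 10.6, "ID02294.5p-miR", "7", "-125", "86", 24, "5UTR"),
    r("PIK3CA", 10.6, "ID01804.3p-miR", "8", "-134", "91", 23, "5UTR"),
    r("PIK3CA", 10.6, "ID01873.3p-miR", "8", "-123", "94", 21, "5UTR"),
    r("PIK3CA", 10.6, "ID02064.5p-miR", "9", "-127", "88", 23, "5UTR"),
    r("PIK3CA", 10.6, "ID02084.3p-miR", "9", "-129", "86", 24, "5UTR"),
    r("TBC1D9", 10.0, "ID01895.5p-miR", "125", "-134", "90", 24, "5UTR"),
    r("TBC1D9", 10.0, "ID02187.5p-miR", "130", "-127", "92", 23, "5UTR"),
    r("TBC1D9", 10.0, "ID03229.5p-miR", "130, 133", "-121", "90", 22,
      "5UTR"),
    r("TBC1D9", 10.0, "ID01041.5p-miR", "132", "-132", "90", 24, "5UTR"),
    r("TBC1D9", 10.0, "ID01702.3p-miR", "136", "-140", "93", 24, "5UTR"),
    r("TBC1D9", 10.0, "ID02084.3p-miR", "137", "-136", "90", 24, "5UTR"),
    r("TBC1D9", 10.0, "ID00457.3p-miR", "138", "-125", "92", 22, "5UTR"),
    # --- CDS table -------------------------------------------------------
    r("ARID1A", 19.5, "ID02052.5p-miR", "410", "-132", "89", 24, "CDS"),
    r("ARID1A", 19.5, "ID00522.5p-miR", "410", "-127", "91", 23, "CDS"),
    r("ARID1A", 19.5, "ID02187.5p-miR", "411", "-127", "92", 23, "CDS"),
    r("ARID1A", 19.5, "ID02692.5p-miR", "413", "-127", "90", 23, "CDS"),
    r("ARID1A", 19.5, "ID00457.3p-miR", "415", "-125", "92", 22, "CDS"),
    r("ARID1A", 19.5, "ID02064.5p-miR", "417", "-134", "93", 23, "CDS"),
    r("ARID1A", 19.5, "ID02084.3p-miR", "418", "-138", "92", 24, "CDS"),
    r("ARID1A", 19.5, "ID02538.3p-miR", "420", "-125", "94", 22, "CDS"),
    r("ARID1A", 19.5, "ID01704.5p-miR", "471", "-123", "89", 23, "CDS"),
    r("ARID1A", 19.5, "ID02761.3p-miR", "487, 493", "-134, -140", "90, 94",
      24, "CDS"),
    r("ARID1A", 19.5, "ID00756.3p-miR", "843", "-125", "91", 23, "CDS"),
    r("ARID1A", 19.5, "ID02294.5p-miR", "851", "-129", "88", 24, "CDS"),
    r("ARID1A", 19.5, "ID00061.3p-miR", "852", "-125", "91", 22, "CDS"),
    r("E2F1", 3.4, "ID02051.3p-miR", "291", "-153", "100", 24, "CDS"),
    r("E2F1", 3.4, "ID03448.3p-miR", "292", "-123", "91", 22, "CDS"),
    r("E2F1", 3.4, "ID01157.5p-miR", "295", "-117", "93", 20, "CDS"),
    r("MAPK1", 17.2, "ID03332.3p-miR", "243", "-134", "90", 24, "CDS"),
    r("MAPK1", 17.2, "ID01310.3p-miR", "244", "-121", "92", 22, "CDS"),
    r("MAPK1", 17.2, "ID00798.3p-miR", "246", "-136", "91", 24, "CDS"),
    r("MAPK1", 17.2, "ID01546.5p-miR", "246", "-132", "90", 24, "CDS"),
    r("TERT", 0.4, "ID01098.3p-miR", "3224", "-125", "89", 24, "CDS"),
    r("TERT", 0.4, "ID01338.5p-miR", "3236", "-132", "91", 24, "CDS"),
    r("TERT", 0.4, "ID01816.3p-miR", "3237", "-138", "92", 24, "CDS"),
    r("VEGFC", 0.4, "ID02052.5p-miR", "498", "-132", "89", 24, "CDS"),
    r("VEGFC", 0.4, "ID02187.5p-miR", "500", "-123", "89", 23, "CDS"),
    r("VEGFC", 0.4, "ID01041.5p-miR", "501", "-132", "90", 24, "CDS"),
    r("VEGFC", 0.4, "ID01873.3p-miR", "501", "-123", "94", 21, "CDS"),
    r("VEGFC", 0.4, "ID00457.3p-miR", "503", "-127", "94", 22, "CDS"),
    r("VEGFC", 0.4, "miR-3960", "504", "-115", "92", 20, "CDS"),
    r("VEGFC", 0.4, "ID02064.5p-miR", "505", "-129", "90", 23, "CDS"),
    # --- 3'UTR table -----------------------------------------------------
    r("ATM", 8.9, "ID03006.5p-miR", "9778", "-121", "89", 24, "3UTR"),
    r("ATM", 8.9, "miR-5095", "9787", "-108", "93", 21, "3UTR"),
    r("ATM", 8.9, "miR-619-5p", "9793", "-119", "98", 22, "3UTR"),
    r("ATM", 8.9, "miR-5096", "9882", "-104", "92", 21, "3UTR"),
    r("ATM", 8.9, "miR-5585-3p", "9950", "-110", "95", 22, "3UTR"),
    r("ATM", 8.9, "miR-1273a", "11054", "-119", "90", 25, "3UTR"),
    r("ATM", 8.9, "miR-1273g-3p", "11076", "-113", "96", 21, "3UTR"),
    r("ATM", 8.9, "miR-1273e", "11119", "-108", "93", 22, "3UTR"),
    r("ATM", 8.9, "miR-5585-5p", "11156", "-106", "91", 22, "3UTR"),
    r("FLT1", 4.6, "ID01030.3p-miR", "6909 ÷ 6923 (7)",
      "-108 ÷ -110", "89 ÷ 91", 23, "3UTR"),
    r("FLT1", 4.6, "miR-466", "6911 ÷ 6937 (9)", "-106 ÷ -108",
      "89 ÷ 93", 23, "3UTR"),
    r("FLT1", 4.6, "ID00436.3p-miR", "6913 ÷ 6925 (7)", "-104", "89",
      23, "3UTR"),
    r("IGF1", 5.9, "ID00470.5p-miR", "4042 ÷ 4058 (9)", "-108", "89",
      23, "3UTR"),
    r("IGF1", 5.9, "miR-574-5p", "4042 ÷ 4062 (11)",
      "-108 ÷ -113", "89 ÷ 93", 23, "3UTR"),
    r("IGF1", 5.9, "miR-1273g-3p", "6009", "-113", "96", 21, "3UTR"),
    r("IGF1", 5.9, "miR-1273f", "6042", "-102", "98", 19, "3UTR"),
    r("IGF1", 5.9, "miR-1273d", "6043", "-119", "87", 25, "3UTR"),
    r("IGF1", 5.9, "miR-1273e", "6052", "-108", "93", 22, "3UTR"),
    r("IGF2", 3.2, "ID00470.5p-miR", "2286 ÷ 2351 (6)",
      "-108 ÷ -113", "89 ÷ 93", 23, "3UTR"),
    r("IGF2", 3.2, "miR-574-5p", "2288, 2290", "-108", "89", 23, "3UTR"),
    r("IGF2", 3.2, "miR-574-5p", "2397 ÷ 2408 (4)",
      "-108 ÷ -113", "89 ÷ 93", 23, "3UTR"),
    r("IGF2", 3.2, "ID00470.5p-miR", "2404, 2412", "-110", "91", 23, "3UTR"),
    r("IGF2", 3.2, "ID00470.5p-miR", "2442 ÷ 2463 (3)",
      "-108 ÷ -113", "89 ÷ 93", 23, "3UTR"),
    r("IGF2", 3.2, "miR-574-5p", "2465, 2484", "-108", "89", 23, "3UTR"),
    r("IGF2", 3.2, "ID00470.5p-miR", "2520 ÷ 2539 (3)", "-108", "89",
      23, "3UTR"),
    r("IGF2", 3.2, "miR-574-5p", "2522", "-108", "89", 23, "3UTR"),
    r("IGF2", 3.2, "ID00470.5p-miR", "2655 ÷ 2672 (3)",
      "-108 ÷ -110", "89 ÷ 91", 23, "3UTR"),
    r("IGF2", 3.2, "ID00470.5p-miR", "2704, 2725", "-108", "89", 23, "3UTR"),
    r("IGF2", 3.2, "miR-574-5p", "2727, 2731", "-108, -110", "89, 91", 23,
      "3UTR"),
    r("JAK2", 14.1, "miR-466", "5182 ÷ 5200 (10)", "-104 ÷ -106",
      "89 ÷ 91", 23, "3UTR"),
    r("JAK2", 14.1, "ID01030.3p-miR", "5184 ÷ 5200 (9)", "-108", "89",
      23, "3UTR"),
    r("JAK2", 14.1, "ID00436.3p-miR", "5184 ÷ 5202 (10)",
      "-104 ÷ -106", "89 ÷ 91", 23, "3UTR"),
    r("SP1", 18.8, "miR-466", "4145 ÷ 4161 (9)", "-104 ÷ -106",
      "89 ÷ 91", 23, "3UTR"),
    r("SP1", 18.8, "ID01030.3p-miR", "4147 ÷ 4159 (7)", "-108", "89",
      23, "3UTR"),
    r("SP1", 18.8, "ID00436.3p-miR", "4147 ÷ 4161 (8)",
      "-104 ÷ -106", "89 ÷ 91", 23, "3UTR"),
    r("XRCC1", 17.2, "miR-574-5p", "2033 ÷ 2055 (11)",
      "-108 ÷ -113", "89 ÷ 93", 23, "3UTR"),
    r("XRCC1", 17.2, "ID00470.5p-miR", "2035 ÷ 2055 (9)",
      "-108 ÷ -113", "89 ÷ 93", 23, "3UTR"),
    r("ZEB1", 14.8, "miR-574-5p", "3587 ÷ 3605 (10)", "-113", "93",
      23, "3UTR"),
    r("ZEB1", 14.8, "ID00470.5p-miR", "3587 ÷ 3605 (10)", "-108",
      "89", 23, "3UTR")
  )
  tibble::tibble(
    gene = vapply(rows, `[[`, character(1), 1),
    nx = vapply(rows, `[[`, numeric(1), 2),
    mirna_id = vapply(rows, `[[`, character(1), 3),
    starts = vapply(rows, `[[`, character(1), 4),
    dG = vapply(rows, `[[`, character(1), 5),
    ratio = vapply(rows, `[[`, character(1), 6),
    length = as.integer(vapply(rows, `[[`, numeric(1), 7)),
    region = vapply(rows, `[[`, character(1), 8)
  )
}

#' Published binding-site rows (as printed)
#'
#' The reference site tables for 5'UTR, CDS and 3'UTR clusters of
#' gastric-cancer candidate genes, one row per printed table row with the
#' start, dG and ratio columns kept in printed (possibly range) notation.
#'
#' @param region Optional filter: `"5UTR"`, `"CDS"` or `"3UTR"`.
#' @return A tibble `gene`, `nx`, `mirna_id`, `starts`, `dG`, `ratio`,
#'   `length`, `region`.
#' @seealso [published_sites()] for the expanded one-row-per-start form.
#' @export
published_site_rows <- function(region = NULL) {
  x <- .published_rows()
  if (!is.null(region)) x <- x[x$region %in% region, , drop = FALSE]
  x
}

# linear interpolation of a printed value range across n expanded starts
.interp_values <- function(s, n) {
  s <- gsub("÷", ",", s)
  v <- as.numeric(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (length(v) == 1) return(rep(v, n))
  if (length(v) == n) return(v)
  seq(v[1], v[length(v)], length.out = n)
}

#' Published binding sites, one row per start
#'
#' Expands the printed rows of [published_site_rows()] into individual
#' sites: a printed range `a ÷ b (n)` yields `n` evenly spaced rounded
#' starts (the inner starts are not printed; even spacing is the
#' documented convention), and printed dG/ratio ranges are linearly
#' interpolated across the expanded starts (representative values only).
#' Each printed start is one interval — the convention under which the
#' published summed cluster lengths reproduce.
#'
#' @inheritParams published_site_rows
#' @return A sites tibble: `mirna_id`, `gene`, `start`, `length`, `dG`,
#'   `ratio_pct`, `region`, `nx`.
#' @export
published_sites <- function(region = NULL) {
  rows <- published_site_rows(region)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    rr <- rows[i, ]
    st <- expand_start_range(rr$starts)[[1]]
    n <- length(st)
    tibble::tibble(
      mirna_id = rr$mirna_id, gene = rr$gene, start = st,
      length = rr$length,
      dG = .interp_values(rr$dG, n),
      ratio_pct = .interp_values(rr$ratio, n),
      region = rr$region, nx = rr$nx
    )
  })
  dplyr::bind_rows(out)
}

#' Published cluster claims
#'
#' The cluster-level statements accompanying the reference tables: printed
#' span (nt), printed summed site length (nt) where stated, and printed
#' compaction ratio, per gene and region. Input for
#' [check_cluster_claims()].
#'
#' @return A tibble `gene`, `region`, `span_printed`, `sum_len_printed`,
#'   `compaction_printed` (`NA` where not stated).
#' @export
published_cluster_claims <- function() {
  tibble::tribble(
    ~gene, ~region, ~span_printed, ~sum_len_printed, ~compaction_printed,
    "ARID1A", "5UTR", 57L, 272L, 4.8,
    "E2F1", "5UTR", 35L, 148L, 4.2,
    "ODC1", "5UTR", 38L, NA_integer_, 10.6,
    "PIK3CA", "5UTR", 33L, 282L, 8.5,
    "TBC1D9", "5UTR", 37L, NA_integer_, 5.0,
    "ARID1A", "CDS", 32L, 184L, 5.8,
    "MAPK1", "CDS", 28L, NA_integer_, 2.9,
    "VEGFC", "CDS", 31L, NA_integer_, 5.1
  )
}

#' Published miRNA-to-alternative-gene associations
#'
#' The reference association table: miRNAs with two or more alternative
#' candidate target genes.
#'
#' @return A tibble `mirna_id`, `genes` (list-column), `n_genes`.
#' @export
published_alternatives <- function() {
  x <- tibble::tribble(
    ~mirna_id, ~genes,
    "ID02064.5p-miR", c("ARID1A", "E2F1", "NFKB1", "ODC1", "TDFB1", "VEGFC"),
    "miR-3960", c("ARID1A", "CDX2", "E2F1", "ODC1", "VEGFC"),
    "ID02052.5p-miR", c("CDX2", "DNMT1", "E2F1", "VEGFC"),
    "ID01041.5p-miR", c("CDX2", "TBC1D9", "VEGFC"),
    "ID02761.3p-miR", c("ARID1A", "EZH2", "PTEN"),
    "ID01702.3p-miR", c("ARID1A", "PIC3CA", "TBC1D9"),
    "ID01895.5p-miR", c("PIC3CA", "CDX2", "TBC1D9"),
    "ID03332.3p-miR", c("KRAS", "MAPK1", "SIRT1"),
    "ID00296.3p-miR", c("ARID1A", "TGFB1"),
    "ID02084.5p-miR", c("ARID1A", "ODC1")
  )
  x$n_genes <- lengths(x$genes)
  x
}
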