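# Sliding-window site scan: score every window of each transcript against
# each miRNA, keep windows whose dG/dGm ratio reaches the threshold.

# Per-start hydrogen-bond and paired-position counts of every window of
# `tx_idx` (encoded transcript) against `m_idx` (encoded miRNA), antiparallel.
# Vectorized over starts: for each miRNA position, one lookup over the whole
# transcript, accumulated with an offset.
.window_counts <- function(m_idx, tx_idx) {
  m <- length(m_idx)
  L <- length(tx_idx)
  n_win <- L - m + 1L
  if (n_win < 1L) {
    return(list(hbonds = integer(0), paired = integer(0)))
  }
  m_anti <- rev(m_idx)
  hb <- numeric(n_win)
  pr <- numeric(n_win)
  for (i in seq_len(m)) {
    step <- .hbond_matrix[m_anti[i], ][tx_idx[i:(i + n_win - 1L)]]
    hb <- hb + step
    pr <- pr + (step > 0)
  }
  list(hbonds = as.integer(hb), paired = as.integer(pr))
}

#' Scan transcripts for miRNA binding sites
#'
#' Slides each miRNA across each transcript (gapless, antiparallel, full
#' miRNA length) and keeps every window whose dG/dGm ratio is greater than
#' or equal to `threshold_pct`. All passing starts are kept, including runs
#' of adjacent overlapping starts — collapsing into ranges is a reporting
#' concern (see [collapse_ranges()]). Each site is labeled with the mRNA
#' region (5UTR/CDS/3UTR) containing its start.
#'
#' @param mirnas A miRNA tibble (columns `id`, `seq`), e.g. from
#'   [read_mirna_fasta()], or a named character vector of RNA strings.
#' @param transcripts A transcript tibble (columns `gene`, `seq`,
#'   `utr5_len`, `cds_len`, `utr3_len`, optionally `nx`), e.g. from
#'   [read_transcripts()].
#' @param model An [energy_model()].
#' @param threshold_pct Minimum ratio (%), inclusive; sites at exactly the
#'   threshold are kept. Default 90.
#' @return A sites tibble, sorted by gene, miRNA and start: `mirna_id`,
#'   `gene`, `start` (1-based from the 5'UTR first nucleotide), `length`,
#'   `dG`, `dGm`, `ratio_pct`, `region`, `nx`. A transcript shorter than a
#'   miRNA yields no sites for that pair (with a warning).
#' @examples
#' mir <- tibble::tibble(id = "m1", seq = "ACGUACGUACGUACGUACGU")
#' tx <- tibble::tibble(
#'   gene = "G1",
#'   seq = paste0(strrep("A", 30), reverse_complement(mir$seq),
#'                strrep("A", 30)),
#'   utr5_len = 20L, cds_len = 40L, utr3_len = 20L)
#' scan_sites(mir, tx)
#' @export
scan_sites <- function(mirnas, transcripts, model = energy_model(),
                       threshold_pct = 90) {
  if (is.character(mirnas)) {
    mirnas <- tibble::tibble(id = names(mirnas), seq = unname(mirnas))
  }
  out <- list()
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts[t, ]
    tx_idx <- .encode_rna(tx$seq)
    for (m in seq_len(nrow(mirnas))) {
      mir <- mirnas[m, ]
      m_idx <- .encode_rna(mir$seq)
      if (length(tx_idx) < length(m_idx)) {
        warning("Transcript '", tx$gene, "' (", length(tx_idx),
                " nt) is shorter than miRNA '", mir$id, "' (",
                length(m_idx), " nt); skipped", call. = FALSE)
        next
      }
      cnt <- .window_counts(m_idx, tx_idx)
      max_bonds <- sum(.max_bonds_by_code[m_idx])
      ratio <- switch(model$ratio_mode,
        bonds  = 100 * cnt$hbonds / max_bonds,
        paired = 100 * cnt$paired / length(m_idx)
      )
      keep <- which(ratio >= threshold_pct)
      if (length(keep) == 0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        mirna_id = mir$id,
        gene = tx$gene,
        start = keep,
        length = length(m_idx),
        dG = -model$k_e * cnt$hbonds[keep],
        dGm = -model$k_e * max_bonds,
        ratio_pct = ratio[keep],
        region = classify_region(keep, tx$utr5_len, tx$cds_len),
        nx = if ("nx" %in% names(tx)) tx$nx else NA_real_
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      mirna_id = character(0), gene = character(0), start = integer(0),
      length = integer(0), dG = numeric(0), dGm = numeric(0),
      ratio_pct = numeric(0), region = character(0), nx = numeric(0)
    ))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$gene, .data$mirna_id, .data$start)
}

#' Classify a site start into 5UTR, CDS or 3UTR
#'
#' The region is decided by the site's start position alone (a site may
#' straddle a boundary; assignment by start is deterministic and matches
#' the start-of-site orientation of the reference tables): start <=
#' `utr5_len` is 5UTR, start <= `utr5_len + cds_len` is CDS, else 3UTR.
#' A zero-length region is simply never matched.
#'
#' @param start Integer vector of 1-based start positions.
#' @param utr5_len,cds_len Segment lengths of the transcript.
#' @return Character vector over `{"5UTR", "CDS", "3UTR"}`.
#' @export
classify_region <- function(start, utr5_len, cds_len) {
  ifelse(start <= utr5_len, "5UTR",
         ifelse(start <= utr5_len + cds_len, "CDS", "3UTR"))
}

#' Collapse runs of adjacent same-miRNA starts into ranges
#'
#' The reference tables print runs of overlapping starts of one miRNA on a
#' gene as a single range, e.g. `17 ÷ 23(3)`. This collapses a sites
#' tibble into one row per (gene, miRNA, run): successive starts whose
#' difference is at most `max_gap` belong to one run. The default
#' `max_gap = NULL` uses overlap, i.e. difference strictly less than the
#' site length.
#'
#' @param sites A sites tibble.
#' @param max_gap Maximum start difference joining a run, or `NULL` for the
#'   overlap rule (`< length`).
#' @return A tibble with one row per run: `gene`, `mirna_id`, `region`,
#'   `start_min`, `start_max`, `count`, `length`, `dG_min`, `dG_max`,
#'   `label` (formatted range, see [format_range()]).
#' @export
collapse_ranges <- function(sites, max_gap = NULL) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(
      gene = character(0), mirna_id = character(0), region = character(0),
      start_min = integer(0), start_max = integer(0), count = integer(0),
      length = integer(0), dG_min = numeric(0), dG_max = numeric(0),
      label = character(0)
    ))
  }
  sites |>
    dplyr::arrange(.data$gene, .data$mirna_id, .data$start) |>
    dplyr::group_by(.data$gene, .data$mirna_id) |>
    dplyr::group_modify(function(df, key) {
      gap <- if (is.null(max_gap)) df$length[1] - 1L else max_gap
      run <- cumsum(c(1L, as.integer(diff(df$start) > gap)))
      df |>
        dplyr::group_by(run = run) |>
        dplyr::summarise(
          region = .data$region[1],
          start_min = min(.data$start),
          start_max = max(.data$start),
          count = dplyr::n(),
          length = .data$length[1],
          dG_min = min(.data$dG),
          dG_max = max(.data$dG),
          .groups = "drop"
        ) |>
        dplyr::select(-"run")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = format_range(.data$start_min, .data$start_max,
                                       .data$count)) |>
    dplyr::arrange(.data$gene, .data$start_min, .data$mirna_id)
}

#' Format a collapsed start range in the reference-table notation
#'
#' A single start prints bare (`"85"`), two starts print comma-separated
#' (`"2288, 2290"`), three or more print as a range with the count
#' (`"4042 ÷ 4062 (11)"`).
#'
#' @param start_min,start_max,count Integer vectors describing each range.
#' @param glyph Range separator; the default is the division-sign glyph
#'   used by the reference tables, pass `"-"` for an ASCII fallback.
#' @return Character vector of formatted ranges.
#' @export
format_range <- function(start_min, start_max, count, glyph = "÷") {
  ifelse(count == 1L, as.character(start_min),
    ifelse(count == 2L, paste0(start_min, ", ", start_max),
      paste0(start_min, " ", glyph, " ", start_max, " (", count, ")")))
}

#' Format a dG range in the reference-table notation
#'
#' @param dG_min,dG_max Numeric vectors (kJ/mole); rounded to integers.
#' @inheritParams format_range
#' @return Character vector, e.g. `"-129 ÷ -140"` or `"-115"`.
#' @export
format_energy_range <- function(dG_min, dG_max, glyph = "÷") {
  lo <- round(dG_min)
  hi <- round(dG_max)
  ifelse(lo == hi, as.character(lo), paste0(lo, " ", glyph, " ", hi))
}

#' Expand a printed start-range string into individual starts
#'
#' Inverse (up to spacing) of [format_range()]: `"85"` gives 85,
#' `"2288, 2290"` gives both starts, `"17 ÷ 23(3)"` gives `n` evenly
#' spaced starts rounded to integers (inner starts of a printed range are
#' not individually printed; even spacing is the documented convention).
#'
#' @param x Character vector of printed range strings.
#' @return A list of integer vectors, one per element of `x`.
#' @export
expand_start_range <- function(x) {
  lapply(x, function(s) {
    s <- gsub(",(?=\\d)", ", ", gsub("\\s+", " ", trimws(s)), perl = TRUE)
    if (grepl("÷", s)) {
      m <- regmatches(s, regexec(
        "^(-?\\d+) ?÷ ?(-?\\d+) ?\\((\\d+)\\)$", s))[[1]]
      if (length(m) != 4) stop("Cannot parse range '", s, "'", call. = FALSE)
      a <- as.integer(m[2]); b <- as.integer(m[3]); n <- as.integer(m[4])
      as.integer(round(seq(a, b, length.out = n)))
    } else if (grepl(",", s)) {
      as.integer(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
    } else {
      as.integer(s)
    }
  })
}
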