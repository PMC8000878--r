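# Cluster organization of binding sites: connected components of the
# interval-overlap graph, with span / summed-length / compaction statistics.

#' Assign sites to overlap clusters
#'
#' Within each gene, clusters are the connected components of the graph in
#' which two sites are joined iff their nucleotide intervals
#' `[start, start + length - 1]` (1-based inclusive) overlap by at least
#' one nucleotide. Touching-but-disjoint intervals (e.g. `[1,10]` and
#' `[11,20]`) do not connect. Any miRNAs may share a cluster; every
#' reported start counts as its own interval. Computed by a sorted sweep,
#' which is exactly connected components for intervals.
#'
#' @param sites A sites tibble (one gene or many).
#' @return `sites` with an added integer `cluster` column, numbered within
#'   gene by increasing span start.
#' @export
assign_clusters <- function(sites) {
  if (nrow(sites) == 0) {
    sites$cluster <- integer(0)
    return(sites)
  }
  sites |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      ord <- order(df$start, df$start + df$length)
      df <- df[ord, , drop = FALSE]
      ends <- df$start + df$length - 1L
      cl <- integer(nrow(df))
      cur <- 0L
      max_end <- -Inf
      for (i in seq_len(nrow(df))) {
        if (df$start[i] > max_end) cur <- cur + 1L  # gap: new component
        cl[i] <- cur
        max_end <- max(max_end, ends[i])
      }
      df$cluster <- cl
      df
    }) |>
    dplyr::ungroup()
}

#' Summarize binding-site clusters
#'
#' Groups overlapping sites into clusters (see [assign_clusters()]) and
#' computes, per cluster: the span (`min start` to `max end`, inclusive
#' length), the summed member site lengths (each reported start counted
#' once), and the compaction ratio `sum_len / span_len` — how many times
#' the member sites would outspan the cluster if laid end to end. Clusters
#' are labeled with the region containing their span start.
#'
#' @param sites A sites tibble.
#' @return A tibble with one row per cluster: `gene`, `cluster`, `region`,
#'   `span_start`, `span_end`, `span_len`, `sum_len`, `n_members`,
#'   `n_mirnas`, `compaction`, `members` (list-column of member tibbles),
#'   sorted by gene and span start.
#' @examples
#' s <- tibble::tibble(
#'   mirna_id = c("a", "b", "c"), gene = "G",
#'   start = c(1L, 5L, 30L), length = c(10L, 10L, 10L),
#'   dG = -100, ratio_pct = 92, region = "5UTR")
#' find_clusters(s)[, c("span_start", "span_len", "sum_len", "compaction")]
#' @export
find_clusters <- function(sites) {
  empty <- tibble::tibble(
    gene = character(0), cluster = integer(0), region = character(0),
    span_start = integer(0), span_end = integer(0), span_len = integer(0),
    sum_len = integer(0), n_members = integer(0), n_mirnas = integer(0),
    compaction = numeric(0), members = list()
  )
  if (nrow(sites) == 0) return(empty)
  asg <- assign_clusters(sites)
  asg |>
    dplyr::group_by(.data$gene, .data$cluster) |>
    dplyr::group_modify(function(df, key) {
      df$gene <- key$gene
      df$cluster <- key$cluster
      span_start <- min(df$start)
      span_end <- max(df$start + df$length - 1L)
      span_len <- span_end - span_start + 1L
      sum_len <- sum(df$length)
      tibble::tibble(
        region = df$region[which.min(df$start)][1],
        span_start = as.integer(span_start),
        span_end = as.integer(span_end),
        span_len = as.integer(span_len),
        sum_len = as.integer(sum_len),
        n_members = nrow(df),
        n_mirnas = dplyr::n_distinct(df$mirna_id),
        compaction = sum_len / span_len,
        members = list(df)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene, .data$span_start)
}

#' Span, summed length and compaction of one cluster
#'
#' @param cluster One row of the [find_clusters()] output.
#' @return A named list `span_len`, `sum_len`, `compaction` (compaction
#'   rounded to one decimal, the reporting convention).
#' @export
cluster_stats <- function(cluster) {
  list(
    span_len = cluster$span_len,
    sum_len = cluster$sum_len,
    compaction = round(cluster$compaction, 1)
  )
}

#' Per-cluster report table
#'
#' One row per cluster member run (same-miRNA starts collapsed via
#' [collapse_ranges()]), carrying the gene's NX value, the cluster span and
#' compaction, and formatted start/energy ranges.
#'
#' @param clusters Output of [find_clusters()].
#' @param transcripts Optional transcript tibble supplying `nx` per gene.
#' @param glyph Range separator passed to the formatters.
#' @return A tibble: `gene`, `nx`, `cluster`, `region`, `span`,
#'   `compaction`, `mirna_id`, `starts`, `dG`, `length`, `count`.
#' @export
cluster_table <- function(clusters, transcripts = NULL, glyph = "÷") {
  if (nrow(clusters) == 0) {
    return(tibble::tibble(
      gene = character(0), nx = numeric(0), cluster = integer(0),
      region = character(0), span = character(0), compaction = numeric(0),
      mirna_id = character(0), starts = character(0), dG = character(0),
      length = integer(0), count = integer(0)
    ))
  }
  nx_map <- NULL
  if (!is.null(transcripts) && "nx" %in% names(transcripts)) {
    nx_map <- stats::setNames(transcripts$nx, transcripts$gene)
  }
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    runs <- collapse_ranges(cl$members[[1]])
    tibble::tibble(
      gene = cl$gene,
      nx = if (!is.null(nx_map)) unname(nx_map[cl$gene]) else
        if ("nx" %in% names(cl$members[[1]])) cl$members[[1]]$nx[1] else
          NA_real_,
      cluster = cl$cluster,
      region = cl$region,
      span = paste0(cl$span_start, " ", glyph, " ", cl$span_end,
                    " (", cl$span_len, " nt)"),
      compaction = round(cl$compaction, 1),
      mirna_id = runs$mirna_id,
      starts = format_range(runs$start_min, runs$start_max, runs$count,
                            glyph = glyph),
      dG = format_energy_range(runs$dG_min, runs$dG_max, glyph = glyph),
      length = runs$length,
      count = runs$count
    )
  })
  dplyr::bind_rows(rows)
}

#' Check printed cluster claims against their own table rows
#'
#' Published cluster descriptions sometimes disagree with the site rows
#' they summarize. Given the site rows and the printed claims (span and/or
#' compaction per cluster), this recomputes span, summed length and
#' compaction from the rows and flags claims that are not derivable:
#' a printed span must match the table-derived span within `span_tol`
#' nucleotides, and a printed compaction must match `sum_len / span` within
#' `comp_tol` (after rounding to one decimal) for the printed span or the
#' table-derived span — printed spans are known to drift by a nucleotide,
#' so either anchor is accepted.
#'
#' @param sites Site rows (tibble with `gene`, `region`, `start`, `length`).
#' @param claims Tibble with `gene`, `region`, and any of `span_printed`,
#'   `compaction_printed`, `sum_len_printed`; one row per claimed cluster,
#'   matched to the recomputed cluster in that gene+region containing the
#'   most sites.
#' @param span_tol Allowed span discrepancy, nt (default 1).
#' @param comp_tol Allowed compaction discrepancy on the one-decimal scale
#'   (default 0.1).
#' @return `claims` with recomputed `span_derived`, `sum_len_derived`,
#'   `compaction_derived`, `compaction_from_printed_span`, and logical
#'   flags `span_consistent`, `sum_len_consistent`, `compaction_consistent`
#'   (`NA` where the claim is absent).
#' @export
check_cluster_claims <- function(sites, claims, span_tol = 1,
                                 comp_tol = 0.1) {
  clusters <- find_clusters(sites)
  res <- lapply(seq_len(nrow(claims)), function(i) {
    cm <- claims[i, ]
    cand <- clusters[clusters$gene == cm$gene &
                       clusters$region == cm$region, , drop = FALSE]
    if (nrow(cand) == 0) {
      stop("No recomputed cluster for ", cm$gene, " / ", cm$region,
           call. = FALSE)
    }
    cl <- cand[which.max(cand$n_members), ]
    span_d <- cl$span_len
    sum_d <- cl$sum_len
    comp_d <- round(sum_d / span_d, 1)
    comp_p <- if (!is.null(cm$span_printed) && !is.na(cm$span_printed)) {
      round(sum_d / cm$span_printed, 1)
    } else NA_real_
    span_ok <- if ("span_printed" %in% names(cm) && !is.na(cm$span_printed)) {
      abs(cm$span_printed - span_d) <= span_tol
    } else NA
    sum_ok <- if ("sum_len_printed" %in% names(cm) &&
                  !is.na(cm$sum_len_printed)) {
      cm$sum_len_printed == sum_d
    } else NA
    comp_ok <- if ("compaction_printed" %in% names(cm) &&
                   !is.na(cm$compaction_printed)) {
      isTRUE(abs(cm$compaction_printed - comp_d) <= comp_tol) ||
        isTRUE(abs(cm$compaction_printed - comp_p) <= comp_tol)
    } else NA
    dplyr::bind_cols(cm, tibble::tibble(
      span_derived = span_d,
      sum_len_derived = sum_d,
      compaction_derived = comp_d,
      compaction_from_printed_span = comp_p,
      span_consistent = span_ok,
      sum_len_consistent = sum_ok,
      compaction_consistent = comp_ok
    ))
  })
  dplyr::bind_rows(res)
}
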