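# miRNA-gene association tables, region-specific effective-energy filter,
# the occupancy model of translational suppression, expression-weighted
# competition ranking, and the NX / site-count report.

#' Default region-specific effectiveness thresholds (kJ/mole)
#'
#' The criterion for an effective miRNA:mRNA interaction: -130 kJ/mole and
#' stronger for 5'UTR and CDS sites, -115 kJ/mole and stronger for 3'UTR
#' sites (free energies are negative; "stronger" means more negative).
#'
#' @return Named numeric vector with entries `5UTR`, `CDS`, `3UTR`.
#' @export
default_region_thresholds <- function() {
  c("5UTR" = -130, "CDS" = -130, "3UTR" = -115)
}

#' Filter sites by region-specific effective-interaction thresholds
#'
#' Keeps sites whose free energy is at or below (i.e. at least as strong
#' as) the threshold of their region.
#'
#' @param sites A sites tibble with `dG` and `region` columns.
#' @param thresholds Named numeric vector of negative thresholds per
#'   region; defaults to [default_region_thresholds()].
#' @return The filtered sites tibble.
#' @examples
#' s <- tibble::tibble(mirna_id = c("a", "b"), gene = "G",
#'                     start = c(1L, 40L), length = 23L,
#'                     dG = c(-134, -125), region = "5UTR")
#' effective_sites(s)  # keeps only the -134 site
#' @export
effective_sites <- function(sites, thresholds = default_region_thresholds()) {
  if (any(thresholds >= 0)) {
    stop("Effectiveness thresholds must be negative (kJ/mole)",
         call. = FALSE)
  }
  missing_reg <- setdiff(unique(sites$region), names(thresholds))
  if (length(missing_reg) > 0) {
    stop("No threshold for region(s): ", paste(missing_reg, collapse = ", "),
         call. = FALSE)
  }
  keep <- sites$dG <= thresholds[sites$region]
  sites[keep, , drop = FALSE]
}

#' Alternative target genes and alternative miRNAs
#'
#' From a (typically threshold-filtered) site list, derives the two
#' association tables: miRNAs with binding sites in two or more distinct
#' genes (each gene is an alternative target of that miRNA), and genes
#' bound by two or more distinct miRNAs (alternative miRNAs of that gene).
#' Entries with a single partner are omitted. Output is deterministically
#' sorted (by descending partner count, then id).
#'
#' @param sites A sites tibble.
#' @return A list with two tibbles: `mirna_to_genes` (`mirna_id`, `genes`
#'   list-column of sorted gene symbols, `n_genes`) and `gene_to_mirnas`
#'   (`gene`, `mirnas` list-column, `n_mirnas`).
#' @export
alternatives <- function(sites) {
  pairs <- dplyr::distinct(sites, .data$mirna_id, .data$gene)
  m2g <- pairs |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(genes = list(sort(unique(.data$gene))),
                     n_genes = dplyr::n_distinct(.data$gene),
                     .groups = "drop") |>
    dplyr::filter(.data$n_genes >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$mirna_id)
  g2m <- pairs |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(mirnas = list(sort(unique(.data$mirna_id))),
                     n_mirnas = dplyr::n_distinct(.data$mirna_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_mirnas >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_mirnas), .data$gene)
  list(mirna_to_genes = m2g, gene_to_mirnas = g2m)
}

#' Translational suppression from the miRNA:mRNA concentration ratio
#'
#' Occupancy model: with concentration ratio `R = [miRNA] / [mRNA]`, the
#' fraction of suppressed protein synthesis is `100 * R / (1 + R)` percent.
#' This is 0 at R = 0, 50 at R = 1, approaches 100 as R grows, and
#' satisfies the exact complementarity `s(R) + s(1/R) = 100`; a 1:10 ratio
#' gives ~9.1% ("10%" in round figures) and 10:1 gives ~90.9% ("90%").
#'
#' @param mirna_conc Non-negative miRNA concentration (arbitrary units), or
#'   directly the ratio R when `mrna_conc` is 1.
#' @param mrna_conc Positive mRNA concentration (same units).
#' @return Suppression percentage in `[0, 100)`. Vectorized.
#' @examples
#' suppression(1, 10)   # ~9.1
#' suppression(10, 1)   # ~90.9
#' @export
suppression <- function(mirna_conc, mrna_conc = 1) {
  if (any(mirna_conc < 0)) {
    stop("miRNA concentration must be non-negative", call. = FALSE)
  }
  if (any(mrna_conc <= 0)) {
    stop("mRNA concentration must be positive", call. = FALSE)
  }
  R <- mirna_conc / mrna_conc
  100 * R / (1 + R)
}

#' Rank a cluster's miRNAs by competitive advantage
#'
#' When several miRNAs share a cluster only one can occupy it at a time;
#' the advantage goes to miRNAs binding with stronger free energy and
#' present at higher concentration. The two factors are combined as
#' `score = rel_expression * |dG|` (a documented heuristic — only the
#' ranking direction is meaningful); missing expressions count as 1. Ties
#' break lexicographically by miRNA id.
#'
#' @param members Member sites of one cluster (tibble with `mirna_id`,
#'   `dG`), e.g. `find_clusters(sites)$members[[i]]`.
#' @param expressions Named numeric vector mapping miRNA id to relative
#'   expression; unnamed miRNAs default to 1.
#' @return A tibble `mirna_id`, `dG`, `rel_expression`, `score`, sorted by
#'   descending score.
#' @examples
#' m <- tibble::tibble(mirna_id = c("miR-619-5p", "miR-5095"),
#'                     dG = c(-121, -117))
#' competition_rank(m, c("miR-5095" = 4.8))  # miR-5095 first
#' @export
competition_rank <- function(members, expressions = NULL) {
  best <- members |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(dG = min(.data$dG), .groups = "drop")
  expr <- rep(1, nrow(best))
  if (!is.null(expressions)) {
    hit <- match(best$mirna_id, names(expressions))
    expr[!is.na(hit)] <- expressions[hit[!is.na(hit)]]
  }
  best$rel_expression <- expr
  best$score <- expr * abs(best$dG)
  dplyr::arrange(best, dplyr::desc(.data$score), .data$mirna_id)
}

#' Gene expression versus binding-site load
#'
#' Reports, per gene, the NX expression value, the total number of binding
#' sites, and the number of multi-member clusters (two or more overlapping
#' sites). Highly expressed genes tend to carry few, separate sites rather
#' than clusters; this table makes that comparison directly.
#'
#' @param transcripts Transcript tibble with `gene` and `nx`.
#' @param sites A sites tibble over those genes.
#' @return A tibble `gene`, `nx`, `n_sites`, `n_multi_clusters`, sorted by
#'   descending NX.
#' @export
nx_site_report <- function(transcripts, sites) {
  counts <- sites |>
    dplyr::count(.data$gene, name = "n_sites")
  multi <- find_clusters(sites) |>
    dplyr::filter(.data$n_members >= 2) |>
    dplyr::count(.data$gene, name = "n_multi_clusters")
  transcripts |>
    dplyr::select("gene", "nx") |>
    dplyr::left_join(counts, by = "gene") |>
    dplyr::left_join(multi, by = "gene") |>
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      n_multi_clusters = dplyr::coalesce(.data$n_multi_clusters, 0L)
    ) |>
    dplyr::arrange(dplyr::desc(.data$nx))
}
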