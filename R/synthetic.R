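# Synthetic miRNA/transcript generator with planted binding sites and a
# truth ledger, so every pipeline stage is testable without downloads.

.sample_bases <- function(n, gc_frac) {
  p <- c(A = (1 - gc_frac) / 2, C = gc_frac / 2,
         G = gc_frac / 2, U = (1 - gc_frac) / 2)
  sample(RNA_BASES, n, replace = TRUE, prob = p)
}

#' Generate random miRNA sequences
#'
#' Independent per-base draws with total G+C probability `gc_frac`; lengths
#' uniform over `length_range`. Deterministic under `seed`.
#'
#' @param n Number of miRNAs (>= 1).
#' @param length_range Integer pair, inclusive length bounds (nt). Default
#'   c(20, 25), the length range of the reference site tables.
#' @param gc_frac G+C fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param prefix Id prefix; ids are `<prefix>-001` and so on.
#' @return A miRNA tibble (`id`, `seq`, `length`, `rel_expression`).
#' @export
random_mirnas <- function(n, length_range = c(20L, 25L), gc_frac = 0.5,
                          seed = 1L, prefix = "syn-mir") {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (gc_frac < 0 || gc_frac > 1) {
    stop("`gc_frac` must be in [0, 1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  pool <- seq(length_range[1], length_range[2])
  lens <- pool[sample.int(length(pool), n, replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    paste(.sample_bases(L, gc_frac), collapse = "")
  }, character(1))
  tibble::tibble(
    id = sprintf("%s-%03d", prefix, seq_len(n)),
    seq = seqs, length = lens, rel_expression = NA_real_
  )
}

#' Specify a site to plant
#'
#' @param mirna_id Id of the miRNA (must exist in the miRNA table passed to
#'   [plant_sites()]).
#' @param start 1-based transcript position of the planted window.
#' @param target_ratio_pct Intended paired-position percentage of the
#'   planted duplex (100 = exact reverse complement; lower values are
#'   realized by mutating `round((1 - target/100) * length)` positions).
#' @return A one-row tibble.
#' @export
plant_spec <- function(mirna_id, start, target_ratio_pct = 100) {
  tibble::tibble(mirna_id = mirna_id, start = as.integer(start),
                 target_ratio_pct = target_ratio_pct)
}

# Bases forming no recognized pair with the given opposing base.
.nonpairing_for <- c(A = "AG", C = "CU", G = "AG", U = "CU")

#' Plant miRNA binding sites into a synthetic transcript
#'
#' Builds a transcript of uniform-random background and writes, at each
#' planted start, the reverse complement of the named miRNA with `k`
#' positions mutated to non-pairing bases, where `k` realizes the plant's
#' target paired-fraction. Mutated positions are sampled away from both
#' duplex ends (never the outermost two positions) and the replacement
#' base forms no recognized pair with the opposing miRNA base, so the
#' realized ratio is exactly computable. Overlapping plants are allowed —
#' later plants overwrite earlier bases — and the truth ledger records the
#' realized ratio of every plant recomputed from the final sequence, in
#' both ratio modes.
#'
#' @param transcript_len Total transcript length (nt).
#' @param regions Named integer vector `c(utr5_len=, cds_len=, utr3_len=)`
#'   summing to `transcript_len`.
#' @param plants Tibble of [plant_spec()] rows.
#' @param mirnas miRNA tibble providing the sequences.
#' @param seed Integer seed (background and mutation placement).
#' @param gene Gene symbol for the transcript.
#' @param nx Optional NX expression value.
#' @param model [energy_model()] used for the truth ledger's bond-mode
#'   ratio (`k_e` does not affect either realized ratio).
#' @return A list: `transcript` (one-row transcript tibble) and `truth`
#'   (tibble `gene`, `mirna_id`, `start`, `length`, `target_ratio_pct`,
#'   `realized_paired_pct`, `realized_bond_pct`, `region`).
#' @export
plant_sites <- function(transcript_len, regions, plants, mirnas, seed = 1L,
                        gene = "SYNG", nx = NA_real_,
                        model = energy_model()) {
  stopifnot(all(c("utr5_len", "cds_len", "utr3_len") %in% names(regions)))
  if (sum(regions) != transcript_len) {
    stop("Region lengths sum to ", sum(regions), " != ", transcript_len,
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  tx <- .sample_bases(transcript_len, 0.5)
  for (p in seq_len(nrow(plants))) {
    pl <- plants[p, ]
    mir <- mirnas[mirnas$id == pl$mirna_id, ]
    if (nrow(mir) != 1) {
      stop("Unknown miRNA id '", pl$mirna_id, "'", call. = FALSE)
    }
    L <- nchar(mir$seq)
    if (pl$start < 1 || pl$start + L - 1L > transcript_len) {
      stop("Plant for '", pl$mirna_id, "' at ", pl$start,
           " falls outside the transcript", call. = FALSE)
    }
    win <- strsplit(reverse_complement(mir$seq), "", fixed = TRUE)[[1]]
    k <- round((1 - pl$target_ratio_pct / 100) * L)
    if (k > 0) {
      interior <- seq(3L, L - 2L)
      if (k > length(interior)) {
        stop("Target ratio ", pl$target_ratio_pct,
             "% needs more mutations than interior positions allow",
             call. = FALSE)
      }
      pos <- sample(interior, k)
      opp <- rev(strsplit(mir$seq, "", fixed = TRUE)[[1]])
      for (i in pos) {
        choices <- strsplit(.nonpairing_for[[opp[i]]], "", fixed = TRUE)[[1]]
        choices <- setdiff(choices, win[i])
        win[i] <- if (length(choices) == 1) choices else sample(choices, 1)
      }
    }
    tx[pl$start:(pl$start + L - 1L)] <- win
  }
  seq_str <- paste(tx, collapse = "")
  transcript <- tibble::tibble(
    gene = gene, seq = seq_str,
    utr5_len = as.integer(regions[["utr5_len"]]),
    cds_len = as.integer(regions[["cds_len"]]),
    utr3_len = as.integer(regions[["utr3_len"]]),
    nx = nx
  )
  truth <- dplyr::bind_rows(lapply(seq_len(nrow(plants)), function(p) {
    pl <- plants[p, ]
    mir <- mirnas[mirnas$id == pl$mirna_id, ]
    L <- nchar(mir$seq)
    win <- substr(seq_str, pl$start, pl$start + L - 1L)
    d_pair <- duplex(mir$seq, win, energy_model(model$k_e, "paired"))
    d_bond <- duplex(mir$seq, win, energy_model(model$k_e, "bonds"))
    tibble::tibble(
      gene = gene, mirna_id = pl$mirna_id, start = pl$start,
      length = L, target_ratio_pct = pl$target_ratio_pct,
      realized_paired_pct = d_pair$ratio_pct,
      realized_bond_pct = d_bond$ratio_pct,
      region = classify_region(pl$start, regions[["utr5_len"]],
                               regions[["cds_len"]])
    )
  }))
  list(transcript = transcript, truth = truth)
}

#' A fixed synthetic cosmos emulating clustered-site target genes
#'
#' Builds a small deterministic universe — 10 genes, 38 miRNAs — that
#' exercises every downstream branch of the pipeline: a 5'UTR cluster of a
#' five-member miRNA family sharing one window (one- and two-mismatch
#' variants of a common sequence), multi-start runs of dinucleotide-repeat
#' miRNAs (GU- and CA-repeat tracts, where a step-2 shift rebinds the same
#' miRNA), a hub miRNA planted in six genes' 3'UTRs, a gene bound by six
#' distinct miRNAs, isolated singletons on highly expressed (high-NX)
#' genes, and sub-threshold decoy plants (realized paired ratio below
#' 85%). All randomness derives from `seed`.
#'
#' @param seed Integer seed.
#' @return A list (`synthetic_truth`): `mirnas`, `transcripts` (10 rows),
#'   `plants`, `truth` (per-plant realized ratios), `model` (the
#'   paired-mode [energy_model()] the targets are expressed in), `seed`.
#' @export
scenario_gastric_like <- function(seed = 7L) {
  model <- energy_model(ratio_mode = "paired")
  mirnas <- random_mirnas(30, seed = seed + 1000L)

  # five-member family: variants of one 22-nt sequence (<= 2 mismatches)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed + 2000L)
  base_seq <- paste(.sample_bases(22, 0.5), collapse = "")
  fam <- vapply(1:4, function(i) {
    ch <- strsplit(base_seq, "", fixed = TRUE)[[1]]
    pos <- sample(3:20, if (i <= 2) 1 else 2)
    for (p in pos) ch[p] <- sample(setdiff(RNA_BASES, ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  special <- tibble::tibble(
    id = c("syn-fam-a", "syn-fam-b", "syn-fam-c", "syn-fam-d", "syn-fam-e",
           "syn-mir-ac", "syn-mir-gu", "syn-mir-hub"),
    seq = c(base_seq, fam,
            strrep("AC", 11),   # binds GU-repeat tracts
            strrep("GU", 11),   # binds CA-repeat tracts
            paste(.sample_bases(23, 0.5), collapse = "")),
    length = c(rep(22L, 7L), 23L),
    rel_expression = NA_real_
  )
  mirnas <- dplyr::bind_rows(mirnas, special)

  reg <- c(utr5_len = 200L, cds_len = 600L, utr3_len = 400L)
  L <- sum(reg)
  nx <- c(3.4, 5.9, 10.6, 14.1, 17.2, 19.5, 25.2, 47.0, 76.6, 105.0)
  genes <- sprintf("SYNG%02d", 1:10)

  plants <- list(
    # G1: family cluster in the 5'UTR (six distinct miRNAs on the gene,
    # counting the hub below) + a CDS multi-start GU tract
    SYNG01 = dplyr::bind_rows(
      plant_spec("syn-fam-a", 120), plant_spec("syn-fam-b", 120),
      plant_spec("syn-fam-c", 120), plant_spec("syn-fam-d", 120),
      plant_spec("syn-fam-e", 120),
      # step-2 run: 8 starts over a 36-nt GU tract
      dplyr::bind_rows(lapply(seq(301, by = 2, length.out = 8),
                              function(s) plant_spec("syn-mir-ac", s))),
      plant_spec("syn-mir-hub", 900)
    ),
    # G2: CA tract in the 3'UTR (multi-start run) + hub + a decoy
    SYNG02 = dplyr::bind_rows(
      dplyr::bind_rows(lapply(seq(851, by = 2, length.out = 10),
                              function(s) plant_spec("syn-mir-gu", s))),
      plant_spec("syn-mir-hub", 950),
      plant_spec("syn-mir-001", 400, target_ratio_pct = 80)
    ),
    # G3..G6: hub singleton + an ordinary singleton each
    SYNG03 = dplyr::bind_rows(plant_spec("syn-mir-hub", 820),
                              plant_spec("syn-mir-002", 50),
                              plant_spec("syn-mir-003", 450, 95)),
    SYNG04 = dplyr::bind_rows(plant_spec("syn-mir-hub", 1000),
                              plant_spec("syn-mir-004", 300)),
    SYNG05 = dplyr::bind_rows(plant_spec("syn-mir-hub", 870),
                              plant_spec("syn-mir-005", 150, 80),
                              plant_spec("syn-mir-006", 600)),
    SYNG06 = dplyr::bind_rows(plant_spec("syn-mir-hub", 1050),
                              plant_spec("syn-mir-007", 210, 95)),
    # G7..G10: high-NX genes with one isolated site each
    SYNG07 = plant_spec("syn-mir-008", 500),
    SYNG08 = plant_spec("syn-mir-009", 700),
    SYNG09 = plant_spec("syn-mir-010", 250),
    SYNG10 = plant_spec("syn-mir-011", 950, 80)
  )

  transcripts <- list()
  truths <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    res <- plant_sites(L, reg, plants[[g]], mirnas, seed = seed + i,
                       gene = g, nx = nx[i], model = model)
    transcripts[[i]] <- res$transcript
    truths[[i]] <- res$truth
  }
  structure(
    list(mirnas = mirnas,
         transcripts = dplyr::bind_rows(transcripts),
         plants = dplyr::bind_rows(lapply(names(plants), function(g) {
           dplyr::mutate(plants[[g]], gene = g, .before = 1)
         })),
         truth = dplyr::bind_rows(truths),
         model = model, seed = seed),
    class = "synthetic_truth"
  )
}

#' Write a synthetic scenario to disk
#'
#' Emits the standard file set: miRNA FASTA, transcript FASTA, regions TSV
#' and a BED-like truth TSV (gene, start, end, miRNA, realized ratios).
#'
#' @param scenario A `synthetic_truth` list from [scenario_gastric_like()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(scenario$mirnas$seq, scenario$mirnas$id),
              file.path(dir, "mirnas.fa"))
  write_fasta(stats::setNames(scenario$transcripts$seq,
                              scenario$transcripts$gene),
              file.path(dir, "transcripts.fa"))
  readr::write_tsv(
    scenario$transcripts[, c("gene", "utr5_len", "cds_len", "utr3_len",
                             "nx")],
    file.path(dir, "regions.tsv"), progress = FALSE)
  truth_bed <- scenario$truth |>
    dplyr::transmute(
      gene = .data$gene, start = .data$start,
      end = .data$start + .data$length - 1L,
      mirna_id = .data$mirna_id,
      target_ratio_pct = .data$target_ratio_pct,
      realized_paired_pct = .data$realized_paired_pct,
      realized_bond_pct = .data$realized_bond_pct,
      region = .data$region)
  readr::write_tsv(truth_bed, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
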