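# Readers/writers for the external formats: miRNA FASTA, transcript FASTA +
# regions TSV sidecar, sites TSV (published-table column order) and BED6.

#' Read a miRNA FASTA file
#'
#' Reads miRNA sequences, normalizing to the RNA alphabet (uppercase, T to
#' U). DNA-alphabet FASTA (e.g. NCBI exports) is therefore accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` (RNA, 5'-3'), `length`, and
#'   `rel_expression` (`NA`; fill from expression data when available).
#' @details Record ids must be unique; any non-ACGU character remaining
#'   after normalization is an error naming the record and position.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("Duplicate miRNA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- unname(normalize_rna(as.character(set)))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGU]", seqs[i])
    if (bad > 0) {
      stop("Record '", ids[i], "': non-ACGU character '",
           substr(seqs[i], bad, bad), "' at position ", bad, call. = FALSE)
    }
    if (nchar(seqs[i]) == 0) {
      stop("Record '", ids[i], "' has an empty sequence", call. = FALSE)
    }
  }
  tibble::tibble(
    id = ids, seq = seqs, length = nchar(seqs),
    rel_expression = NA_real_
  )
}

#' Read transcripts with their region annotation
#'
#' Reads an mRNA FASTA plus a sidecar TSV giving, per gene, the lengths of
#' the 5'UTR, CDS and 3'UTR segments and an optional NX expression value.
#' Coordinates throughout the package are 1-based from the first nucleotide
#' of the 5'UTR, so the three segment lengths must sum to the sequence
#' length.
#'
#' @param fasta Path to the transcript FASTA (gene symbol as record id).
#' @param regions Path to a TSV with header columns `gene`, `utr5_len`,
#'   `cds_len`, `utr3_len` and optionally `nx`.
#' @return A tibble with columns `gene`, `seq` (RNA), `utr5_len`, `cds_len`,
#'   `utr3_len`, `nx`, and `cds_frame_warning` (TRUE when an annotated CDS
#'   length is not divisible by 3 — partial annotations are accepted but
#'   flagged).
#' @export
read_transcripts <- function(fasta, regions) {
  set <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("Duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_rna(as.character(set))
  reg <- readr::read_tsv(regions, show_col_types = FALSE,
                         progress = FALSE)
  needed <- c("gene", "utr5_len", "cds_len", "utr3_len")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0) {
    stop("Regions TSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"nx" %in% names(reg)) reg$nx <- NA_real_
  reg$nx <- suppressWarnings(as.numeric(reg$nx))

  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- ids[i]
    row <- reg[reg$gene == g, , drop = FALSE]
    if (nrow(row) == 0) {
      stop("No regions row for gene '", g, "'", call. = FALSE)
    }
    total <- row$utr5_len + row$cds_len + row$utr3_len
    L <- nchar(seqs[i])
    if (total != L) {
      stop("Gene '", g, "': region lengths sum to ", total,
           " != ", L, " (sequence length)", call. = FALSE)
    }
    bad <- regexpr("[^ACGU]", seqs[i])
    if (bad > 0) {
      stop("Gene '", g, "': non-ACGU character '",
           substr(seqs[i], bad, bad), "' at position ", bad, call. = FALSE)
    }
    out[[i]] <- tibble::tibble(
      gene = g, seq = unname(seqs[i]),
      utr5_len = as.integer(row$utr5_len),
      cds_len = as.integer(row$cds_len),
      utr3_len = as.integer(row$utr3_len),
      nx = row$nx,
      cds_frame_warning = row$cds_len > 0 && row$cds_len %% 3 != 0
    )
  }
  dplyr::bind_rows(out)
}

#' Write binding sites as a TSV in the published-table column order
#'
#' Columns follow the layout of the reference site tables: gene, NX, miRNA,
#' start of site (nt), dG (kJ/mole, rounded to integer), dG/dGm ratio (%,
#' rounded to integer), site length (nt), plus the region label. Starts are
#' 1-based from the first nucleotide of the 5'UTR.
#'
#' @param sites A sites tibble (see [scan_sites()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- tibble::tibble(
    gene = sites$gene,
    nx = if ("nx" %in% names(sites)) sites$nx else NA_real_,
    mirna = sites$mirna_id,
    start = sites$start,
    dG_kj_mole = round(sites$dG),
    ratio_pct = round(sites$ratio_pct),
    length = sites$length,
    region = sites$region
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a sites TSV written by [write_sites_tsv()]
#'
#' @param path Path to the TSV.
#' @return A sites tibble with the standard column names (`mirna_id`,
#'   `gene`, `start`, `length`, `dG`, `ratio_pct`, `region`, `nx`).
#' @export
read_sites_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    mirna_id = x$mirna, gene = x$gene,
    start = as.integer(x$start), length = as.integer(x$length),
    dG = as.numeric(x$dG_kj_mole), ratio_pct = as.numeric(x$ratio_pct),
    region = x$region, nx = x$nx
  )
}

#' Write binding sites as BED6
#'
#' Converts the package's 1-based inclusive transcript coordinates to BED's
#' 0-based half-open convention: BED start = site start - 1, BED end =
#' start - 1 + length. The chrom field is the gene id, the score is
#' `round(ratio_pct * 10)`, and the strand is `+`.
#'
#' @inheritParams write_sites_tsv
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(
    chrom = sites$gene,
    start = sites$start - 1L,
    end = sites$start - 1L + sites$length,
    name = sites$mirna_id,
    score = as.integer(round(sites$ratio_pct * 10)),
    strand = "+"
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (names become record ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
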