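# Ortholog comparison of binding-site cluster regions: flank identity,
# substitution classification (transition/transversion/indel, wobble
# preservation), energy impact, and insert detection. Inputs are
# pre-aligned (gap character '-'); no alignment is performed here.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

#' Build an ortholog set from aligned sequences
#'
#' @param label Gene label.
#' @param entries Named character vector: species tag (e.g. `hsa`, `ptr`,
#'   `ggo`) to aligned RNA string (gaps as `-`); all equal length.
#' @param flank5_len,flank3_len Lengths (columns) of the 5' and 3' flank
#'   windows used by [flank_identity()].
#' @return An `ortholog_set` list.
#' @export
ortholog_set <- function(label, entries, flank5_len, flank3_len) {
  if (length(entries) < 2) {
    stop("An ortholog set needs at least two entries", call. = FALSE)
  }
  entries <- vapply(entries, normalize_rna, character(1))
  lens <- nchar(entries)
  if (length(unique(lens)) != 1) {
    stop("Aligned entries must have equal length; got ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  if (flank5_len + flank3_len > lens[1]) {
    stop("Flank windows exceed the alignment length", call. = FALSE)
  }
  structure(list(label = label, entries = entries,
                 flank5_len = as.integer(flank5_len),
                 flank3_len = as.integer(flank3_len)),
            class = "ortholog_set")
}

#' Read an ortholog set from an aligned multi-FASTA
#'
#' @param path Aligned multi-FASTA; record ids are species tags.
#' @inheritParams ortholog_set
#' @export
read_ortholog_fasta <- function(path, label, flank5_len, flank3_len) {
  set <- Biostrings::readBStringSet(path)
  entries <- stats::setNames(as.character(set),
                             sub("\\s.*$", "", names(set)))
  ortholog_set(label, entries, flank5_len, flank3_len)
}

.column_identity_pct <- function(mat) {
  # fraction of columns where all rows agree, in percent
  if (ncol(mat) == 0) return(100)
  ident <- apply(mat, 2, function(col) length(unique(col)) == 1)
  100 * mean(ident)
}

#' Flank identity of an ortholog set
#'
#' Column-wise identity of the 5' and 3' flank windows across all entries:
#' the percentage of flank columns at which every species carries the same
#' character.
#'
#' @param set An [ortholog_set()].
#' @return A list `pct5`, `pct3`, `all_identical5`, `all_identical3`.
#' @export
flank_identity <- function(set) {
  stopifnot(inherits(set, "ortholog_set"))
  mat <- do.call(rbind, strsplit(set$entries, "", fixed = TRUE))
  L <- ncol(mat)
  f5 <- mat[, seq_len(set$flank5_len), drop = FALSE]
  f3 <- mat[, seq(L - set$flank3_len + 1L, L), drop = FALSE]
  pct5 <- .column_identity_pct(f5)
  pct3 <- .column_identity_pct(f3)
  list(pct5 = pct5, pct3 = pct3,
       all_identical5 = pct5 == 100, all_identical3 = pct3 == 100)
}

.classify_sub <- function(ref, alt) {
  ifelse(ref == "-" | alt == "-", "indel",
    ifelse((ref %in% PURINES & alt %in% PURINES) |
             (ref %in% PYRIMIDINES & alt %in% PYRIMIDINES),
           "transition", "transversion"))
}

#' Classify substitutions between two aligned region sequences
#'
#' One record per differing column. A substitution is a transition when
#' both bases are purines or both pyrimidines, a transversion otherwise,
#' and an indel when either side is a gap. When a miRNA duplex is supplied
#' (the miRNA whose site occupies the region, antiparallel as in
#' [duplex()]), each record also carries the signed free-energy change
#' `ddG = k_e * (bonds_ref - bonds_alt)` — positive when the substitution
#' weakens the duplex — and `wobble_preserving`, TRUE when the substituted
#' base still forms a recognized (possibly 1-bond wobble) pair with the
#' opposing miRNA base. A C to U substitution opposite a miRNA G is the
#' canonical tolerated case: the G-C pair becomes a G-U wobble.
#'
#' @param ref,alt Aligned RNA strings of equal length (gaps as `-`).
#' @param mirna_seq Optional miRNA (5'-3') spanning the region; its length
#'   must equal the region length (gap columns are skipped for energy).
#' @param model An [energy_model()].
#' @return A tibble `position`, `ref_base`, `alt_base`, `klass`,
#'   `wobble_preserving`, `ddG` (NA without a miRNA or at indels).
#' @export
substitutions <- function(ref, alt, mirna_seq = NULL,
                          model = energy_model()) {
  ref <- normalize_rna(ref)
  alt <- normalize_rna(alt)
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  if (length(r) != length(a)) {
    stop("Aligned sequences differ in length (", length(r), " vs ",
         length(a), "); supply a gapped alignment", call. = FALSE)
  }
  opp <- NULL
  if (!is.null(mirna_seq)) {
    m <- strsplit(normalize_rna(mirna_seq), "", fixed = TRUE)[[1]]
    if (length(m) != length(r)) {
      stop("miRNA length (", length(m),
           ") must equal the region length (", length(r), ")",
           call. = FALSE)
    }
    opp <- rev(m)  # antiparallel: region position i opposes miRNA L-i+1
  }
  diffs <- which(r != a)
  if (length(diffs) == 0) {
    return(tibble::tibble(
      position = integer(0), ref_base = character(0),
      alt_base = character(0), klass = character(0),
      wobble_preserving = logical(0), ddG = numeric(0)
    ))
  }
  klass <- .classify_sub(r[diffs], a[diffs])
  wob <- rep(NA, length(diffs))
  ddG <- rep(NA_real_, length(diffs))
  if (!is.null(opp)) {
    for (j in seq_along(diffs)) {
      i <- diffs[j]
      if (klass[j] == "indel") next
      b_ref <- count_hbonds(r[i], opp[i])
      b_alt <- count_hbonds(a[i], opp[i])
      ddG[j] <- model$k_e * (b_ref - b_alt)
      wob[j] <- b_alt > 0
    }
  }
  tibble::tibble(
    position = diffs, ref_base = r[diffs], alt_base = a[diffs],
    klass = klass, wobble_preserving = wob, ddG = ddG
  )
}

#' Report species-specific inserts in an aligned ortholog set
#'
#' A column where one species carries bases while at least one other
#' carries a gap is an insert in that species; consecutive such columns
#' are merged into one record.
#'
#' @param set An [ortholog_set()].
#' @return A tibble `species`, `position` (first alignment column of the
#'   run), `inserted` (the inserted bases).
#' @export
insert_report <- function(set) {
  stopifnot(inherits(set, "ortholog_set"))
  mat <- do.call(rbind, strsplit(set$entries, "", fixed = TRUE))
  rownames(mat) <- names(set$entries)
  out <- list()
  for (sp in rownames(mat)) {
    row <- mat[sp, ]
    others <- mat[setdiff(rownames(mat), sp), , drop = FALSE]
    ins_col <- row != "-" & apply(others == "-", 2, any)
    if (!any(ins_col)) next
    runs <- rle(ins_col)
    pos <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
    for (k in which(runs$values)) {
      cols <- seq(pos[k], length.out = runs$lengths[k])
      out[[length(out) + 1L]] <- tibble::tibble(
        species = sp, position = pos[k],
        inserted = paste(row[cols], collapse = "")
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(species = character(0), position = integer(0),
                          inserted = character(0)))
  }
  dplyr::bind_rows(out)
}
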