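# Base ordering used by all integer encodings.
RNA_BASES <- c("A", "C", "G", "U")

# Hydrogen-bond counts for the four recognized pair types: G-C 3, A-U 2,
# G-U 1, A-C 1; every other combination forms no pair.
.hbond_matrix <- local({
  m <- matrix(0L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["G", "C"] <- m["C", "G"] <- 3L
  m["A", "U"] <- m["U", "A"] <- 2L
  m["G", "U"] <- m["U", "G"] <- 1L
  m["A", "C"] <- m["C", "A"] <- 1L
  m
})

# Internucleotide distances (nm) for the recognized pairs; NA when unpaired.
.distance_matrix <- local({
  m <- matrix(NA_real_, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "C"] <- m["C", "A"] <- 1.04
  m["G", "C"] <- m["C", "G"] <- 1.03
  m["A", "U"] <- m["U", "A"] <- 1.03
  m["G", "U"] <- m["U", "G"] <- 1.02
  m
})

.check_bases <- function(b, arg) {
  bad <- !(b %in% RNA_BASES)
  if (any(bad)) {
    stop("Invalid RNA base(s) in `", arg, "`: ",
         paste(unique(b[bad]), collapse = ", "),
         " (alphabet is A, C, G, U)", call. = FALSE)
  }
  invisible(b)
}

#' Hydrogen bonds formed by a base pair
#'
#' Counts the hydrogen bonds contributed by one mRNA:miRNA base opposition.
#' Canonical Watson-Crick pairs contribute 3 (G-C) or 2 (A-U) bonds; the
#' non-canonical wobble pairs G-U and A-C contribute 1 bond each; every
#' other combination contributes none. The count is symmetric in its
#' arguments. Vectorized over both arguments.
#'
#' @param b1,b2 Character vectors of single RNA bases (`A`, `C`, `G`, `U`).
#' @return Integer vector of bond counts in `0:3`.
#' @examples
#' count_hbonds("G", "C")  # 3
#' count_hbonds("U", "G")  # 1 (wobble)
#' count_hbonds("A", "G")  # 0
#' @export
count_hbonds <- function(b1, b2) {
  .check_bases(b1, "b1")
  .check_bases(b2, "b2")
  .hbond_matrix[cbind(b1, b2)]
}

#' Internucleotide distance of a base pair
#'
#' Returns the internucleotide distance, in nanometers, for the recognized
#' pair types: 1.04 nm for A-C, 1.03 nm for G-C and A-U, 1.02 nm for G-U.
#' Unpaired combinations return `NA`.
#'
#' @inheritParams count_hbonds
#' @return Numeric vector of distances (nm), `NA` where the bases do not
#'   form a recognized pair.
#' @examples
#' pair_distance("A", "C")  # 1.04
#' pair_distance("C", "U")  # NA
#' @export
pair_distance <- function(b1, b2) {
  .check_bases(b1, "b1")
  .check_bases(b2, "b2")
  .distance_matrix[cbind(b1, b2)]
}

#' Duplex energy model
#'
#' Bundles the tunable constants of the hydrogen-bond energy model: the
#' per-bond energy scale `k_e` (kJ/mole per hydrogen bond) and the mode
#' used for the site-quality ratio.
#'
#' The free energy of a duplex is `dG = -k_e * total_hbonds`, and the
#' perfect-complement reference is `dGm = -k_e * (3 * nGC + 2 * nAU)` over
#' the miRNA's own composition. With `ratio_mode = "bonds"` (default) the
#' site ratio is `100 * dG / dGm`, which is invariant to `k_e`. With
#' `ratio_mode = "paired"` the ratio is the percentage of duplex positions
#' forming any recognized pair (e.g. 20 paired of 22 nt gives 91%).
#'
#' @param k_e Positive energy scale, kJ/mole per hydrogen bond. The default
#'   2.4 places a fully complementary mixed-composition 24-nt duplex near
#'   -150 kJ/mole.
#' @param ratio_mode `"bonds"` or `"paired"`.
#' @return An object of class `energy_model`.
#' @examples
#' energy_model()
#' energy_model(ratio_mode = "paired")
#' @export
energy_model <- function(k_e = 2.4, ratio_mode = c("bonds", "paired")) {
  if (!is.numeric(k_e) || length(k_e) != 1L || !is.finite(k_e) || k_e <= 0)
    stop("`k_e` must be a single positive number", call. = FALSE)
  ratio_mode <- match.arg(ratio_mode)
  structure(list(k_e = k_e, ratio_mode = ratio_mode),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> k_e =", x$k_e, "kJ/mole per H-bond; ratio_mode =",
      x$ratio_mode, "\n")
  invisible(x)
}

# Integer-encode an RNA string (A=1, C=2, G=3, U=4); errors on anything else.
.encode_rna <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(ch, RNA_BASES)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop("Non-ACGU character '", ch[pos], "' at position ", pos, call. = FALSE)
  }
  idx
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Used by all readers; exported because the
#' synthetic generator and tests share it.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector over `{A,C,G,U}` (unvalidated; readers validate).
#' @export
normalize_rna <- function(seq) {
  chartr("Tt", "Uu", toupper(seq))
}

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement (A-U, G-C), reversed. The reverse complement of a
#' miRNA is the mRNA window it binds with a perfect duplex.
#'
#' @param seq Character vector of RNA strings over `{A,C,G,U}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AUGC")  # "GCAU"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    ch <- rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Perfect-complement reference energy of a miRNA
#'
#' Free energy of the miRNA bound to its exact Watson-Crick complement:
#' `-k_e * (3 * nGC + 2 * nAU)` where `nGC` and `nAU` count G/C and A/U
#' bases in the miRNA. This is the normalization reference for the
#' site-quality ratio.
#'
#' @param mirna_seq A single RNA string (the miRNA, 5'-3').
#' @param model An [energy_model()].
#' @return Free energy in kJ/mole (<= 0).
#' @examples
#' dgm("AUGC")  # -(2 + 2 + 3 + 3) * 2.4 = -24
#' @export
dgm <- function(mirna_seq, model = energy_model()) {
  idx <- .encode_rna(mirna_seq)
  -model$k_e * sum(ifelse(idx %in% c(2L, 3L), 3, 2))
}

# Max bonds each miRNA base can form (G/C -> 3, A/U -> 2), by encoded base.
.max_bonds_by_code <- c(2, 3, 3, 2)

#' Score a gapless antiparallel miRNA:mRNA duplex
#'
#' Aligns a transcript window (mRNA, 5'-3') against the full-length miRNA in
#' antiparallel orientation: window position `i` opposes the miRNA base at
#' position `length - i + 1` (counted 5'-3'). No gaps, bulges or loops are
#' allowed. Each opposition contributes hydrogen bonds per [count_hbonds()];
#' the duplex free energy is `dG = -k_e * total_hbonds` and the quality
#' ratio is computed per the model's `ratio_mode`.
#'
#' @param mirna_seq RNA string of the miRNA (5'-3').
#' @param window RNA string of the mRNA window; must equal the miRNA length.
#' @param model An [energy_model()].
#' @return An object of class `duplex_scheme`: a list with `steps` (tibble
#'   with `mrna_base`, `mirna_base`, `hbonds`, `distance_nm`, `paired`),
#'   `total_hbonds`, `n_paired`, `dG`, `dGm`, `ratio_pct`.
#' @examples
#' d <- duplex("GGGG", "CCCC")
#' d$total_hbonds  # 12
#' d$ratio_pct     # 100
#' @export
duplex <- function(mirna_seq, window, model = energy_model()) {
  m_idx <- .encode_rna(mirna_seq)
  w_idx <- .encode_rna(window)
  if (length(m_idx) != length(w_idx)) {
    stop("Window length (", length(w_idx), ") must equal miRNA length (",
         length(m_idx), ")", call. = FALSE)
  }
  m_anti <- rev(m_idx)  # miRNA base opposing each window position
  hb <- .hbond_matrix[cbind(w_idx, m_anti)]
  paired <- hb > 0L
  total <- sum(hb)
  dG <- -model$k_e * total
  dGm_val <- -model$k_e * sum(.max_bonds_by_code[m_idx])
  ratio <- switch(model$ratio_mode,
    bonds  = if (dGm_val == 0) 0 else 100 * dG / dGm_val,
    paired = 100 * sum(paired) / length(m_idx)
  )
  steps <- tibble::tibble(
    mrna_base = RNA_BASES[w_idx],
    mirna_base = RNA_BASES[m_anti],
    hbonds = as.integer(hb),
    distance_nm = .distance_matrix[cbind(w_idx, m_anti)],
    paired = paired
  )
  structure(
    list(steps = steps, total_hbonds = as.integer(total),
         n_paired = sum(paired), dG = dG, dGm = dGm_val,
         ratio_pct = ratio, model = model),
    class = "duplex_scheme"
  )
}

#' Render a duplex pairing scheme as three aligned text lines
#'
#' Top line: mRNA window 5'-3'. Middle line: `|` for Watson-Crick pairs (2-3
#' bonds), `:` for 1-bond wobble pairs, space for unpaired. Bottom line:
#' miRNA 3'-5' (so opposing bases are in the same column).
#'
#' @param scheme A `duplex_scheme` from [duplex()].
#' @return A single string with three newline-separated lines.
#' @export
render_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "duplex_scheme"))
  s <- scheme$steps
  marks <- ifelse(s$hbonds >= 2L, "|", ifelse(s$hbonds == 1L, ":", " "))
  paste(
    paste0("5'-", paste(s$mrna_base, collapse = ""), "-3' mRNA"),
    paste0("   ", paste(marks, collapse = "")),
    paste0("3'-", paste(s$mirna_base, collapse = ""), "-5' miRNA"),
    sep = "\n"
  )
}

#' @export
print.duplex_scheme <- function(x, ...) {
  cat(render_scheme(x), "\n")
  cat(sprintf("hbonds %d; dG %.1f kJ/mole; dGm %.1f; ratio %.1f%% (%s)\n",
              x$total_hbonds, x$dG, x$dGm, x$ratio_pct, x$model$ratio_mode))
  invisible(x)
}
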