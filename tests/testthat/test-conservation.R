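# Ortholog flank identity, substitution classification and energy impact.

test_that("identical flanks give 100% identity", {
  core <- c(hsa = "ACGUACGUAC", ptr = "ACGUACGCAC", ggo = "ACGUUCGUAC")
  entries <- vapply(core, function(x) {
    paste0("GGGAGCAGCUG", x, "GAGCCUGAGCCGG")
  }, character(1))
  set <- ortholog_set("GENE", entries, flank5_len = 11, flank3_len = 13)
  fi <- flank_identity(set)
  expect_equal(fi$pct5, 100)
  expect_equal(fi$pct3, 100)
  expect_true(fi$all_identical5)
  expect_true(fi$all_identical3)
})

test_that("one mismatching flank column lowers identity to 10/11", {
  entries <- c(hsa = paste0("GGGAGCAGCUG", "AAAA"),
               ptr = paste0("GGGAGCAGCUG", "AAAA"),
               mmu = paste0("GGGAGCAGCUA", "AAAA"))
  set <- ortholog_set("GENE", entries, flank5_len = 11, flank3_len = 2)
  fi <- flank_identity(set)
  expect_equal(fi$pct5, 100 * 10 / 11)
  expect_false(fi$all_identical5)
})

test_that("two identical sequences are fully identical", {
  set <- ortholog_set("G", c(a = "ACGUACGU", b = "ACGUACGU"), 3, 3)
  fi <- flank_identity(set)
  expect_equal(c(fi$pct5, fi$pct3), c(100, 100))
  expect_error(ortholog_set("G", c(a = "ACGU", b = "ACGUA"), 2, 2),
               "equal length")
  expect_error(ortholog_set("G", c(a = "ACGU"), 2, 2), "two entries")
})

test_that("substitutions classify transitions, transversions and indels", {
  # exhaustive 12-pair truth table
  purines <- c("A", "G"); pyrimidines <- c("C", "U")
  for (ref in c(purines, pyrimidines)) {
    for (alt in setdiff(c(purines, pyrimidines), ref)) {
      rec <- substitutions(ref, alt)
      same_class <- (ref %in% purines) == (alt %in% purines)
      expect_identical(rec$klass,
                       if (same_class) "transition" else "transversion")
    }
  }
  expect_identical(substitutions("A-G", "AUG")$klass, "indel")
  expect_identical(nrow(substitutions("ACGU", "ACGU")), 0L)
})

test_that("C->U opposite a miRNA G keeps a wobble and costs 2 bonds", {
  # region position 1 opposes the miRNA's last base (antiparallel)
  mir <- "AAAG"           # reversed: G A A A
  rec <- substitutions("CAAA", "UAAA", mirna_seq = mir)
  expect_identical(rec$klass, "transition")
  expect_true(rec$wobble_preserving)     # G-C (3) -> G-U (1)
  expect_equal(rec$ddG, 2 * 2.4)
  # G->A opposite a miRNA C: transition, still paired via A-C
  rec2 <- substitutions("GAAA", "AAAA", mirna_seq = "AAAC")
  expect_identical(rec2$klass, "transition")
  expect_true(rec2$wobble_preserving)    # G-C (3) -> A-C (1)
})

test_that("substitutions are anti-symmetric under ref/alt swap", {
  set.seed(111)
  for (i in 1:20) {
    L <- 12
    ref <- random_rna(L)
    alt_ch <- strsplit(ref, "")[[1]]
    pos <- sample(L, 3)
    for (p in pos) alt_ch[p] <- sample(setdiff(c("A", "C", "G", "U"),
                                               alt_ch[p]), 1)
    alt <- paste(alt_ch, collapse = "")
    mir <- random_rna(L)
    fwd <- substitutions(ref, alt, mirna_seq = mir)
    rev_ <- substitutions(alt, ref, mirna_seq = mir)
    expect_identical(fwd$klass, rev_$klass)
    expect_equal(fwd$ddG, -rev_$ddG)
  }
})

test_that("ddG equals the duplex energy change recomputed from scratch", {
  set.seed(121)
  for (i in 1:20) {
    L <- 20
    mir <- random_rna(L)
    ref <- random_rna(L)
    alt_ch <- strsplit(ref, "")[[1]]
    pos <- sample(L, 2)
    for (p in pos) alt_ch[p] <- sample(setdiff(c("A", "C", "G", "U"),
                                               alt_ch[p]), 1)
    alt <- paste(alt_ch, collapse = "")
    recs <- substitutions(ref, alt, mirna_seq = mir)
    dref <- duplex(mir, ref)
    dalt <- duplex(mir, alt)
    # a destabilizing substitution (positive ddG) raises dG toward zero
    expect_equal(sum(recs$ddG), dalt$dG - dref$dG)
  }
})

test_that("wobble-preserving substitutions barely move the site ratio", {
  # for sites of >= 20 nt, a substitution keeping a recognized pair shifts
  # the paired-fraction ratio by < 5 percentage points
  set.seed(131)
  mdl <- energy_model(ratio_mode = "paired")
  for (i in 1:20) {
    mir <- random_rna(22)
    ref <- reverse_complement(mir)
    opp <- rev(strsplit(mir, "")[[1]])
    p <- sample(22, 1)
    wobble_alt <- switch(opp[p], G = "U", U = "G", A = "C", C = "A")
    alt_ch <- strsplit(ref, "")[[1]]
    if (alt_ch[p] == wobble_alt) next
    alt_ch[p] <- wobble_alt
    alt <- paste(alt_ch, collapse = "")
    rec <- substitutions(ref, alt, mirna_seq = mir)
    if (!all(rec$wobble_preserving)) next
    shift <- abs(duplex(mir, ref, mdl)$ratio_pct -
                   duplex(mir, alt, mdl)$ratio_pct)
    expect_lt(shift, 5)
  }
})

test_that("insert_report finds species-specific inserted runs", {
  set <- ortholog_set("TBC1D9", c(
    hsa = "AACGCAA",
    ptr = "AA---AA",
    ggo = "AA---AA"
  ), 2, 2)
  ins <- insert_report(set)
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$species, "hsa")
  expect_identical(ins$inserted, "CGC")
  expect_identical(ins$position, 3L)
  # no gaps -> empty; two separate 1-nt inserts -> two records
  none <- ortholog_set("X", c(a = "ACGU", b = "ACGU"), 1, 1)
  expect_identical(nrow(insert_report(none)), 0L)
  two <- ortholog_set("Y", c(a = "AUCGA", b = "A-C-A"), 1, 1)
  ins2 <- insert_report(two)
  expect_identical(nrow(ins2), 2L)
  expect_identical(ins2$inserted, c("U", "G"))
})
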