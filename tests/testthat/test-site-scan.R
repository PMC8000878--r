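# Sliding-window scan, region classification and range collapsing.

make_tx <- function(seq, utr5 = 0L, cds = NULL, utr3 = 0L, gene = "G") {
  L <- nchar(seq)
  if (is.null(cds)) cds <- L - utr5 - utr3
  tibble::tibble(gene = gene, seq = seq, utr5_len = as.integer(utr5),
                 cds_len = as.integer(cds), utr3_len = as.integer(utr3),
                 nx = NA_real_)
}

test_that("a planted exact complement is recovered at its start with 100%", {
  set.seed(21)
  mir <- tibble::tibble(id = "m1", seq = random_rna(22))
  tx_seq <- paste0(random_rna(49), reverse_complement(mir$seq),
                   random_rna(40))
  sites <- scan_sites(mir, make_tx(tx_seq), threshold_pct = 90)
  expect_true(any(sites$start == 50 & sites$ratio_pct == 100))
})

test_that("the ratio threshold is inclusive at exactly 90%", {
  # 20-nt miRNA: 18 paired positions = 90.0% kept; 17 = 85% excluded
  set.seed(22)
  mir <- random_rna(20)
  w90 <- window_with_paired(mir, 18)
  w85 <- window_with_paired(mir, 17)
  mdl <- energy_model(ratio_mode = "paired")
  mirs <- tibble::tibble(id = "m", seq = mir)
  bg <- strrep("A", 30)
  s90 <- scan_sites(mirs, make_tx(paste0(bg, w90, bg)), mdl, 90)
  expect_true(any(s90$start == 31 & s90$ratio_pct == 90))
  s85 <- scan_sites(mirs, make_tx(paste0(bg, w85, bg)), mdl, 90)
  expect_false(any(s85$start == 31))
})

test_that("adjacent overlapping starts are all reported", {
  # period-3 miRNA: its complement planted at 17, 20, 23 keeps all three
  # windows exact, so all three starts must be kept (no suppression)
  mir <- tibble::tibble(id = "m", seq = strrep("ACG", 8))  # 24 nt
  win <- reverse_complement(mir$seq)
  tx <- paste0(strrep("A", 16), substr(win, 1, 6), win, strrep("A", 40))
  sites <- scan_sites(mir, make_tx(tx), threshold_pct = 100)
  expect_true(all(c(17, 20, 23) %in% sites$start))
})

test_that("scan matches the brute-force oracle on random pairs", {
  set.seed(31)
  for (i in 1:40) {
    mir <- random_rna(sample(18:24, 1))
    tx <- random_rna(sample(80:200, 1))
    thr <- sample(c(70, 80, 90), 1)
    mode <- sample(c("bonds", "paired"), 1)
    got <- scan_sites(tibble::tibble(id = "m", seq = mir), make_tx(tx),
                      energy_model(ratio_mode = mode), thr)
    expect_identical(got$start, oracle_scan_starts(mir, tx, thr, mode))
  }
})

test_that("raising the threshold never adds sites", {
  set.seed(41)
  mir <- tibble::tibble(id = "m", seq = random_rna(20))
  tx <- make_tx(random_rna(400))
  lo <- scan_sites(mir, tx, threshold_pct = 70)
  hi <- scan_sites(mir, tx, threshold_pct = 80)
  expect_true(all(hi$start %in% lo$start))
})

test_that("a transcript shorter than the miRNA warns and yields no sites", {
  mir <- tibble::tibble(id = "m", seq = strrep("ACGU", 6))
  expect_warning(s <- scan_sites(mir, make_tx("ACGUACGU")), "shorter")
  expect_identical(nrow(s), 0L)
})

test_that("region classification is start-based with inclusive boundaries", {
  expect_identical(classify_region(100, 100, 200), "5UTR")
  expect_identical(classify_region(101, 100, 200), "CDS")
  expect_identical(classify_region(300, 100, 200), "CDS")
  expect_identical(classify_region(301, 100, 200), "3UTR")
  expect_identical(classify_region(1, 0, 200), "CDS")
  # labels partition the sites
  set.seed(51)
  starts <- sample(1:500, 50)
  regs <- classify_region(starts, 150, 200)
  expect_identical(sum(table(regs)), 50L)
})

test_that("collapse_ranges groups overlapping same-miRNA starts", {
  s <- make_sites(start = c(17, 20, 23), length = 23,
                  mirna_id = rep("mA", 3))
  r <- collapse_ranges(s)
  expect_identical(nrow(r), 1L)
  expect_identical(r$label, "17 ÷ 23 (3)")
  expect_identical(r$count, 3L)

  single <- collapse_ranges(make_sites(85, 24, mirna_id = "mB"))
  expect_identical(single$label, "85")

  far <- collapse_ranges(make_sites(c(100, 400), 23,
                                    mirna_id = c("mC", "mC")))
  expect_identical(nrow(far), 2L)
})

test_that("range formatting follows the printed notation", {
  expect_identical(format_range(4042L, 4062L, 11L), "4042 ÷ 4062 (11)")
  expect_identical(format_range(2288L, 2290L, 2L), "2288, 2290")
  expect_identical(format_range(85L, 85L, 1L), "85")
  expect_identical(format_range(17L, 23L, 3L, glyph = "-"), "17 - 23 (3)")
  expect_identical(format_energy_range(-129.4, -140.2), "-129 ÷ -140")
  expect_identical(format_energy_range(-115, -115), "-115")
})

test_that("printed start ranges expand to the printed count of starts", {
  expect_identical(expand_start_range("85")[[1]], 85L)
  expect_identical(expand_start_range("2288, 2290")[[1]], c(2288L, 2290L))
  expect_identical(expand_start_range("17 ÷ 23 (3)")[[1]],
                   c(17L, 20L, 23L))
  x <- expand_start_range("4042 ÷ 4062 (11)")[[1]]
  expect_length(x, 11L)
  expect_identical(range(x), c(4042L, 4062L))
})
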