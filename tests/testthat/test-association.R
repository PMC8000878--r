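# Effective-energy filtering, association tables, the suppression model,
# competition ranking and the NX report.

test_that("effective_sites applies region-specific energy thresholds", {
  s <- make_sites(c(10, 40, 70), 23, mirna_id = c("a", "b", "c"),
                  region = c("5UTR", "5UTR", "3UTR"))
  s$dG <- c(-134, -125, -119)
  kept <- effective_sites(s)
  expect_setequal(kept$mirna_id, c("a", "c"))  # -134 passes -130; -119 passes -115
  expect_error(effective_sites(s, c("5UTR" = 130, "CDS" = -130,
                                    "3UTR" = -115)), "negative")
  expect_error(effective_sites(s, c("5UTR" = -130)), "3UTR")
})

test_that("loosening a threshold never removes an effective site", {
  set.seed(91)
  s <- make_sites(sample(1:500, 40), 23,
                  region = sample(c("5UTR", "CDS", "3UTR"), 40,
                                  replace = TRUE))
  s$dG <- -runif(40, 100, 150)
  strict <- effective_sites(s)
  loose <- effective_sites(s, c("5UTR" = -120, "CDS" = -120,
                                "3UTR" = -105))
  expect_true(all(paste(strict$mirna_id, strict$start) %in%
                    paste(loose$mirna_id, loose$start)))
})

test_that("alternatives keeps only miRNAs/genes with 2+ partners", {
  s <- dplyr::bind_rows(
    make_sites(c(1, 1, 1, 1, 1, 1), 20, gene = "GA",
               mirna_id = c("hub", "m1", "m2", "m3", "m4", "m5")),
    make_sites(rep(1, 5), 20, gene = "GB",
               mirna_id = c("hub", "m1", "m9", "m9", "solo_m")),
    make_sites(1, 20, gene = "GC", mirna_id = "hub")
  )
  alt <- alternatives(s)
  hub <- alt$mirna_to_genes[alt$mirna_to_genes$mirna_id == "hub", ]
  expect_identical(hub$n_genes, 3L)
  expect_identical(hub$genes[[1]], c("GA", "GB", "GC"))
  # m9 has two sites but one gene; solo_m one site: both absent
  expect_false(any(c("m9", "solo_m") %in% alt$mirna_to_genes$mirna_id))
  # GC hit only by hub: absent from the gene table
  expect_false("GC" %in% alt$gene_to_mirnas$gene)
  ga <- alt$gene_to_mirnas[alt$gene_to_mirnas$gene == "GA", ]
  expect_identical(ga$n_mirnas, 6L)
  # order invariance and witnessing
  alt2 <- alternatives(s[sample(nrow(s)), ])
  expect_identical(alt$mirna_to_genes, alt2$mirna_to_genes)
  for (i in seq_len(nrow(alt$mirna_to_genes))) {
    m <- alt$mirna_to_genes$mirna_id[i]
    for (g in alt$mirna_to_genes$genes[[i]]) {
      expect_true(any(s$mirna_id == m & s$gene == g))
    }
  }
})

test_that("suppression follows the occupancy form", {
  expect_equal(suppression(1, 1), 50)
  expect_equal(suppression(1, 10), 100 / 11)     # ~9.1, printed as 10%
  expect_equal(suppression(10, 1), 1000 / 11)    # ~90.9, printed as 90%
  expect_lt(abs(suppression(1, 10) - 10), 1)
  expect_lt(abs(suppression(10, 1) - 90), 1)
  expect_equal(suppression(0), 0)
  set.seed(101)
  for (R in exp(runif(50, -5, 5))) {
    expect_equal(suppression(R) + suppression(1 / R), 100)
  }
  expect_error(suppression(-1), "non-negative")
  expect_error(suppression(1, 0), "positive")
})

test_that("competition ranking weighs expression against energy", {
  m <- tibble::tibble(mirna_id = c("miR-619-5p", "miR-5095"),
                      dG = c(-121, -117))
  r <- competition_rank(m, c("miR-5095" = 4.8))
  expect_identical(r$mirna_id[1], "miR-5095")   # 4.8 * 117 > 121
  expect_equal(r$score, c(4.8 * 117, 121))
  # equal expression: stronger (more negative) dG first
  r2 <- competition_rank(tibble::tibble(mirna_id = c("a", "b"),
                                        dG = c(-110, -130)))
  expect_identical(r2$mirna_id[1], "b")
  # single member ranks alone
  r3 <- competition_rank(tibble::tibble(mirna_id = "x", dG = -120))
  expect_identical(r3$mirna_id, "x")
  # ties break lexicographically
  r4 <- competition_rank(tibble::tibble(mirna_id = c("z", "y"),
                                        dG = c(-120, -120)))
  expect_identical(r4$mirna_id, c("y", "z"))
})

test_that("nx_site_report counts sites and multi-member clusters", {
  tx <- tibble::tibble(gene = c("HI", "LO", "ZERO"),
                       nx = c(25.2, 3.4, 1.0))
  s <- dplyr::bind_rows(
    make_sites(1, 20, gene = "HI", mirna_id = "m1"),
    make_sites(c(50, 55, 60, 100), 20, gene = "LO",
               mirna_id = c("a", "b", "c", "d"))
  )
  rep <- nx_site_report(tx, s)
  expect_identical(rep$gene, c("HI", "LO", "ZERO"))  # NX descending
  expect_identical(rep$n_sites, c(1L, 4L, 0L))
  expect_identical(rep$n_multi_clusters, c(0L, 1L, 0L))
})
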