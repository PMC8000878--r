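# Cluster detection (interval connected components), compaction statistics
# and the printed-claim consistency checker.

test_that("published 5'UTR rows reproduce the printed cluster statistics", {
  arid <- published_sites("5UTR") |> dplyr::filter(gene == "ARID1A")
  cl <- find_clusters(arid)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$span_start, 136L)
  expect_identical(cl$span_end, 192L)
  expect_identical(cl$span_len, 57L)
  expect_identical(cl$sum_len, 272L)
  expect_equal(cluster_stats(cl)$compaction, 4.8)

  e2f1 <- published_sites("5UTR") |> dplyr::filter(gene == "E2F1")
  expect_identical(find_clusters(e2f1)$sum_len, 148L)

  pik <- published_sites("5UTR") |> dplyr::filter(gene == "PIK3CA")
  expect_identical(find_clusters(pik)$sum_len, 282L)
})

test_that("published CDS rows reproduce the first cluster's statistics", {
  arid_cds <- published_sites("CDS") |> dplyr::filter(gene == "ARID1A")
  cl <- find_clusters(arid_cds)
  first <- cl[which.max(cl$n_members), ]
  expect_identical(first$span_start, 410L)
  expect_identical(first$span_len, 32L)
  expect_identical(first$sum_len, 184L)
  expect_equal(round(first$compaction, 1), 5.8)
})

test_that("disjoint sites form singleton clusters with compaction 1", {
  cl <- find_clusters(make_sites(c(1, 30), c(20, 21)))
  expect_identical(nrow(cl), 2L)
  expect_equal(cl$compaction, c(1, 1))
})

test_that("transitive overlap joins sites into one cluster", {
  cl <- find_clusters(make_sites(c(1, 5, 12), c(10, 10, 10)))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 3L)
  # touching but disjoint intervals do not connect
  cl2 <- find_clusters(make_sites(c(1, 11), c(10, 10)))
  expect_identical(nrow(cl2), 2L)
})

test_that("clustering equals igraph connected components on random sets", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    start <- sample(1:400, n, replace = TRUE)
    len <- sample(15:30, n, replace = TRUE)
    s <- make_sites(start, len)
    got <- assign_clusters(s)
    want <- oracle_cluster_membership(start, len)
    # same partition: joint table is a permutation matrix
    ord <- match(paste(got$start, got$length), paste(start, len))
    tab <- table(got$cluster, want[ord])
    expect_identical(sum(tab > 0), length(unique(got$cluster)))
    expect_identical(length(unique(got$cluster)),
                     length(unique(want)))
  }
})

test_that("compaction is at least 1, exceeding 1 exactly for overlaps", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    s <- make_sites(sample(1:300, n, replace = TRUE),
                    sample(15:30, n, replace = TRUE))
    cl <- find_clusters(s)
    expect_true(all(cl$compaction >= 1))
    expect_true(all(cl$compaction[cl$n_members == 1] == 1))
    expect_true(all(cl$compaction[cl$n_members > 1] > 1))
    expect_identical(sum(cl$n_members), nrow(s))
  }
})

test_that("clusters are invariant to input order", {
  set.seed(81)
  s <- make_sites(sample(1:300, 30, replace = TRUE),
                  sample(15:30, 30, replace = TRUE))
  a <- find_clusters(s)
  b <- find_clusters(s[sample(nrow(s)), ])
  expect_identical(a[, c("span_start", "span_end", "sum_len", "n_members")],
                   b[, c("span_start", "span_end", "sum_len", "n_members")])
})

test_that("cluster_table lists one row per member run with range labels", {
  s <- make_sites(c(10, 14, 17, 20), 22,
                  mirna_id = c("mA", "mB", "mB", "mB"))
  tab <- cluster_table(find_clusters(s))
  expect_identical(nrow(tab), 2L)
  expect_identical(sort(tab$mirna_id), c("mA", "mB"))
  expect_identical(tab$starts[tab$mirna_id == "mB"], "14 ÷ 20 (3)")
  expect_true(all(tab$compaction >= 1))
  # NX flows through from the transcripts table
  tx <- tibble::tibble(gene = "G", nx = 19.5)
  expect_equal(unique(cluster_table(find_clusters(s), tx)$nx), 19.5)
})

test_that("the claim checker flags underivable printed compactions", {
  chk <- check_cluster_claims(published_sites(c("5UTR", "CDS")),
                              published_cluster_claims())
  flagged <- chk$gene[!chk$compaction_consistent]
  expect_setequal(flagged, c("ODC1", "MAPK1"))
  # the checker reports the table-derived values alongside
  odc1 <- chk[chk$gene == "ODC1", ]
  expect_identical(odc1$sum_len_derived, 463L)
  expect_false(isTRUE(all.equal(odc1$compaction_derived, 10.6)))
  mapk1 <- chk[chk$gene == "MAPK1", ]
  expect_identical(mapk1$sum_len_derived, 94L)
  # every printed span reconciles within a nucleotide
  expect_true(all(chk$span_consistent))
  # printed summed lengths reproduce exactly wherever stated
  expect_true(all(chk$sum_len_consistent, na.rm = TRUE))
})
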