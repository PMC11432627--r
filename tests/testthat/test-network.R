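test_that("collapsed network keeps duplicates but merges overlapping enhancers", {
  a <- make_epi("chr1", 100L, "G1", "ESC", tss = 10000)
  a$end <- 600L
  b <- make_epi("chr1", 500L, "G2", "NSC", tss = 10000)
  b$end <- 1000L
  col <- build_collapsed_network(list(ESC = a, NSC = b))
  expect_equal(nrow(col$records), 2L)
  expect_equal(col$merged_enhancers,
               data.frame(chrom = "chr1", start = 100L, end = 1000L))

  # same EPI in 3 cell types: 3 rows, 1 merged enhancer
  same <- lapply(c("ESC", "NSC", "NPC"), function(ct)
    make_epi("chr1", 1000L, "G1", ct))
  names(same) <- c("ESC", "NSC", "NPC")
  col2 <- build_collapsed_network(same)
  expect_equal(nrow(col2$records), 3L)
  expect_equal(nrow(col2$merged_enhancers), 1L)

  # disjoint single-EPI networks stay apart
  six <- lapply(1:6, function(i) make_epi("chr1", i * 5000L, paste0("G", i),
                                          names(default_stages())[i]))
  names(six) <- names(default_stages())
  col3 <- build_collapsed_network(six)
  expect_equal(nrow(col3$records), 6L)
  expect_equal(nrow(col3$merged_enhancers), 6L)
})

test_that("gap merge clusters transitively within the gap and is idempotent", {
  x <- data.frame(chrom = "chr1", start = c(100L, 650L), end = c(600L, 1150L))
  m <- merge_within_gap(x, gap = 100)  # separation 50 <= 100
  expect_equal(m$clusters, data.frame(chrom = "chr1", start = 100L, end = 1150L))
  expect_equal(m$membership, c(1L, 1L))

  y <- data.frame(chrom = "chr1", start = c(100L, 750L), end = c(600L, 1250L))
  m2 <- merge_within_gap(y, gap = 100)  # separation 150 > 100
  expect_equal(nrow(m2$clusters), 2L)

  # gap = 0 is plain overlap/adjacency merging
  z <- data.frame(chrom = "chr1", start = c(100L, 600L, 1200L),
                  end = c(600L, 1100L, 1700L))
  m3 <- merge_within_gap(z, gap = 0)
  expect_equal(nrow(m3$clusters), 2L)

  # idempotence: merging a merged set changes nothing
  again <- merge_within_gap(m3$clusters, gap = 0)
  expect_equal(again$clusters, m3$clusters)
})

test_that("subset categories follow the documented decision order", {
  st <- default_stages()
  expect_equal(assign_subset_category(c(0.05, 0, 0, 0, 0, 0), st), "ESC")
  expect_equal(assign_subset_category(c(0.03, 0.04, 0, 0, 0, 0), st), "Progenitor")
  expect_equal(assign_subset_category(c(0, 0, 0, 0.03, 0.04, 0), st), "Mature")
  expect_equal(assign_subset_category(c(0.03, 0, 0, 0.04, 0, 0), st), "Removed")
  # 3 progenitor + 2 mature = 5 non-zero: Ubi wins over mixed-removal
  expect_equal(assign_subset_category(c(0.1, 0.1, 0.1, 0.1, 0.1, 0), st), "Ubi")
  expect_error(assign_subset_category(c(0.1, 0.1), st), "length 6")
  expect_error(assign_subset_category(rep(0, 6), st), "zero")
})

test_that("subset network aggregates member scores per cell type", {
  st <- default_stages()
  nets <- list(
    ESC = make_epi("chr1", c(1000L, 1550L), c("G1", "G1"), "ESC",
                   score = c(0.05, 0.09)),       # within 100 bp: one cluster
    NSC = make_epi("chr1", 1000L, "G1", "NSC", score = 0.03),
    NPC = make_epi("chr1", 50000L, "G2", "NPC", score = 0.04),
    AD = make_epi("chr1", 50000L, "G2", "AD", score = 0.02),
    Ngn2 = make_epi("chr2", 1000L, "G3", "Ngn2", score = 0.05),
    Motor = make_epi("chr2", 90000L, "G4", "Motor", score = 0.05)
  )
  sub <- build_subset_network(nets, st)
  sub <- sub[order(sub$chrom, sub$start), ]
  # cluster 1: ESC (max of 0.05/0.09) + NSC -> Progenitor
  expect_equal(sub$category, c("Progenitor", "Removed", "Ngn2", "Motor"))
  expect_equal(sub$ESC[1], 0.09)
  expect_equal(sub$NSC[1], 0.03)
  submean <- build_subset_network(nets, st, agg = "mean")
  submean <- submean[order(submean$chrom, submean$start), ]
  expect_equal(submean$ESC[1], 0.07)
})

test_that("C1-C4 labels follow the enhancer/promoter degree 2x2", {
  lone <- make_epi("chr1", 1000L, "G1")
  expect_equal(classify_substructure(lone), "C1")

  fanout <- make_epi("chr1", c(1000L, 1000L), c("G1", "G2"))
  expect_equal(classify_substructure(fanout), c("C2", "C2"))

  # edges {E1-G1, E1-G2, E2-G1}: worked degree table
  g <- make_epi("chr1", c(1000L, 1000L, 9000L), c("G1", "G2", "G1"))
  expect_equal(classify_substructure(g), c("C4", "C2", "C3"))
  expect_equal(unname(substructure_distribution(classify_substructure(g))),
               c(0, 1/3, 1/3, 1/3))

  iso <- make_epi("chr1", c(1000L, 9000L, 17000L), paste0("G", 1:3))
  expect_equal(unname(substructure_distribution(classify_substructure(iso))),
               c(1, 0, 0, 0))
  expect_error(substructure_distribution(character(0)), "empty")
})

test_that("labels agree with a brute-force degree oracle on random networks", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    rec <- make_epi("chr1", sample(seq(1000L, 200000L, by = 1000L), n),
                    paste0("G", sample.int(max(2, n %/% 3), n, replace = TRUE)))
    rec <- rec[!duplicated(paste(rec$start, rec$target_gene)), ]
    expect_equal(classify_substructure(rec), substructure_bruteforce(rec))
    d <- substructure_distribution(classify_substructure(rec))
    expect_equal(sum(d), 1)
  }
})

test_that("degree maps are consistent with the records", {
  g <- make_epi("chr1", c(1000L, 1000L, 9000L), c("G1", "G2", "G1"))
  deg <- network_degrees(g)
  expect_equal(unname(deg$enhancer_degree[interval_key(g)[1]]), 2L)
  expect_equal(unname(deg$promoter_degree["G1"]), 2L)
  expect_true(all(deg$enhancer_degree >= 1))
})

test_that("dropping cross-cell-type duplicates shifts weight toward C1+C2", {
  # a shared promoter regulated by a shared enhancer (duplicated across
  # cell types) and by specific enhancers: duplicate rows overweight the
  # C3/C4 side, so deduplicating weakly raises the C1+C2 share
  nets <- list(
    ESC = make_epi("chr1", c(1000L, 9000L), c("GS", "GS"), "ESC"),
    NSC = make_epi("chr1", c(1000L, 17000L), c("GS", "G2"), "NSC"),
    NPC = make_epi("chr1", 1000L, "GS", "NPC")
  )
  col <- build_collapsed_network(nets)$records
  lab_dup <- classify_substructure(col)
  pair <- paste(interval_key(col), col$target_gene)
  lab_uni <- classify_substructure(col[!duplicated(pair), ])
  share <- function(l) mean(l %in% c("C1", "C2"))
  expect_gte(share(lab_uni), share(lab_dup))

  # and on generated data under the default sharing structure
  epi <- generate_epi_tables(small_config(seed = 3))
  col2 <- build_collapsed_network(epi$networks)$records
  pair2 <- paste(interval_key(col2), col2$target_gene)
  expect_gte(share(classify_substructure(col2[!duplicated(pair2), ])),
             share(classify_substructure(col2)))
})
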