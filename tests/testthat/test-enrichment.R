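test_that("promoter regions are strand-aware and clipped at chromosome bounds", {
  genes <- data.frame(chrom = "chr1",
                      start = c(10000L, 5000L, 1500L),
                      end = c(12000L, 20000L, 3000L),
                      strand = c("+", "-", "+"),
                      name = c("GA", "GB", "GC"))
  expect_warning(pr <- derive_promoter_regions(genes), "clipped")
  expect_equal(pr[pr$name == "GA", c("start", "end")],
               data.frame(start = 8000L, end = 10000L), ignore_attr = TRUE)
  expect_equal(pr[pr$name == "GB", c("start", "end")],
               data.frame(start = 20000L, end = 22000L), ignore_attr = TRUE)
  expect_equal(pr[pr$name == "GC", c("start", "end")],
               data.frame(start = 0L, end = 1500L), ignore_attr = TRUE)
  genes$strand[1] <- "."
  expect_error(derive_promoter_regions(genes), "strand")
})

test_that("elements count once however many variants they contain", {
  el <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                   end = c(500L, 1500L, 2500L))
  v5 <- data.frame(chrom = "chr1", start = c(10L, 20L, 30L, 40L, 50L),
                   end = c(11L, 21L, 31L, 41L, 51L))
  expect_equal(count_elements_with_variant(el[1, ], v5), 1L)
  outside <- data.frame(chrom = "chr1", start = 900L, end = 901L)
  expect_equal(count_elements_with_variant(el, outside), 0L)
  v2 <- data.frame(chrom = "chr1", start = c(100L, 2100L), end = c(101L, 2101L))
  # brute-force per-element scan oracle
  oracle <- sum(vapply(seq_len(nrow(el)), function(i)
    any(v2$start >= el$start[i] & v2$start < el$end[i]), logical(1)))
  expect_equal(count_elements_with_variant(el, v2), oracle)
  expect_equal(oracle, 2L)
})

test_that("empirical p matches the exact hypergeometric tail on small pools", {
  pool <- data.frame(chrom = "chr1", start = seq(0L, 4000L, by = 1000L),
                     end = seq(500L, 4500L, by = 1000L))
  variants <- data.frame(chrom = "chr1", start = c(100L, 1100L),
                         end = c(101L, 1101L))  # elements 1 and 2 bear
  target <- pool[1:2, ]
  res <- empirical_enrichment_test(target, pool, variants, kind = "enhancer",
                                   R = 10000, seed = 3)
  expect_equal(res$observed, 2L)
  # exact tail: P(X >= 2) with 2 bearing of 5, draw 2 = 1/C(5,2) = 0.1
  expect_equal(hyper_tail_ge(2, 2, 5, 2), 0.1)
  expect_lt(abs(res$p_empirical - 0.1), 0.01)
  expect_true(res$nominal || res$p_empirical > 0.05)

  # degenerate: target = pool, every draw identical, p = 1
  res2 <- empirical_enrichment_test(pool, pool, variants, R = 200, seed = 1)
  expect_equal(res2$p_empirical, 1)
  expect_error(empirical_enrichment_test(rbind(pool, transform(pool, chrom = "chr2")),
                                         pool, variants, R = 10),
               "more elements")
})

test_that("empirical test is seed-reproducible and thresholds are applied", {
  pool <- data.frame(chrom = "chr1", start = seq(0L, 19000L, by = 1000L),
                     end = seq(500L, 19500L, by = 1000L))
  variants <- data.frame(chrom = "chr1", start = c(100L, 3100L, 7100L),
                         end = c(101L, 3101L, 7101L))
  a <- empirical_enrichment_test(pool[1:6, ], pool, variants, R = 500, seed = 9)
  b <- empirical_enrichment_test(pool[1:6, ], pool, variants, R = 500, seed = 9)
  expect_identical(a$null_counts, b$null_counts)
  expect_equal(a$threshold, 0.008333)
  # legacy estimator can reach zero; default never does
  expect_gt(a$p_empirical, 0)
})

test_that("gene-kind enrichment uses exact full-symbol matching", {
  pool <- c("SOX2", "SOX21", "NANOG", "POU5F1", "OTX2")
  geneset <- c("SOX2", "GATA3")
  res <- empirical_enrichment_test(c("SOX21", "NANOG"), pool, geneset,
                                   kind = "gene", R = 100, seed = 1)
  expect_equal(res$observed, 0L)  # SOX21 does not match SOX2
  res2 <- empirical_enrichment_test(c("SOX2", "NANOG"), pool, geneset,
                                    kind = "gene", R = 100, seed = 1)
  expect_equal(res2$observed, 1L)
})

test_that("empirical p-values are approximately uniform under the null", {
  set.seed(77)
  n_pool <- 600L
  pool <- data.frame(chrom = "chr1",
                     start = seq(0L, (n_pool - 1L) * 1000L, by = 1000L))
  pool$end <- pool$start + 500L
  ps <- vapply(1:500, function(r) {
    v <- data.frame(chrom = "chr1",
                    start = sample.int(n_pool * 1000L, 700L) - 1L)
    v$end <- v$start + 1L
    tgt <- pool[sample.int(n_pool, 300L), ]
    empirical_enrichment_test(tgt, pool, v, R = 199, seed = r)$p_empirical
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("Fisher wrapper agrees exactly with exhaustive enumeration", {
  bal <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(bal$p_two_sided, 1)
  diag2 <- fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))
  expect_equal(diag2$p_two_sided, 1 / 3, tolerance = 1e-12)
  diag10 <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag10$p_two_sided, 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  cp <- fisher_exact_2x2(matrix(c(6, 2, 3, 9), 2), or_method = "cross_product")
  expect_equal(cp$odds_ratio, (6 * 9) / (2 * 3))

  set.seed(5)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided, fisher_enum_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("monotonicity: growing the target never lowers the observed count", {
  pool <- data.frame(chrom = "chr1", start = seq(0L, 29000L, by = 1000L),
                     end = seq(500L, 29500L, by = 1000L))
  v <- data.frame(chrom = "chr1", start = c(100L, 5100L, 9100L),
                  end = c(101L, 5101L, 9101L))
  obs <- vapply(1:20, function(k)
    count_elements_with_variant(pool[1:k, ], v), integer(1))
  expect_true(all(diff(obs) >= 0))
})

test_that("sub-structure Fisher contrast builds the documented 2x2", {
  el <- data.frame(chrom = "chr1",
                   start = c(0L, 1000L, 2000L, 3000L),
                   end = c(500L, 1500L, 2500L, 3500L),
                   label = c("C3", "C3", "C4", "C1"))
  case <- data.frame(chrom = "chr1", start = c(10L, 1010L, 2010L),
                     end = c(11L, 1011L, 2011L))
  ctrl <- data.frame(chrom = "chr1", start = c(2020L, 3020L, 9000L),
                     end = c(2021L, 3021L, 9001L))
  f <- substructure_variant_fisher(el, case, ctrl, "C3")
  expect_equal(unname(f$table), rbind(c(2L, 1L), c(0L, 2L)))
  expect_error(substructure_variant_fisher(el, case, ctrl, "C2"), "C2")
  none <- data.frame(chrom = "chr2", start = 1L, end = 2L)
  expect_error(substructure_variant_fisher(el, none, none, "C3"),
               "no variant")
})

test_that("LFC contingency applies strict FDR and LFC cuts", {
  de <- data.frame(gene = paste0("G", 1:6),
                   lfc = c(2, 1.0, -2, 0.5, 1.5, -1.5),
                   fdr = c(0.01, 0.01, 0.02, 0.03, 0.05, 0.04))
  tab <- build_lfc_contingency(de, genes_a = paste0("G", 1:6),
                               genes_b = character(0), direction = "up")
  # G5 excluded (FDR == 0.05); G2 has LFC exactly 1 -> fails strict cut
  expect_equal(tab["network_a", "passes_lfc"], 1L)  # only G1
  expect_equal(sum(tab["network_a", ]), 5L)
  tabd <- build_lfc_contingency(de, genes_a = paste0("G", 1:6),
                                genes_b = character(0), direction = "down")
  expect_equal(tabd["network_a", "passes_lfc"], 2L)  # G3, G6
  expect_error(build_lfc_contingency(de[de$fdr > 0.9, ], "G1", "G2"),
               "FDR")
})

test_that("planted differential expression is recovered between networks", {
  cfg <- small_config(seed = 21)
  epi <- generate_epi_tables(cfg)
  ex <- generate_expression_and_genesets(cfg, epi)
  a <- ex$truth$comparison[1]; b <- ex$truth$comparison[2]
  tab <- build_lfc_contingency(ex$de, unique(epi$networks[[b]]$target_gene),
                               unique(epi$networks[[a]]$target_gene),
                               direction = "up")
  f <- fisher_exact_2x2(tab)
  expect_gt(f$odds_ratio, 1)
})
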