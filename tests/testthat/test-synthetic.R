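test_that("genome generation echoes the configuration deterministically", {
  cfg <- small_config(seed = 1)
  g <- generate_genome(cfg)
  expect_equal(nrow(g), 2L)
  expect_equal(g$length, rep(1e7, 2))
  expect_identical(g, generate_genome(small_config(seed = 1)))
  expect_error(sim_config(chrom_length = 0))
  expect_error(sim_config(frac_celltype_specific_enh = 0.8,
                          frac_stage_shared_enh = 0.5), "sum")
})

test_that("identical config and seed reproduce every table exactly", {
  cfg <- small_config(seed = 13)
  e1 <- generate_epi_tables(cfg)
  e2 <- generate_epi_tables(cfg)
  expect_identical(e1$networks, e2$networks)
  expect_identical(e1$tpm, e2$tpm)
  t1 <- generate_tfbs_table(cfg, e1)
  t2 <- generate_tfbs_table(cfg, e2)
  expect_identical(t1$fimo, t2$fimo)
  v1 <- generate_variant_sets(cfg, generate_genome(cfg))
  v2 <- generate_variant_sets(cfg, generate_genome(cfg))
  expect_identical(v1$case, v2$case)
})

test_that("manifest sharing classes match the generated data exactly", {
  cfg <- small_config(seed = 8)
  epi <- generate_epi_tables(cfg)
  man <- epi$manifest
  n_enh <- cfg$n_enhancers_per_celltype
  expect_equal(man$n_specific + man$n_stage_shared + man$n_ubiquitous, n_enh)
  # each network's enhancer count equals the configured size
  for (ct in names(epi$networks)) {
    expect_equal(nrow(unique(epi$networks[[ct]][, c("chrom", "start", "end")])),
                 n_enh)
  }
  # specific enhancers appear in exactly their own network, ubiquitous in six
  counts <- table(interval_key(do.call(rbind, lapply(epi$networks, function(x)
    unique(x[, c("chrom", "start", "end")])))))
  key_of <- interval_key(man$enhancers)
  expect_true(all(counts[key_of[man$enhancers$class == "specific"]] == 1L))
  expect_true(all(counts[key_of[man$enhancers$class == "stage_shared"]] == 3L))
  expect_true(all(counts[key_of[man$enhancers$class == "ubiquitous"]] == 6L))
  # every enhancer within 5 Mb of its target TSS and exactly 500 bp wide
  col <- build_collapsed_network(epi$networks)$records
  expect_true(all(col$end - col$start == 500L))
  expect_true(all(abs((col$start + col$end) / 2 - col$tss) <= 5e6))
})

test_that("score and expression fractions straddle the filters as configured", {
  cfg <- small_config(seed = 15, frac_low_abc = 0.3, frac_low_tpm = 0.25)
  epi <- generate_epi_tables(cfg)
  col <- build_collapsed_network(epi$networks)$records
  expect_equal(mean(col$abc_score < 0.02), 0.3, tolerance = 0.05)
  expect_equal(mean(epi$tpm <= 1), 0.25, tolerance = 0.05)

  # nothing below either filter: filter_epis is a no-op
  cfg0 <- small_config(seed = 16, frac_low_abc = 0, frac_low_tpm = 0)
  epi0 <- generate_epi_tables(cfg0)
  col0 <- build_collapsed_network(epi0$networks)$records
  expect_equal(nrow(filter_epis(col0)), nrow(col0))
})

test_that("jittered shared enhancers stay within 100 bp and still merge", {
  cfg <- small_config(seed = 17, shared_jitter = 60)
  epi <- generate_epi_tables(cfg)
  man <- epi$manifest$enhancers
  ubi <- man[man$class == "ubiquitous", ]
  # the jittered copies across cell types merge back into one cluster each
  col <- build_collapsed_network(epi$networks)
  sub <- build_subset_network(epi$networks)
  expect_lte(nrow(sub), nrow(man))
  for (ct in names(epi$networks)) {
    enh <- unique(epi$networks[[ct]][, c("chrom", "start", "end")])
    hit <- overlap_elements(ubi[, c("chrom", "start", "end")], enh)
    expect_true(all(hit))  # jitter <= 100 < width, so copies still overlap
  }
})

test_that("variant generation is uniform without planting and errors sensibly", {
  cfg <- small_config(seed = 19)
  g <- generate_genome(cfg)
  v <- generate_variant_sets(cfg, g)
  expect_equal(nrow(v$case), cfg$n_case_variants)
  expect_equal(nrow(v$control), cfg$n_control_variants)
  expect_true(all(v$case$end - v$case$start == 1L))
  expect_false(any(v$case_planted))

  cfg0 <- small_config(seed = 19, n_case_variants = 0)
  v0 <- generate_variant_sets(cfg0, g)
  expect_equal(nrow(v0$case), 0L)

  cfgp <- small_config(seed = 19,
                       planted_enrichment = list(substructure = "C2",
                                                 multiplier = 3))
  el <- data.frame(chrom = "chr1", start = 0L, end = 500L, label = "C1")
  expect_error(generate_variant_sets(cfgp, g, el), "C2")
  expect_error(generate_variant_sets(cfgp, g, NULL), "required")
})

test_that("null planting leaves case and control statistically exchangeable", {
  cfg <- small_config(seed = 23)
  epi <- generate_epi_tables(cfg)
  el <- substructure_elements(epi$networks)
  v <- generate_variant_sets(cfg, generate_genome(cfg), el)
  f <- substructure_variant_fisher(el, v$case, v$control, "C3")
  expect_gt(f$p_two_sided, 0.001)  # no systematic case/control difference
})

test_that("disease gene list overlaps targets at the planted fraction", {
  cfg <- small_config(seed = 25, disease_overlap_frac = 0.5)
  epi <- generate_epi_tables(cfg)
  ex <- generate_expression_and_genesets(cfg, epi)
  tgt <- unique(unlist(lapply(cfg$disease_celltypes,
                              function(ct) epi$networks[[ct]]$target_gene)))
  expect_equal(mean(ex$disease_genes %in% tgt), 0.5, tolerance = 0.05)
  expect_equal(length(ex$disease_genes), cfg$n_disease_genes)
  # TPM tables round-trip through the two-column format
  path <- withr::local_tempfile()
  write_tpm_table(ex$tpm_tables$ESC, path)
  expect_identical(read_tpm_table(path), ex$tpm_tables$ESC)
})

test_that("activity peaks feed end-to-end ABC scoring", {
  cfg <- small_config(seed = 27)
  epi <- generate_epi_tables(cfg)
  peaks <- generate_activity_peaks(cfg, epi)
  esc <- peaks$ESC[peaks$ESC$chrom == "chr1", ]
  tss <- as.integer(median(esc$start))
  sc <- compute_abc_scores(esc, tss = tss)
  expect_equal(sum(sc$abc_score), 1, tolerance = 1e-9)
})
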