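# Independent oracles and small fixtures shared across tests.

# Two-sided Fisher p by exhaustive enumeration of tables with the observed
# margins: sum the hypergeometric probabilities of every table no more
# probable than the observed one (with the standard relative-error guard
# for floating-point ties).
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  dobs <- stats::dhyper(tab[1, 1], m, n, k)
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

# Exact upper tail of the number of variant-bearing elements in a uniform
# without-replacement draw: P(X >= obs), X ~ Hypergeometric(bearing,
# non-bearing, draw size).
hyper_tail_ge <- function(obs, n_bearing, n_pool, n_draw) {
  sum(stats::dhyper(obs:min(n_bearing, n_draw), n_bearing,
                    n_pool - n_bearing, n_draw))
}

# Brute-force C1-C4 labels: per-record degree count by explicit loops.
substructure_bruteforce <- function(records) {
  ekey <- paste0(records$chrom, ":", records$start, "-", records$end)
  out <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    de <- length(unique(records$target_gene[ekey == ekey[i]]))
    dg <- length(unique(ekey[records$target_gene == records$target_gene[i]]))
    out[i] <- if (de == 1 && dg == 1) "C1" else if (de > 1 && dg == 1) "C2"
      else if (de == 1 && dg > 1) "C3" else "C4"
  }
  out
}

# Small, fast study configuration for unit tests; `...` overrides defaults.
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_enhancers_per_celltype = 300, n_genes = 400,
               chrom_length = 1e7, n_tfs = 15, sites_per_tf = 60,
               n_case_variants = 2000, n_control_variants = 2000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# A tiny hand-made EPI data.frame in the package dialect.
make_epi <- function(chrom, start, gene, cell_type = "ESC",
                     score = 0.05, tpm = 10, tss = NULL) {
  n <- max(length(chrom), length(start), length(gene))
  chrom <- rep_len(chrom, n); start <- rep_len(as.integer(start), n)
  gene <- rep_len(gene, n)
  data.frame(chrom = chrom, start = start, end = start + 500L,
             cell_type = rep_len(cell_type, n), target_gene = gene,
             tss = if (is.null(tss)) start + 10000L else rep_len(as.integer(tss), n),
             gene_strand = "+", abc_score = rep_len(score, n),
             target_tpm = rep_len(tpm, n), stringsAsFactors = FALSE)
}
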