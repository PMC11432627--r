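#' Configuration for the synthetic six-cell-type study generator
#'
#' The generator emulates a six-cell-type neuronal differentiation design:
#' three progenitor cell types and three mature neuron cell types, each
#' with an EPI network of 500-bp enhancers, cross-cell-type enhancer
#' sharing (cell-type-specific, stage-shared, ubiquitous), ABC scores
#' straddling the 0.02 activity threshold, gene expression straddling the
#' 1-TPM filter, FIMO-style TF binding tables with a tunable stage bias,
#' and case/control variant sets with an optional enrichment planted into
#' a chosen C1-C4 sub-structure.
#'
#' @param seed RNG seed; together with the other fields it fully
#'   determines every generated table.
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param chrom_length chromosome length in bp (>= 1e5; all equal).
#' @param stages named stage map (3 progenitor + 3 mature cell types).
#' @param n_enhancers_per_celltype enhancers in each cell type's network.
#' @param frac_celltype_specific_enh fraction of each network's enhancers
#'   private to that cell type.
#' @param frac_stage_shared_enh fraction shared by all three cell types
#'   of the same stage; the remainder is ubiquitous (all six).
#' @param shared_jitter maximum per-cell-type coordinate jitter (bp,
#'   <= 100) applied to shared enhancers; 0 writes identical coordinates.
#' @param n_genes genes placed on the genome (targets and background).
#' @param extra_target_prob probability an enhancer regulates a second
#'   gene (creates enhancer degree > 1).
#' @param frac_low_abc fraction of ABC scores drawn below the 0.02
#'   threshold.
#' @param frac_low_tpm fraction of (gene, cell type) TPM values drawn at
#'   or below 1.
#' @param n_tfs number of transcription factors (>= 3).
#' @param tf_stage_bias bias strength in [0, 1] for stage-preferring TFs
#'   (0 = uniform binding).
#' @param sites_per_tf expected binding sites per TF.
#' @param tfbs_fail_frac fraction of FIMO rows drawn with p >= 1e-5
#'   (removed by the binding filter).
#' @param n_case_variants,n_control_variants variant counts.
#' @param planted_enrichment list(substructure = "none" or "C1".."C4",
#'   multiplier >= 1): case variants fall into elements of that
#'   sub-structure with `multiplier`-fold density.
#' @param n_disease_genes size of the disease gene list.
#' @param disease_overlap_frac fraction of the disease list drawn from
#'   target genes of `disease_celltypes`.
#' @param disease_celltypes cell types whose targets seed the disease
#'   list (default the mature group).
#' @param n_planted_de genes planted as differentially expressed between
#'   the first progenitor and the ESC-derived progenitor comparison pair.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chrom_length = 3e7,
                       stages = default_stages(),
                       n_enhancers_per_celltype = 5000,
                       frac_celltype_specific_enh = 0.35,
                       frac_stage_shared_enh = 0.40,
                       shared_jitter = 0,
                       n_genes = 6000,
                       extra_target_prob = 0.3,
                       frac_low_abc = 0.2,
                       frac_low_tpm = 0.2,
                       n_tfs = 60,
                       tf_stage_bias = 0.6,
                       sites_per_tf = 150,
                       tfbs_fail_frac = 0.2,
                       n_case_variants = 125000,
                       n_control_variants = 125000,
                       planted_enrichment = list(substructure = "none",
                                                 multiplier = 1),
                       n_disease_genes = 120,
                       disease_overlap_frac = 0.5,
                       disease_celltypes = NULL,
                       n_planted_de = 150) {
  .check_stages(stages)
  stopifnot(n_chromosomes >= 1, chrom_length >= 1e5,
            n_enhancers_per_celltype >= 1, n_genes >= 10,
            shared_jitter >= 0, shared_jitter <= 100,
            frac_low_abc >= 0, frac_low_abc <= 1,
            frac_low_tpm >= 0, frac_low_tpm <= 1,
            tf_stage_bias >= 0, tf_stage_bias <= 1,
            n_case_variants >= 0, n_control_variants >= 0,
            extra_target_prob >= 0, extra_target_prob <= 1)
  fr <- c(frac_celltype_specific_enh, frac_stage_shared_enh)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("sharing fractions must lie in [0,1] and sum to at most 1")
  }
  if (n_tfs < 3) stop("n_tfs must be at least 3 (k-means uses k = 3)")
  if (!planted_enrichment$substructure %in% c("none", "C1", "C2", "C3", "C4")) {
    stop("planted_enrichment$substructure must be 'none' or one of C1..C4")
  }
  if (planted_enrichment$multiplier < 1) {
    stop("planted_enrichment$multiplier must be >= 1")
  }
  if (is.null(disease_celltypes)) {
    disease_celltypes <- names(stages)[stages == "mature"]
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Chromosome size table for a synthetic genome
#'
#' @param config a [sim_config()].
#' @return data.frame with `chrom` ("chr1".."chrN") and `length` (bp).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(chrom = paste0("chr", seq_len(config$n_chromosomes)),
             length = rep(as.numeric(config$chrom_length),
                          config$n_chromosomes),
             stringsAsFactors = FALSE)
}

# Non-overlapping placement slots: enhancers and genes sit on a 2-kb grid
# so distinct elements never overlap and sharing classes stay exact.
.genome_slots <- function(genome, width = 500L, spacing = 2000L,
                          margin = 10000L) {
  slots <- lapply(seq_len(nrow(genome)), function(i) {
    pos <- seq(margin, genome$length[i] - margin - width, by = spacing)
    data.frame(chrom = genome$chrom[i], start = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, slots)
}

#' Generate per-cell-type EPI tables with known sharing structure
#'
#' Enhancers (500 bp) are placed on a non-overlapping genomic grid and
#' assigned by construction to sharing classes at exactly the configured
#' fractions: cell-type-specific enhancers appear in one network only,
#' stage-shared enhancers in all three networks of one stage, ubiquitous
#' enhancers in all six. Shared enhancers reuse identical coordinates
#' unless `shared_jitter > 0`, in which case each cell type sees the
#' element shifted by at most that many bp. Every enhancer regulates one
#' or two genes with a TSS within 5 Mb; ABC scores and target TPMs are
#' drawn so configured fractions fall below the 0.02 and 1-TPM filters.
#'
#' @param config a [sim_config()].
#' @param genome from [generate_genome()].
#' @return list with `networks` (named list of EPI data.frames in the
#'   [read_epi_table()] dialect), `genes` (TSS annotation with `name`,
#'   `strand`, `tss`), `tpm` (gene x cell-type TPM matrix), and
#'   `manifest` (ground truth: per-enhancer sharing class and owner,
#'   per-gene targeting).
#' @export
generate_epi_tables <- function(config, genome = generate_genome(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cts <- names(config$stages)
  n_enh <- config$n_enhancers_per_celltype
  n_spec <- round(config$frac_celltype_specific_enh * n_enh)
  n_stage <- round(config$frac_stage_shared_enh * n_enh)
  n_ubi <- n_enh - n_spec - n_stage
  if (n_ubi < 0) stop("sharing fractions exceed 1 after rounding")
  n_distinct <- 6L * n_spec + 2L * n_stage + n_ubi

  slots <- .genome_slots(genome)
  need <- n_distinct + config$n_genes
  if (nrow(slots) < need) {
    stop("genome too small: ", need, " placement slots needed, ",
         nrow(slots), " available; increase chrom_length or n_chromosomes")
  }
  pick <- sample.int(nrow(slots), need)
  gene_slots <- slots[pick[seq_len(config$n_genes)], , drop = FALSE]
  enh_slots <- slots[pick[config$n_genes + seq_len(n_distinct)], , drop = FALSE]

  # gene annotation: body [pos, pos+1500); TSS at start (+) or end (-)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(
    chrom = gene_slots$chrom,
    start = gene_slots$start,
    end = gene_slots$start + 1500L,
    name = sprintf("G%05d", seq_len(config$n_genes)),
    strand = strand,
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(strand == "+", genes$start, genes$end)

  # enhancer catalogue with exact class assignment
  classes <- c(rep(cts, each = n_spec),
               rep(c("progenitor", "mature"), each = n_stage),
               rep("all", n_ubi))
  class_kind <- c(rep("specific", 6L * n_spec),
                  rep("stage_shared", 2L * n_stage),
                  rep("ubiquitous", n_ubi))
  enh <- data.frame(
    enh_id = sprintf("E%06d", seq_len(n_distinct)),
    chrom = enh_slots$chrom,
    start = enh_slots$start,
    end = enh_slots$start + 500L,
    class = class_kind,
    owner = classes,
    stringsAsFactors = FALSE
  )

  # target genes: uniform within the 5-Mb window around the enhancer mid
  enh$mid <- (enh$start + enh$end) / 2
  target1 <- character(n_distinct)
  target2 <- rep(NA_character_, n_distinct)
  extra <- stats::runif(n_distinct) < config$extra_target_prob
  for (ch in unique(enh$chrom)) {
    gsel <- which(genes$chrom == ch)
    tss_ord <- gsel[order(genes$tss[gsel])]
    tss_sorted <- genes$tss[tss_ord]
    esel <- which(enh$chrom == ch)
    lo <- findInterval(enh$mid[esel] - 5e6, tss_sorted) + 1L
    hi <- findInterval(enh$mid[esel] + 5e6, tss_sorted)
    if (any(hi < lo)) stop("no gene within 5 Mb of some enhancer; increase n_genes")
    pick1 <- lo + floor(stats::runif(length(esel)) * (hi - lo + 1L))
    target1[esel] <- genes$name[tss_ord[pick1]]
    can2 <- extra[esel] & (hi - lo + 1L) >= 2L
    if (any(can2)) {
      i2 <- which(can2)
      p2 <- lo[i2] + floor(stats::runif(length(i2)) * (hi[i2] - lo[i2] + 1L))
      bump <- p2 == pick1[i2]
      p2[bump] <- ifelse(p2[bump] < hi[i2][bump], p2[bump] + 1L, p2[bump] - 1L)
      target2[esel[i2]] <- genes$name[tss_ord[p2]]
    }
  }
  enh$target1 <- target1
  enh$target2 <- target2

  # TPM matrix: configured fraction at or below the 1-TPM filter
  tpm <- matrix(0, config$n_genes, 6, dimnames = list(genes$name, cts))
  low <- matrix(stats::runif(config$n_genes * 6) < config$frac_low_tpm,
                config$n_genes, 6)
  tpm[low] <- round(stats::runif(sum(low), 0, 1), 3)
  tpm[!low] <- round(exp(stats::runif(sum(!low), log(1.5), log(300))), 3)

  # per-cell-type membership
  members <- lapply(cts, function(ct) {
    which(enh$owner == ct | enh$owner == unname(config$stages[ct]) |
            enh$owner == "all")
  })
  names(members) <- cts

  gene_row <- stats::setNames(seq_len(config$n_genes), genes$name)
  networks <- lapply(cts, function(ct) {
    idx <- members[[ct]]
    e <- enh[idx, , drop = FALSE]
    if (config$shared_jitter > 0) {
      shared <- e$class != "specific"
      off <- integer(nrow(e))
      off[shared] <- sample(seq(-config$shared_jitter, config$shared_jitter),
                            sum(shared), replace = TRUE)
      e$start <- e$start + off
      e$end <- e$end + off
    }
    two <- !is.na(e$target2)
    rec <- data.frame(
      chrom = c(e$chrom, e$chrom[two]),
      start = c(e$start, e$start[two]),
      end = c(e$end, e$end[two]),
      cell_type = ct,
      target_gene = c(e$target1, e$target2[two]),
      stringsAsFactors = FALSE
    )
    gi <- gene_row[rec$target_gene]
    rec$tss <- genes$tss[gi]
    rec$gene_strand <- genes$strand[gi]
    n <- nrow(rec)
    low_abc <- stats::runif(n) < config$frac_low_abc
    score <- numeric(n)
    score[low_abc] <- stats::runif(sum(low_abc), 0.001, 0.0199)
    score[!low_abc] <- pmin(0.02 * exp(stats::rexp(sum(!low_abc))), 1)
    rec$abc_score <- round(score, 6)
    rec$target_tpm <- tpm[cbind(gi, match(ct, cts))]
    rec
  })
  names(networks) <- cts

  manifest <- list(
    enhancers = enh[, c("enh_id", "chrom", "start", "end", "class",
                        "owner", "target1", "target2")],
    n_specific = n_spec, n_stage_shared = n_stage, n_ubiquitous = n_ubi,
    frac_specific = n_spec / n_enh,
    genes = genes
  )
  list(networks = networks, genes = genes, tpm = tpm, manifest = manifest)
}

#' Generate a FIMO-style TFBS table with planted stage bias
#'
#' TFs are split evenly into three archetypes (progenitor-preferring,
#' mature-preferring, uniform). A biased TF allocates its binding sites
#' across cell types with weight `1 + 2b` in its preferred stage and
#' `1 - b` elsewhere (`b = tf_stage_bias`); within a cell type it binds
#' distinct enhancers of that cell type's network. Each bound enhancer
#' yields one or two motif rows for the TF (exercising motif-to-TF
#' collapsing), and a configured fraction of rows is drawn with
#' p >= 1e-5 so the binding filter removes them.
#'
#' @param config a [sim_config()].
#' @param epi result of [generate_epi_tables()].
#' @return list with `fimo` (data.frame in FIMO TSV column layout) and
#'   `tf_truth` (data.frame tf/archetype).
#' @export
generate_tfbs_table <- function(config, epi) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tfs < 3) stop("n_tfs must be at least 3")
  set.seed(config$seed + 101L)
  cts <- names(config$stages)
  archetypes <- rep(c("progenitor", "mature", "uniform"),
                    length.out = config$n_tfs)
  tfs <- sprintf("TF%03d", seq_len(config$n_tfs))
  b <- config$tf_stage_bias

  enh_by_ct <- lapply(epi$networks, .network_enhancers)
  rows <- vector("list", config$n_tfs * 6L)
  ri <- 0L
  for (t in seq_len(config$n_tfs)) {
    w <- rep(1, 6)
    if (archetypes[t] != "uniform") {
      w <- ifelse(config$stages == archetypes[t], 1 + 2 * b, 1 - b)
    }
    alloc <- as.integer(stats::rmultinom(1, config$sites_per_tf, w))
    for (ci in seq_along(cts)) {
      n_ct <- nrow(enh_by_ct[[ci]])
      k <- min(alloc[ci], n_ct)
      if (k == 0) next
      e <- enh_by_ct[[ci]][sample.int(n_ct, k), , drop = FALSE]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(tf = tfs[t], chrom = e$chrom,
                               start = e$start, end = e$end,
                               stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, rows[seq_len(ri)])

  # one or two motif rows per bound enhancer; fraction fails the filter
  dup <- stats::runif(nrow(sites)) < 0.3
  sites2 <- rbind(cbind(sites, motif = "M1"),
                  cbind(sites[dup, , drop = FALSE], motif = "M2"))
  n <- nrow(sites2)
  fail <- stats::runif(n) < config$tfbs_fail_frac
  p <- numeric(n)
  p[fail] <- 10^-stats::runif(sum(fail), 3, 4.9)
  p[!fail] <- 10^-stats::runif(sum(!fail), 5.2, 9)
  rel <- sample.int(480L, n, replace = TRUE)
  fimo <- data.frame(
    motif_id = paste0(sites2$tf, "_", sites2$motif),
    motif_alt_id = sites2$tf,
    sequence_name = paste0(sites2$chrom, ":", sites2$start, "-", sites2$end),
    start = rel,
    stop = rel + 10L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    score = round(stats::runif(n, 5, 20), 3),
    p = signif(p, 4),
    q = NA_real_,
    matched_sequence = "N",
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  names(fimo)[names(fimo) == "p"] <- "p-value"
  names(fimo)[names(fimo) == "q"] <- "q-value"
  list(fimo = fimo,
       tf_truth = data.frame(tf = tfs, archetype = archetypes,
                             stringsAsFactors = FALSE))
}

#' Write a FIMO-layout table to a TSV file
#' @param fimo data.frame from [generate_tfbs_table()].
#' @param path output path.
#' @export
write_fimo_tsv <- function(fimo, path) {
  utils::write.table(fimo, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.uniform_variants <- function(n, genome) {
  if (n == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  idx <- sample.int(nrow(genome), n, replace = TRUE,
                    prob = genome$length)
  pos <- floor(stats::runif(n) * genome$length[idx])
  data.frame(chrom = genome$chrom[idx], start = as.integer(pos),
             end = as.integer(pos) + 1L, stringsAsFactors = FALSE)
}

#' Generate case and control variant sets with an optional planted signal
#'
#' Variants are single-base intervals. Control variants are uniform over
#' the genome. Case variants are uniform unless
#' `config$planted_enrichment` names a sub-structure, in which case the
#' sampling density inside elements of that category is multiplied by
#' the configured factor: a case variant lands inside the (merged)
#' target elements with probability `m*T / (m*T + G - T)` where `T` is
#' the target footprint and `G` the genome size.
#'
#' @param config a [sim_config()].
#' @param genome from [generate_genome()].
#' @param elements labelled elements from [substructure_elements()];
#'   required when an enrichment is planted.
#' @return list with `case`, `control` (variant data.frames) and
#'   `case_planted` (logical: drawn from the boosted component).
#' @export
generate_variant_sets <- function(config, genome, elements = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  planted <- config$planted_enrichment
  G <- sum(genome$length)
  control <- .uniform_variants(config$n_control_variants, genome)
  if (planted$substructure == "none" || planted$multiplier == 1) {
    case <- .uniform_variants(config$n_case_variants, genome)
    return(list(case = case, control = control,
                case_planted = rep(FALSE, nrow(case))))
  }
  if (is.null(elements)) {
    stop("labelled elements required to plant an enrichment")
  }
  tgt <- elements[elements$label == planted$substructure, , drop = FALSE]
  if (nrow(tgt) == 0) {
    stop("no elements labelled ", planted$substructure,
         " present in the networks")
  }
  tgt_gr <- GenomicRanges::reduce(as_granges(tgt[, c("chrom", "start", "end")]))
  tgt_bed <- as_bed_df(tgt_gr)
  T_bp <- sum(tgt_bed$end - tgt_bed$start)
  m <- planted$multiplier
  p_in <- m * T_bp / (m * T_bp + (G - T_bp))
  n <- config$n_case_variants
  inside <- stats::runif(n) < p_in
  case <- .uniform_variants(n, genome)
  n_in <- sum(inside)
  if (n_in > 0) {
    w <- tgt_bed$end - tgt_bed$start
    ei <- sample.int(nrow(tgt_bed), n_in, replace = TRUE, prob = w)
    off <- floor(stats::runif(n_in) * w[ei])
    case$start[inside] <- as.integer(tgt_bed$start[ei] + off)
    case$end[inside] <- case$start[inside] + 1L
    case$chrom[inside] <- tgt_bed$chrom[ei]
  }
  # the non-planted component must avoid the target footprint
  out_idx <- which(!inside)
  for (iter in 1:50) {
    if (length(out_idx) == 0) break
    hit <- overlap_elements(case[out_idx, , drop = FALSE], tgt_bed)
    if (!any(hit)) break
    redraw <- out_idx[hit]
    repl <- .uniform_variants(length(redraw), genome)
    case[redraw, c("chrom", "start", "end")] <- repl
    out_idx <- redraw
  }
  list(case = case, control = control, case_planted = inside)
}

#' Generate expression tables, a DE comparison and a disease gene list
#'
#' Emits the two-column TPM table of every cell type, a differential
#' expression table for the first vs third progenitor cell type with a
#' planted set of genes (half up in each direction, drawn preferentially
#' from genes targeted exclusively by the corresponding network), and a
#' disease gene list overlapping the configured cell types' target genes
#' at the configured fraction.
#'
#' @param config a [sim_config()].
#' @param epi result of [generate_epi_tables()].
#' @param tf_truth optional `tf_truth` from [generate_tfbs_table()]; when
#'   given, each TF gene is appended to the TPM tables with expression
#'   peaking in a cell type of its preferred stage (uniform archetypes
#'   peak anywhere).
#' @return list with `tpm_tables` (named list of named numeric vectors),
#'   `de` (data.frame gene/lfc/fdr), `disease_genes` (character), and
#'   `truth` (planted DE gene sets and disease-list provenance).
#' @export
generate_expression_and_genesets <- function(config, epi, tf_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  cts <- names(config$stages)
  tpm_tables <- lapply(cts, function(ct) epi$tpm[, ct])
  names(tpm_tables) <- cts
  if (!is.null(tf_truth)) {
    for (i in seq_len(nrow(tf_truth))) {
      pool <- if (tf_truth$archetype[i] == "uniform") cts
              else cts[config$stages == tf_truth$archetype[i]]
      peak <- sample(pool, 1)
      expr <- round(stats::runif(6, 1, 10), 3)
      expr[match(peak, cts)] <- round(stats::runif(1, 50, 200), 3)
      for (ci in seq_along(cts)) {
        tpm_tables[[ci]][tf_truth$tf[i]] <- expr[ci]
      }
    }
  }

  # DE contrast: first progenitor (ESC-like) vs third progenitor (NPC-like)
  prog <- cts[config$stages == "progenitor"]
  ct_a <- prog[1]; ct_b <- prog[3]
  targets_a <- unique(epi$networks[[ct_a]]$target_gene)
  targets_b <- unique(epi$networks[[ct_b]]$target_gene)
  only_a <- setdiff(targets_a, targets_b)
  only_b <- setdiff(targets_b, targets_a)
  n_half <- floor(config$n_planted_de / 2)
  pick <- function(pool, backup, k) {
    k1 <- min(k, length(pool))
    c(sample(pool, k1), sample(setdiff(backup, pool), k - k1))
  }
  up_b <- pick(only_b, targets_b, n_half)   # higher in ct_b: LFC > 1
  up_a <- pick(only_a, targets_a, n_half)   # higher in ct_a: LFC < -1
  genes <- epi$genes$name
  lfc <- stats::rnorm(length(genes), 0, 0.4)
  fdr <- stats::runif(length(genes))
  ia <- match(up_a, genes); ib <- match(up_b, genes)
  lfc[ib] <- stats::runif(length(ib), 1.5, 3)
  lfc[ia] <- -stats::runif(length(ia), 1.5, 3)
  fdr[c(ia, ib)] <- stats::runif(length(ia) + length(ib), 0, 0.04)
  de <- data.frame(gene = genes, lfc = round(lfc, 4), fdr = round(fdr, 5),
                   stringsAsFactors = FALSE)

  # disease gene list with a planted overlap fraction
  tgt <- unique(unlist(lapply(config$disease_celltypes,
                              function(ct) epi$networks[[ct]]$target_gene)))
  non_tgt <- setdiff(genes, tgt)
  k_in <- round(config$disease_overlap_frac * config$n_disease_genes)
  k_in <- min(k_in, length(tgt))
  k_out <- min(config$n_disease_genes - k_in, length(non_tgt))
  disease <- c(sample(tgt, k_in), sample(non_tgt, k_out))

  list(tpm_tables = tpm_tables, de = de, disease_genes = disease,
       truth = list(up_in = up_b, down_in = up_a,
                    comparison = c(ct_a, ct_b),
                    disease_from_targets = disease[seq_len(k_in)]))
}

#' Generate activity peak tables for end-to-end ABC scoring
#'
#' For pipelines that start from peaks rather than pre-scored EPI tables:
#' each cell type's enhancers are emitted with ATAC and H3K27ac read
#' counts (log-normal), suitable input for [compute_abc_scores()].
#'
#' @param config a [sim_config()].
#' @param epi result of [generate_epi_tables()].
#' @return named list of data.frames (`chrom`, `start`, `end`,
#'   `atac_count`, `h3k27ac_count`).
#' @export
generate_activity_peaks <- function(config, epi) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  lapply(epi$networks, function(net) {
    e <- .network_enhancers(net)
    n <- nrow(e)
    e$atac_count <- round(stats::rlnorm(n, meanlog = 4, sdlog = 0.8), 1)
    e$h3k27ac_count <- round(stats::rlnorm(n, meanlog = 4.5, sdlog = 0.9), 1)
    e
  })
}
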