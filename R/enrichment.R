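#' Multiple-testing-corrected significance threshold
#'
#' The per-test threshold for a family of per-cell-type tests is
#' `alpha / n_tests`, reported rounded to six decimals (0.05 over six
#' cell types gives 0.008333).
#'
#' @param n_tests number of tests in the family (default 6 cell types).
#' @param alpha family-wise nominal level (default 0.05).
#' @return corrected threshold, rounded to 6 decimals.
#' @export
corrected_threshold <- function(n_tests = 6, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  round(alpha / n_tests, 6)
}

#' Strand-aware promoter regions from a TSS annotation
#'
#' Promoters span the 2000 bp upstream of the transcription start: for a
#' gene on the + strand, `[start - 2000, start)`; on the - strand,
#' `[end, end + 2000)`. Regions are clipped to the chromosome bounds
#' (with a warning) so a TSS within 2000 bp of a chromosome start still
#' yields a valid, shorter promoter.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `strand` and a
#'   `name` (gene symbol) column.
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   right-side clipping.
#' @param upstream promoter length in bp (default 2000).
#' @return data.frame `chrom`, `start`, `end`, `name` (0-based half-open).
#' @export
derive_promoter_regions <- function(genes, chrom_sizes = NULL,
                                    upstream = 2000L) {
  stopifnot(all(c("chrom", "start", "end", "strand", "name") %in% names(genes)))
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand value(s); promoters need '+' or '-'")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start - upstream, genes$end)
  end <- ifelse(plus, genes$start, genes$end + upstream)
  clipped <- start < 0
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[genes$chrom])
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  start <- pmax(start, 0L)
  if (any(clipped)) {
    warning(sum(clipped), " promoter region(s) clipped at chromosome bounds")
  }
  keep <- start < end
  out <- data.frame(chrom = genes$chrom[keep], start = as.integer(start[keep]),
                    end = as.integer(end[keep]), name = genes$name[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Number of elements containing at least one variant
#'
#' Each element counts at most once no matter how many variants fall in
#' it; overlap is the >= 1 bp rule.
#'
#' @param elements interval data.frame.
#' @param variants interval data.frame (width-1 rows for SNVs).
#' @return integer count.
#' @export
count_elements_with_variant <- function(elements, variants) {
  if (nrow(elements) == 0) return(0L)
  sum(overlap_elements(elements, variants))
}

#' Empirical resampling test for variant or gene-list enrichment
#'
#' Tests whether one cell type's elements overlap disease variants (or a
#' disease gene list) more than size-matched random draws from the pooled
#' collapsed-network elements. The observed statistic is the number of
#' target elements containing at least one variant (interval kinds) or
#' the exact-match intersection with the gene list (gene kind). For each
#' of `R` repetitions the same number of elements is drawn uniformly
#' without replacement from the deduplicated pool and the statistic
#' recomputed. The upper-tail p-value is
#' `(1 + #\{draws >= observed\}) / (R + 1)`; the legacy estimator
#' `#\{draws >= observed\} / R` is available via `legacy_p = TRUE`.
#'
#' @param target the cell type's elements: interval data.frame, or
#'   character vector of gene symbols for `kind = "gene"`.
#' @param pool the pooled elements to resample from (same form as
#'   `target`); deduplicated internally (by exact interval, or symbol).
#' @param variants interval data.frame of variants, or the disease gene
#'   list (character) for `kind = "gene"`.
#' @param kind "enhancer", "promoter" (both interval-based) or "gene".
#' @param R number of random draws (default 1000).
#' @param seed RNG seed.
#' @param n_tests family size for the corrected threshold (default 6).
#' @param legacy_p use the uncorrected `#\{>=\}/R` estimator.
#' @return object of class `enrichment_result`: list with `kind`,
#'   `observed`, `null_counts`, `p_empirical`, `significant`, `nominal`,
#'   `n_target`, `n_pool`.
#' @export
empirical_enrichment_test <- function(target, pool, variants,
                                      kind = c("enhancer", "promoter", "gene"),
                                      R = 1000, seed = 1, n_tests = 6,
                                      legacy_p = FALSE) {
  kind <- match.arg(kind)
  if (kind == "gene") {
    target_u <- unique(target)
    pool_u <- unique(pool)
    geneset <- unique(variants)
    bearing <- pool_u %in% geneset
    observed <- sum(target_u %in% geneset)
  } else {
    target_u <- unique(target[, c("chrom", "start", "end")])
    pool_u <- unique(pool[, c("chrom", "start", "end")])
    bearing <- overlap_elements(pool_u, variants)
    observed <- count_elements_with_variant(target_u, variants)
  }
  n_target <- if (is.data.frame(target_u)) nrow(target_u) else length(target_u)
  n_pool <- length(bearing)
  if (n_target == 0) stop("empty target element set")
  if (n_target > n_pool) {
    stop("target has more elements (", n_target,
         ") than the deduplicated pool (", n_pool, ")")
  }
  set.seed(seed)
  null_counts <- vapply(seq_len(R), function(r) {
    sum(bearing[sample.int(n_pool, n_target)])
  }, integer(1))
  ge <- sum(null_counts >= observed)
  p <- if (legacy_p) ge / R else (1 + ge) / (R + 1)
  thr <- corrected_threshold(n_tests)
  structure(list(kind = kind, observed = observed,
                 null_counts = null_counts, p_empirical = p,
                 significant = p <= thr, nominal = p <= 0.05,
                 threshold = thr, n_target = n_target, n_pool = n_pool,
                 R = R, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Empirical enrichment test (%s elements)\n", x$kind))
  cat(sprintf("  target: %d of %d pooled elements; observed overlap: %d\n",
              x$n_target, x$n_pool, x$observed))
  cat(sprintf("  null draws: R = %d, mean = %.2f\n", x$R, mean(x$null_counts)))
  cat(sprintf("  empirical p = %.4g (%s)\n", x$p_empirical,
              if (x$significant) sprintf("significant at %.6f", x$threshold)
              else if (x$nominal) "nominal at 0.05" else "not significant"))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the conditional maximum-likelihood
#' odds ratio (the sample cross-product ratio is available as an
#' option). The two-sided p-value sums the probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param or_method "cml" (conditional MLE, default) or "cross_product".
#' @return list with `table`, `odds_ratio`, `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(table, or_method = c("cml", "cross_product")) {
  or_method <- match.arg(or_method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers")
  }
  if (sum(table) == 0) stop("all-zero table")
  ft <- stats::fisher.test(table)
  or <- if (or_method == "cml") unname(ft$estimate)
        else (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(table = table, odds_ratio = or, p_two_sided = ft$p.value)
}

#' Enhancer elements of EPIs in each sub-structure, per cell type
#'
#' Classifies every cell-type network with [classify_substructure()] and
#' returns the distinct (enhancer, label) element rows used for
#' variant-attribution tests. The same enhancer interval can legitimately
#' carry different labels in different cell types.
#'
#' @param networks named list of per-cell-type EPI data.frames.
#' @return data.frame `chrom`, `start`, `end`, `cell_type`, `label`.
#' @export
substructure_elements <- function(networks) {
  out <- lapply(names(networks), function(ct) {
    rec <- networks[[ct]]
    if (nrow(rec) == 0) return(NULL)
    lab <- classify_substructure(rec)
    el <- data.frame(chrom = rec$chrom, start = rec$start, end = rec$end,
                     cell_type = ct, label = lab, stringsAsFactors = FALSE)
    unique(el)
  })
  do.call(rbind, out)
}

#' Fisher contrast of case vs control variants in one sub-structure
#'
#' Builds the 2x2 table with rows (case, control) and columns (variant
#' falls in an element of `category`, variant falls in an element of any
#' other category). Variants overlapping no labelled element are
#' excluded; a variant overlapping elements of several categories counts
#' once towards each column it belongs to.
#'
#' @param elements labelled element table from [substructure_elements()]
#'   (or any data.frame with `chrom`, `start`, `end`, `label`).
#' @param case,control variant interval data.frames.
#' @param category the sub-structure tested ("C1".."C4").
#' @return result of [fisher_exact_2x2()] on the constructed table.
#' @export
substructure_variant_fisher <- function(elements, case, control, category) {
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(elements)))
  if (!category %in% elements$label) {
    stop("no elements labelled ", category, " in the networks")
  }
  in_cat <- elements[elements$label == category, , drop = FALSE]
  other <- elements[elements$label != category, , drop = FALSE]
  cells <- function(v) {
    c(sum(overlap_elements(v, in_cat)), sum(overlap_elements(v, other)))
  }
  tab <- rbind(case = cells(case), control = cells(control))
  colnames(tab) <- c(category, "other")
  if (sum(tab) == 0) stop("no variant overlaps any labelled element")
  fisher_exact_2x2(tab)
}

#' 2x2 contingency of differential expression vs network membership
#'
#' Differentially expressed genes (FDR < 0.05, strict) are split by a
#' log-fold-change direction threshold (up: LFC > 1; down: LFC < -1,
#' both strict) and by EPI-network membership: either target genes of
#' network A vs network B (`comparison = "between"`), or in network A vs
#' not (`comparison = "within"`).
#'
#' @param de data.frame with `gene`, `lfc`, `fdr`.
#' @param genes_a,genes_b character vectors of network target genes
#'   (`genes_b` ignored for `comparison = "within"`).
#' @param direction "up" (LFC > 1) or "down" (LFC < -1).
#' @param comparison "between" or "within".
#' @param fdr_max strict FDR cut (default 0.05).
#' @param lfc_cut absolute LFC threshold (default 1).
#' @return 2x2 integer matrix, rows = membership, columns = passes the
#'   direction threshold or not.
#' @export
build_lfc_contingency <- function(de, genes_a, genes_b = NULL,
                                  direction = c("up", "down"),
                                  comparison = c("between", "within"),
                                  fdr_max = 0.05, lfc_cut = 1) {
  direction <- match.arg(direction)
  comparison <- match.arg(comparison)
  stopifnot(all(c("gene", "lfc", "fdr") %in% names(de)))
  de <- de[!is.na(de$fdr) & de$fdr < fdr_max, , drop = FALSE]
  if (nrow(de) == 0) stop("no gene passes the FDR filter")
  hit <- if (direction == "up") de$lfc > lfc_cut else de$lfc < -lfc_cut
  if (comparison == "between") {
    stopifnot(!is.null(genes_b))
    in_a <- de$gene %in% genes_a
    in_b <- de$gene %in% genes_b
    tab <- rbind(network_a = c(sum(hit & in_a), sum(!hit & in_a)),
                 network_b = c(sum(hit & in_b), sum(!hit & in_b)))
  } else {
    in_a <- de$gene %in% genes_a
    tab <- rbind(in_network = c(sum(hit & in_a), sum(!hit & in_a)),
                 out_network = c(sum(hit & !in_a), sum(!hit & !in_a)))
  }
  colnames(tab) <- c("passes_lfc", "fails_lfc")
  storage.mode(tab) <- "integer"
  tab
}
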