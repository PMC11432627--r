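#' Default six-cell-type differentiation design
#'
#' Three progenitor cell types (ESC, NSC, NPC) and three mature neuron
#' cell types (AD inhibitory, Ngn2 excitatory, Motor), in fixed order.
#' Used as the default stage map throughout.
#'
#' @return named character vector: names are cell types, values are
#'   `"progenitor"` or `"mature"`.
#' @export
default_stages <- function() {
  c(ESC = "progenitor", NSC = "progenitor", NPC = "progenitor",
    AD = "mature", Ngn2 = "mature", Motor = "mature")
}

.check_stages <- function(stages) {
  if (length(stages) != 6 || is.null(names(stages)) ||
      sum(stages == "progenitor") != 3 || sum(stages == "mature") != 3) {
    stop("stage map must name 6 cell types, 3 progenitor and 3 mature")
  }
  invisible(stages)
}

#' Concatenate per-cell-type EPI networks into the collapsed network
#'
#' The collapsed network keeps every record of every cell type (the same
#' enhancer-gene pair active in three cell types contributes three rows).
#' Alongside it, the enhancer regions of all cell types are merged wherever
#' they overlap by at least 1 bp, giving the non-redundant enhancer list
#' used for pooled resampling.
#'
#' @param networks named list of per-cell-type EPI data.frames (dialect of
#'   [read_epi_table()]); names are used as cell-type labels when a table's
#'   `cell_type` column is absent.
#' @return list with `records` (concatenated EPI data.frame) and
#'   `merged_enhancers` (data.frame of union intervals).
#' @export
build_collapsed_network <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 1)
  nm <- names(networks)
  tabs <- lapply(seq_along(networks), function(i) {
    x <- networks[[i]]
    if (!"cell_type" %in% names(x) && !is.null(nm)) x$cell_type <- nm[i]
    x
  })
  records <- do.call(rbind, tabs)
  rownames(records) <- NULL
  enh <- unique(records[, c("chrom", "start", "end")])
  merged <- if (nrow(enh)) as_bed_df(GenomicRanges::reduce(as_granges(enh)))
            else enh
  list(records = records, merged_enhancers = merged)
}

#' Assign a subset-network category from a six-cell-type score vector
#'
#' Categories partition merged EPIs by which cell types show a non-zero
#' ABC score. Decision order: (1) non-zero in at least 5 of 6 cell types
#' is ubiquitous ("Ubi"); (2) non-zero in exactly one cell type is that
#' cell type's specific category; (3) non-zero in >= 2 cell types, all
#' progenitor, is "Progenitor"; (4) all mature, "Mature"; (5) anything
#' else (2-4 cell types mixing the stages) is "Removed". Ubi is checked
#' first because 5 of 6 cell types necessarily mixes stages.
#'
#' @param scores numeric vector of 6 per-cell-type scores (>= 0), aligned
#'   with `names(stages)`.
#' @param stages stage map as from [default_stages()].
#' @return a single category label.
#' @export
assign_subset_category <- function(scores, stages = default_stages()) {
  .check_stages(stages)
  if (length(scores) != 6) stop("score vector must have length 6")
  nz <- which(scores > 0)
  if (length(nz) == 0) stop("all six scores are zero")
  if (length(nz) >= 5) return("Ubi")
  if (length(nz) == 1) return(names(stages)[nz])
  st <- stages[nz]
  if (all(st == "progenitor")) return("Progenitor")
  if (all(st == "mature")) return("Mature")
  "Removed"
}

#' Build the subset network: 100-bp merge plus stage categorisation
#'
#' Enhancer regions of the concatenated per-cell-type EPIs are merged
#' wherever they lie within `gap` bp of each other; each merged EPI then
#' collects one ABC score per cell type (aggregated over its members by
#' `agg`, default the maximum, preserving "non-zero in cell type X"), and
#' is categorised with [assign_subset_category()].
#'
#' @param networks named list of six per-cell-type (post-filter) EPI
#'   data.frames.
#' @param stages stage map; default [default_stages()].
#' @param gap merge distance in bp (default 100).
#' @param agg per-cell-type score aggregation: "max" or "mean" of member
#'   scores.
#' @return data.frame of merged EPIs: `chrom`, `start`, `end`, one score
#'   column per cell type, and `category`.
#' @export
build_subset_network <- function(networks, stages = default_stages(),
                                 gap = 100L, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  .check_stages(stages)
  cts <- names(stages)
  if (!setequal(names(networks), cts)) {
    stop("networks must be named by the six cell types in the stage map")
  }
  collapsed <- build_collapsed_network(networks[cts])
  rec <- collapsed$records
  mg <- merge_within_gap(rec[, c("chrom", "start", "end")], gap = gap)
  n_cl <- nrow(mg$clusters)
  scores <- matrix(0, nrow = n_cl, ncol = 6, dimnames = list(NULL, cts))
  fun <- if (agg == "max") max else mean
  for (ct in cts) {
    sel <- rec$cell_type == ct
    if (!any(sel)) next
    agg_scores <- tapply(rec$abc_score[sel], mg$membership[sel], fun)
    scores[as.integer(names(agg_scores)), ct] <- as.numeric(agg_scores)
  }
  out <- cbind(mg$clusters, as.data.frame(scores))
  out$category <- vapply(seq_len(n_cl), function(i) {
    assign_subset_category(scores[i, ], stages)
  }, "")
  out
}

#' Classify each EPI of one network into sub-structures C1-C4
#'
#' Within a single cell-type network, the enhancer degree of an EPI is the
#' number of distinct target genes its enhancer regulates, and the
#' promoter degree is the number of distinct enhancers regulating its
#' target gene (promoter identity is the gene symbol). The four
#' sub-structures are the 2x2 of (one vs many) on each side:
#' C1 single enhancer - single promoter; C2 single enhancer driving
#' multiple promoters (enhancer degree > 1); C3 multiple enhancers on a
#' single promoter (promoter degree > 1); C4 many-to-many.
#'
#' @param records EPI data.frame for one cell type.
#' @return character vector of labels ("C1".."C4"), one per record.
#' @export
classify_substructure <- function(records) {
  if (nrow(records) == 0) return(character(0))
  ekey <- interval_key(records)
  gkey <- records$target_gene
  pair <- paste(ekey, gkey, sep = "|")
  first <- !duplicated(pair)
  deg_e <- table(ekey[first])   # distinct genes per enhancer
  deg_g <- table(gkey[first])   # distinct enhancers per gene
  many_e <- as.integer(deg_e[ekey]) > 1L
  many_g <- as.integer(deg_g[gkey]) > 1L
  ifelse(many_e,
         ifelse(many_g, "C4", "C2"),
         ifelse(many_g, "C3", "C1"))
}

#' Sub-structure composition of a network
#'
#' @param labels character vector of C1-C4 labels (from
#'   [classify_substructure()]).
#' @return named numeric vector of the four fractions, summing to 1.
#' @export
substructure_distribution <- function(labels) {
  if (length(labels) == 0) stop("empty network: no sub-structure labels")
  tab <- table(factor(labels, levels = c("C1", "C2", "C3", "C4")))
  stats::setNames(as.numeric(tab) / length(labels), names(tab))
}

#' Enhancer and promoter degrees of one network
#'
#' @param records EPI data.frame for one cell type.
#' @return list with `enhancer_degree` (named by interval key: distinct
#'   target genes) and `promoter_degree` (named by gene symbol: distinct
#'   enhancers).
#' @export
network_degrees <- function(records) {
  ekey <- interval_key(records)
  pair <- paste(ekey, records$target_gene, sep = "|")
  first <- !duplicated(pair)
  list(
    enhancer_degree = c(table(ekey[first])),
    promoter_degree = c(table(records$target_gene[first]))
  )
}
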