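.network_enhancers <- function(records) {
  unique(records[, c("chrom", "start", "end")])
}

#' Fraction of elements unique to each cell type
#'
#' An enhancer is unique to a cell type when it shares no base pair
#' (>= 1 bp rule) with any enhancer of the other five networks; the check
#' runs on the original per-cell-type intervals, before any merging. A
#' promoter is unique when its gene symbol appears in no other network
#' (exact full-symbol matching).
#'
#' @param networks named list of per-cell-type EPI data.frames.
#' @param kind "enhancer" or "promoter".
#' @return named numeric vector: per-cell-type unique fraction.
#' @export
unique_element_fraction <- function(networks, kind = c("enhancer", "promoter")) {
  kind <- match.arg(kind)
  cts <- names(networks)
  stopifnot(!is.null(cts))
  vapply(cts, function(ct) {
    others <- networks[setdiff(cts, ct)]
    if (kind == "enhancer") {
      own <- .network_enhancers(networks[[ct]])
      if (nrow(own) == 0) return(NA_real_)
      other_enh <- do.call(rbind, lapply(others, .network_enhancers))
      mean(!overlap_elements(own, other_enh))
    } else {
      own <- unique(networks[[ct]]$target_gene)
      if (length(own) == 0) return(NA_real_)
      other_genes <- unique(unlist(lapply(others, function(x) x$target_gene)))
      mean(!own %in% other_genes)
    }
  }, numeric(1))
}

#' Jaccard index between two interval sets (element level)
#'
#' The two sets are merged into union intervals; with `a` and `b` the
#' numbers of union intervals containing at least one element of each set
#' and `i` the number containing both, J = i / (a + b - i). The base-pair
#' alternative is shared bp / union bp.
#'
#' @param x,y interval data.frames (chrom/start/end).
#' @param level "element" (default) or "bp".
#' @return Jaccard index in [0, 1]; NA when both sets are empty.
#' @export
jaccard_intervals <- function(x, y, level = c("element", "bp")) {
  level <- match.arg(level)
  if (nrow(x) == 0 && nrow(y) == 0) return(NA_real_)
  if (nrow(x) == 0 || nrow(y) == 0) return(0)
  grx <- as_granges(unique(x[, c("chrom", "start", "end")]))
  gry <- as_granges(unique(y[, c("chrom", "start", "end")]))
  if (level == "bp") {
    shared <- sum(IRanges::width(suppressWarnings(GenomicRanges::intersect(grx, gry))))
    total <- sum(IRanges::width(suppressWarnings(GenomicRanges::union(grx, gry))))
    return(shared / total)
  }
  u <- GenomicRanges::reduce(suppressWarnings(c(grx, gry)))
  in_x <- suppressWarnings(GenomicRanges::countOverlaps(u, grx)) > 0
  in_y <- suppressWarnings(GenomicRanges::countOverlaps(u, gry)) > 0
  i <- sum(in_x & in_y)
  i / (sum(in_x) + sum(in_y) - i)
}

#' Pairwise Jaccard overlap matrix across cell types
#'
#' Enhancer comparisons use interval Jaccard ([jaccard_intervals()]);
#' promoter comparisons use plain set Jaccard on target gene symbols.
#'
#' @param networks named list of per-cell-type EPI data.frames (>= 2).
#' @param kind "enhancer" or "promoter".
#' @param level for enhancers: "element" or "bp".
#' @return symmetric numeric matrix with unit diagonal (for non-empty
#'   sets), labelled by cell type.
#' @export
jaccard_matrix <- function(networks, kind = c("enhancer", "promoter"),
                           level = "element") {
  kind <- match.arg(kind)
  cts <- names(networks)
  stopifnot(length(networks) >= 2, !is.null(cts))
  n <- length(cts)
  m <- matrix(NA_real_, n, n, dimnames = list(cts, cts))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- if (kind == "enhancer") {
        jaccard_intervals(.network_enhancers(networks[[i]]),
                          .network_enhancers(networks[[j]]), level = level)
      } else {
        a <- unique(networks[[i]]$target_gene)
        b <- unique(networks[[j]]$target_gene)
        if (length(a) == 0 && length(b) == 0) NA_real_
        else length(intersect(a, b)) / length(union(a, b))
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}
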