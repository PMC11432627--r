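#' Per-cell-type TF presence counts from a TFBS table
#'
#' For every TF and cell type, counts the number of distinct enhancers of
#' that cell type's network with at least one predicted binding site
#' (multiple motifs of one TF in one enhancer were already collapsed by
#' [read_fimo_tsv()]). TFBS rows whose enhancer interval matches no
#' network enhancer exactly are skipped with a warning; TFs bound nowhere
#' are excluded.
#'
#' @param tfbs data.frame from [read_fimo_tsv()] (`tf`, `chrom`, `start`,
#'   `end`).
#' @param networks named list of per-cell-type EPI data.frames.
#' @return integer matrix, TFs x cell types.
#' @export
binary_presence_matrix <- function(tfbs, networks) {
  cts <- names(networks)
  stopifnot(!is.null(cts), all(c("tf", "chrom", "start", "end") %in% names(tfbs)))
  site_key <- interval_key(tfbs)
  known <- unique(unlist(lapply(networks, function(x) interval_key(.network_enhancers(x)))))
  unknown <- !site_key %in% known
  if (any(unknown)) {
    warning(sum(unknown), " TFBS row(s) reference enhancers absent from ",
            "every network; skipped")
    tfbs <- tfbs[!unknown, , drop = FALSE]
    site_key <- site_key[!unknown]
  }
  tfs <- sort(unique(tfbs$tf))
  counts <- matrix(0L, length(tfs), length(cts), dimnames = list(tfs, cts))
  for (ct in cts) {
    keys_ct <- unique(interval_key(.network_enhancers(networks[[ct]])))
    sel <- site_key %in% keys_ct
    if (!any(sel)) next
    tab <- table(tfbs$tf[sel])
    counts[names(tab), ct] <- as.integer(tab)
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  counts
}

#' Row-normalised (weighted) TF presence matrix
#'
#' Each TF's count in a cell type is divided by the total number of
#' enhancers the TF binds across all six cell types, so every row sums
#' to 1. TFs with zero total binding are dropped with a warning.
#'
#' @param counts matrix from [binary_presence_matrix()].
#' @return numeric matrix of weights, rows summing to 1.
#' @export
weighted_presence_matrix <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " TF(s) with zero total binding excluded")
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  sweep(counts, 1, totals, "/")
}

#' Cluster TF binding profiles into three stage-preference groups
#'
#' k-means (Euclidean, `nstart` restarts under a fixed seed) on the rows
#' of the weighted presence matrix, with clusters labelled by the
#' difference between their centre's mean weight over progenitor columns
#' and over mature columns: the cluster with the largest difference is
#' `higher_progenitor`, the smallest `higher_mature`, and the middle one
#' `equal`. Ties in the ordering are broken by cluster index.
#'
#' @param weights matrix from [weighted_presence_matrix()]; columns must
#'   be the six cell types of `stages`.
#' @param k number of clusters (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @param stages stage map; default [default_stages()].
#' @param nstart number of k-means restarts (best inertia wins).
#' @return list with `assignment` (named factor tf -> label), `centers`,
#'   `cluster` (raw k-means cluster ids), `k`, `seed`.
#' @export
cluster_tf_profiles <- function(weights, k = 3, seed = 1,
                                stages = default_stages(), nstart = 10) {
  .check_stages(stages)
  if (nrow(weights) < k) stop("fewer TFs than clusters (k = ", k, ")")
  stopifnot(all(names(stages) %in% colnames(weights)))
  w <- weights[, names(stages), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(w, centers = k, nstart = nstart)
  prog <- names(stages)[stages == "progenitor"]
  mat <- names(stages)[stages == "mature"]
  delta <- rowMeans(km$centers[, prog, drop = FALSE]) -
    rowMeans(km$centers[, mat, drop = FALSE])
  ord <- order(delta, decreasing = TRUE) # ties: lower cluster index first
  labels <- character(k)
  labels[ord[1]] <- "higher_progenitor"
  labels[ord[k]] <- "higher_mature"
  labels[ord[-c(1, k)]] <- "equal"
  assignment <- factor(labels[km$cluster],
                       levels = c("higher_progenitor", "equal", "higher_mature"))
  names(assignment) <- rownames(w)
  list(assignment = assignment, centers = km$centers,
       cluster = km$cluster, k = k, seed = seed)
}

#' Group TFs by the cell type of their peak expression
#'
#' Each TF is assigned to the cell type with its highest TPM, and to that
#' cell type's differentiation stage. Exact ties go to the first cell
#' type in the stage-map order and are flagged. TFs absent from every
#' table are reported as unassigned.
#'
#' @param tpm_tables named list (by cell type) of named numeric TPM
#'   vectors, as from [read_tpm_table()].
#' @param tfs character vector of TF gene symbols.
#' @param stages stage map; default [default_stages()].
#' @return data.frame with `tf`, `cell_type`, `stage`, `tie`; unassigned
#'   TFs carried in attribute `"unassigned"`.
#' @export
group_tfs_by_expression <- function(tpm_tables, tfs,
                                    stages = default_stages()) {
  .check_stages(stages)
  cts <- names(stages)
  stopifnot(all(cts %in% names(tpm_tables)))
  expr <- sapply(cts, function(ct) {
    v <- tpm_tables[[ct]][tfs]
    ifelse(is.na(v), NA_real_, v)
  })
  if (length(tfs) == 1) expr <- matrix(expr, nrow = 1, dimnames = list(NULL, cts))
  present <- rowSums(!is.na(expr)) > 0
  unassigned <- tfs[!present]
  expr0 <- expr
  expr0[is.na(expr0)] <- -Inf
  idx <- apply(expr0, 1, which.max)
  tie <- apply(expr0, 1, function(r) sum(r == max(r)) > 1)
  out <- data.frame(
    tf = tfs[present],
    cell_type = cts[idx[present]],
    stage = unname(stages[cts[idx[present]]]),
    tie = tie[present],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}
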