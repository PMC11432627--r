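#' Enhancer activity from ATAC and H3K27ac read counts
#'
#' Activity combines chromatin accessibility (ATAC-seq peak read count)
#' and histone acetylation (H3K27ac peak read count). The default is the
#' geometric mean, the combination used by the Activity-by-Contact model;
#' arithmetic mean and raw product are available since only ratios between
#' enhancers matter after the per-promoter normalisation.
#'
#' @param atac_count,h3k27ac_count non-negative read counts (vectorised).
#' @param method one of "geometric", "arithmetic", "product".
#' @return numeric activity, same length as the inputs.
#' @examples
#' enhancer_activity(16, 4) # 8
#' @export
enhancer_activity <- function(atac_count, h3k27ac_count,
                              method = c("geometric", "arithmetic", "product")) {
  method <- match.arg(method)
  if (any(atac_count < 0) || any(h3k27ac_count < 0)) {
    stop("read counts must be non-negative")
  }
  switch(method,
    geometric = sqrt(atac_count * h3k27ac_count),
    arithmetic = (atac_count + h3k27ac_count) / 2,
    product = atac_count * h3k27ac_count
  )
}

#' Power-law contact model
#'
#' Estimated enhancer-promoter contact frequency as a function of genomic
#' distance: `max(distance, d_min)^(-gamma)`. The floor `d_min` keeps
#' contact finite at zero distance and flat below the resolution at which
#' a power law is a sensible description of chromatin contact.
#'
#' @param gamma power-law exponent (> 0), default 1.
#' @param d_min distance floor in bp, default 5000.
#' @param scale positive prefactor; the per-promoter normalisation makes
#'   ABC scores invariant to it, so it only matters when contact values
#'   are inspected directly.
#' @return an object of class `contact_model`.
#' @export
contact_model <- function(gamma = 1.0, d_min = 5000L, scale = 1.0) {
  stopifnot(gamma > 0, d_min >= 1, scale > 0)
  structure(list(gamma = gamma, d_min = d_min, scale = scale),
            class = "contact_model")
}

#' Contact frequency at a genomic distance
#'
#' @param distance non-negative distance(s) in bp.
#' @param model a [contact_model()].
#' @return positive contact frequency, non-increasing in distance.
#' @examples
#' contact_frequency(1000, contact_model(gamma = 1, d_min = 1)) # 1e-3
#' @export
contact_frequency <- function(distance, model = contact_model()) {
  stopifnot(all(distance >= 0))
  model$scale * pmax(distance, model$d_min)^(-model$gamma)
}

#' Activity-by-Contact scores for one promoter
#'
#' For each candidate enhancer within 5 Mb of the TSS (midpoint-to-TSS
#' distance), the score is activity x contact divided by the summed
#' activity x contact over all enhancers in the window. Enhancers beyond
#' the window are excluded from both numerator and denominator, so scores
#' over the window sum to 1. If every in-window activity is zero the
#' promoter is degenerate: all scores are 0 with a warning.
#'
#' @param enhancers data.frame with `chrom`, `start`, `end`, `atac_count`,
#'   `h3k27ac_count` (intervals 0-based half-open, width 500 bp expected).
#' @param tss TSS position in bp (same chromosome as the enhancers).
#' @param model a [contact_model()].
#' @param window half-width of the candidate window in bp (default 5e6).
#' @param activity_method passed to [enhancer_activity()].
#' @return the input data.frame restricted to in-window enhancers, with an
#'   `abc_score` column appended.
#' @export
compute_abc_scores <- function(enhancers, tss, model = contact_model(),
                               window = 5e6,
                               activity_method = "geometric") {
  stopifnot(is.data.frame(enhancers),
            all(c("start", "end", "atac_count", "h3k27ac_count") %in%
                  names(enhancers)))
  mid <- (enhancers$start + enhancers$end) / 2
  dist <- abs(mid - tss)
  keep <- dist <= window
  if (!any(keep)) stop("no enhancer within ", window, " bp of the TSS")
  e <- enhancers[keep, , drop = FALSE]
  act <- enhancer_activity(e$atac_count, e$h3k27ac_count,
                           method = activity_method)
  contact <- contact_frequency(dist[keep], model)
  raw <- act * contact
  total <- sum(raw)
  if (total == 0) {
    warning("all enhancer activities are zero for this promoter; ",
            "scores set to 0")
    e$abc_score <- rep(0, nrow(e))
  } else {
    e$abc_score <- raw / total
  }
  rownames(e) <- NULL
  e
}

#' Filter EPIs on ABC score and target gene expression
#'
#' Active interactions keep an ABC score of at least `score_min` (default
#' 0.02, the score below which interactions are removed) and a target-gene
#' expression strictly greater than `tpm_min` (default 1 TPM). Row order
#' is preserved.
#'
#' @param records EPI data.frame (dialect of [read_epi_table()]).
#' @param score_min minimum ABC score kept (inclusive).
#' @param tpm_min TPM bound; targets must exceed it strictly.
#' @return the filtered records.
#' @export
filter_epis <- function(records, score_min = 0.02, tpm_min = 1) {
  stopifnot(all(c("abc_score", "target_tpm") %in% names(records)))
  keep <- records$abc_score >= score_min & records$target_tpm > tpm_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
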