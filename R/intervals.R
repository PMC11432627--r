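#' Convert a BED-style interval table to a GRanges object
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' an interval covers bases `start .. end - 1`. GenomicRanges is 1-based
#' closed, so conversion shifts `start` by one.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`; extra columns are carried as metadata.
#' @return a `GRanges` with the same rows, extra columns kept as mcols.
#' @export
as_granges <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) > 0 && any(x$start >= x$end)) {
    stop("invalid interval(s): start >= end at row(s) ",
         paste(utils::head(which(x$start >= x$end), 5L), collapse = ", "))
  }
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  extra <- setdiff(names(x), c("chrom", "start", "end", "strand"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- x[, extra, drop = FALSE]
  }
  gr
}

#' Convert a GRanges back to a 0-based half-open interval table
#'
#' @param gr a `GRanges`.
#' @param keep_mcols keep metadata columns.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
as_bed_df <- function(gr, keep_mcols = TRUE) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (keep_mcols && ncol(S4Vectors::mcols(gr)) > 0) {
    out <- cbind(out, as.data.frame(S4Vectors::mcols(gr)))
  }
  rownames(out) <- NULL
  out
}

#' Exact-coordinate key for an enhancer interval
#'
#' Enhancer identity within a cell type is the exact (chrom, start, end)
#' triple; this key is used wherever enhancers are joined across tables
#' (TFBS tables, degree computation).
#' @param x interval data.frame.
#' @return character vector `"chrom:start-end"`.
#' @export
interval_key <- function(x) {
  paste0(x$chrom, ":", x$start, "-", x$end)
}

#' Parse `"chrom:start-end"` keys back to an interval table
#' @param keys character vector of keys.
#' @return data.frame chrom/start/end.
#' @export
parse_interval_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+)$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("unparsable interval identifier(s): ",
         paste(utils::head(keys[bad], 3L), collapse = ", "))
  }
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Merge intervals whose separation is at most `gap` base pairs
#'
#' Intervals within `gap` bp of each other (transitively) collapse to one
#' cluster spanning their union. `gap = 0` merges only overlapping or
#' book-ended intervals.
#'
#' @param intervals data.frame chrom/start/end (0-based half-open).
#' @param gap maximum separation in bp for two intervals to share a cluster.
#' @return list with `clusters` (merged interval data.frame) and
#'   `membership` (integer vector: cluster row index for each input row).
#' @export
merge_within_gap <- function(intervals, gap = 100L) {
  stopifnot(gap >= 0)
  gr <- as_granges(intervals[, c("chrom", "start", "end")])
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged, maxgap = gap)
  membership <- integer(length(gr))
  membership[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  list(clusters = as_bed_df(merged), membership = membership)
}

#' Elements of one interval set overlapping another by at least 1 bp
#'
#' @param a,b interval data.frames (0-based half-open).
#' @return logical vector over rows of `a`: TRUE where the element shares
#'   >= 1 bp with some element of `b`. Half-open adjacency does not count.
#' @export
overlap_elements <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  # sets may live on disjoint chromosomes; that is an ordinary no-overlap
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(a), as_granges(b))
  ) > 0
}
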