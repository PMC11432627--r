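#' Read a BED file of peaks, variants or gene annotations
#'
#' Supports BED3 up to BED6. Coordinates are kept 0-based half-open.
#' A numeric fourth column is interpreted as a score (BED3+score peak
#' files); otherwise columns follow the BED convention
#' (name, score, strand). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` that the file carries.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) {
    stop("malformed BED line(s) (fewer than 3 fields): line ",
         paste(utils::head(which(nf < 3L), 5L), collapse = ", "))
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("non-integer coordinates at line ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  bad <- start >= end
  if (any(bad)) {
    stop("start >= end at line ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  out <- data.frame(chrom = col(1L), start = start, end = end,
                    stringsAsFactors = FALSE)
  maxf <- max(nf)
  if (maxf >= 4L) {
    c4 <- col(4L)
    c4num <- suppressWarnings(as.numeric(c4))
    if (maxf == 4L && !anyNA(c4num[nf >= 4L])) {
      out$score <- c4num
    } else {
      out$name <- c4
      if (maxf >= 5L) out$score <- suppressWarnings(as.numeric(col(5L)))
      if (maxf >= 6L) out$strand <- col(6L)
    }
  }
  out
}

#' Write intervals as BED
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (written in BED column order).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.epi_columns <- c("chrom", "start", "end", "cell_type", "target_gene",
                  "tss", "gene_strand", "abc_score", "target_tpm")

#' Read an EPI table (9-column tab-separated dialect)
#'
#' The dialect carries one enhancer-promoter interaction per row:
#' `chrom, start, end, cell_type, target_gene, tss, gene_strand,
#' abc_score, target_tpm`. Enhancer coordinates are 0-based half-open.
#' To ingest genuine Activity-by-Contact tool output
#' (`EnhancerPredictionsFull.txt`), map its `chr/start/end/CellType/
#' TargetGene/TargetGeneTSS/ABC.Score` columns onto this dialect and add
#' the target gene's strand and TPM.
#'
#' @param path file path.
#' @return data.frame of EPI records.
#' @export
read_epi_table <- function(path) {
  stopifnot(file.exists(path))
  x <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.epi_columns, names(x))
  if (length(missing)) {
    stop("EPI table missing column(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, .epi_columns]
  for (col in c("start", "end", "tss")) x[[col]] <- as.integer(x[[col]])
  for (col in c("abc_score", "target_tpm")) x[[col]] <- as.numeric(x[[col]])
  validate_epi_records(x)
  x
}

#' Validate EPI records against the dialect's invariants
#' @param x EPI data.frame.
#' @return the input, invisibly; errors on violation.
#' @export
validate_epi_records <- function(x) {
  missing <- setdiff(.epi_columns, names(x))
  if (length(missing)) {
    stop("EPI table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$abc_score)) || any(x$abc_score < 0)) {
    stop("abc_score must be a non-negative number")
  }
  if (any(is.na(x$target_tpm)) || any(x$target_tpm < 0)) {
    stop("target_tpm must be a non-negative number")
  }
  if (any(x$start >= x$end)) stop("enhancer start >= end")
  if (!all(x$gene_strand %in% c("+", "-"))) {
    stop("gene_strand must be '+' or '-'")
  }
  mid <- (x$start + x$end) / 2
  if (any(abs(x$tss - mid) > 5e6)) {
    stop("enhancer further than 5 Mb from target TSS")
  }
  key <- paste(interval_key(x), x$target_gene, x$cell_type, sep = "|")
  if (anyDuplicated(key)) {
    warning("duplicate (enhancer, gene, cell_type) row(s) in EPI table")
  }
  invisible(x)
}

#' Write an EPI table in the package dialect
#' @param records EPI data.frame.
#' @param path output path.
#' @export
write_epi_table <- function(records, path) {
  validate_epi_records(records)
  utils::write.table(records[, .epi_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a FIMO TSV of predicted TF binding sites
#'
#' Applies the strict p-value filter (keep p < `p_threshold`) and collapses
#' multiple motifs of the same TF within one enhancer to a single
#' (tf, enhancer) row. `sequence_name` must identify the scanned enhancer
#' as `"chrom:start-end"` (0-based half-open). The TF name is taken from
#' `motif_alt_id` when present and non-empty, otherwise from the part of
#' `motif_id` before the first underscore.
#'
#' @param path FIMO TSV path (standard header with `motif_id`,
#'   `sequence_name`, `start`, `stop`, `strand`, `score`, `p-value`).
#' @param p_threshold strict upper bound on binding p-value (default 1e-5).
#' @return data.frame with `tf`, `chrom`, `start`, `end`, `p` (the minimum
#'   surviving p-value among collapsed motif hits).
#' @export
read_fimo_tsv <- function(path, p_threshold = 1e-5) {
  stopifnot(file.exists(path))
  x <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("motif_id", "sequence_name", "start", "stop", "strand",
            "score", "p-value")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("FIMO table missing column(s): ", paste(missing, collapse = ", "))
  }
  empty <- data.frame(tf = character(), chrom = character(),
                      start = integer(), end = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(x) == 0) return(empty)
  p <- as.numeric(x[["p-value"]])
  x <- x[!is.na(p) & p < p_threshold, , drop = FALSE]
  p <- as.numeric(x[["p-value"]])
  if (nrow(x) == 0) return(empty)
  tf <- if ("motif_alt_id" %in% names(x)) as.character(x$motif_alt_id) else NA_character_
  fallback <- sub("_.*$", "", x$motif_id)
  tf <- ifelse(is.na(tf) | !nzchar(tf), fallback, tf)
  enh <- parse_interval_key(x$sequence_name)
  out <- data.frame(tf = tf, chrom = enh$chrom, start = enh$start,
                    end = enh$end, p = p, stringsAsFactors = FALSE)
  key <- paste(out$tf, interval_key(out), sep = "|")
  pmin_by <- tapply(out$p, key, min)
  out <- out[!duplicated(key), , drop = FALSE]
  out$p <- as.numeric(pmin_by[paste(out$tf, interval_key(out), sep = "|")])
  rownames(out) <- NULL
  out
}

#' Read a two-column gene expression table (gene, TPM)
#'
#' @param path path to a headerless tab-separated file with gene symbol in
#'   column 1 and TPM in column 2.
#' @return named numeric vector of TPM keyed by gene symbol.
#' @export
read_tpm_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(numeric(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) < 2L)) {
    stop("TPM table must have two tab-separated columns")
  }
  gene <- vapply(fields, `[`, "", 1L)
  tpm <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(tpm)) {
    stop("non-numeric TPM at line ",
         paste(utils::head(which(is.na(tpm)), 5L), collapse = ", "))
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene symbol(s) in TPM table: ",
         paste(utils::head(unique(gene[duplicated(gene)]), 5L), collapse = ", "))
  }
  stats::setNames(tpm, gene)
}

#' Write a two-column gene expression table
#' @param tpm named numeric vector (names are gene symbols).
#' @param path output path.
#' @export
write_tpm_table <- function(tpm, path) {
  utils::write.table(data.frame(gene = names(tpm), tpm = unname(tpm)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a one-gene-per-line list file
#'
#' Matching against these lists elsewhere in the package is exact,
#' full-string symbol matching (SOX2 never matches SOX21).
#'
#' @param path file path.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !grepl("^#", lines)])
}
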