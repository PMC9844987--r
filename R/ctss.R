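#' Per-position CAGE TSS count matrix
#'
#' Container for CTSS (CAGE-defined transcription start site) counts: one row
#' per (chrom, pos, strand) key, one column per sample. Rows are kept sorted
#' by chromosome, strand and position, and keys must be unique. Counts are
#' non-negative; they are integers for sequenced data but fractional values
#' are allowed so that expected-count (deterministic) simulations can flow
#' through the same pipeline.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param counts Numeric matrix with one row per position and named columns
#'   (sample identifiers).
#' @return An object of class `ctss_matrix`: a list with elements `info`
#'   (data.frame `chrom`, `pos`, `strand`) and `counts` (matrix).
#' @examples
#' x <- ctss_matrix("chr1", c(100L, 101L), c("+", "+"),
#'                  matrix(1:4, 2, dimnames = list(NULL, c("s1", "s2"))))
#' x
#' @export
ctss_matrix <- function(chrom, pos, strand, counts) {
  counts <- as.matrix(counts)
  n <- length(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(chrom) != n || length(strand) != n || nrow(counts) != n)
    stop("chrom, pos, strand and rows of counts must have equal length")
  if (is.null(colnames(counts)))
    stop("counts must have sample identifiers as column names")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  key <- paste(chrom, strand, pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, strand) keys")
  o <- order(chrom, strand, pos)
  x <- list(
    info = data.frame(chrom = chrom[o], pos = as.integer(pos)[o],
                      strand = strand[o], stringsAsFactors = FALSE),
    counts = counts[o, , drop = FALSE]
  )
  rownames(x$counts) <- NULL
  class(x) <- "ctss_matrix"
  x
}

#' @export
print.ctss_matrix <- function(x, ...) {
  cat("CTSS matrix:", nrow(x$info), "positions x", ncol(x$counts), "samples\n")
  cat("  chromosomes:", paste(unique(x$info$chrom), collapse = ", "), "\n")
  cat("  total count:", sum(x$counts), "\n")
  invisible(x)
}

#' @export
dim.ctss_matrix <- function(x) dim(x$counts)

#' Subset a CTSS matrix by row
#'
#' @param x A [ctss_matrix()].
#' @param i Row index (integer or logical).
#' @param ... Ignored.
#' @return A `ctss_matrix` with the selected positions.
#' @export
`[.ctss_matrix` <- function(x, i, ...) {
  out <- list(info = x$info[i, , drop = FALSE],
              counts = x$counts[i, , drop = FALSE])
  rownames(out$info) <- NULL
  class(out) <- "ctss_matrix"
  out
}

#' Sample identifiers of a CTSS matrix
#' @param x A [ctss_matrix()].
#' @return Character vector of sample ids (column names).
#' @export
ctss_samples <- function(x) colnames(x$counts)

#' Per-CTSS TPM and pooled TPM
#'
#' Tags-per-million normalization at single-position resolution:
#' `TPM[s] = count[s] / mapped_read_total[s] * 1e6`. The pooled signal used
#' for summits and decomposition is the sum of per-sample TPM, so that
#' deeply sequenced libraries do not dominate positional signal.
#'
#' @param ctss A [ctss_matrix()].
#' @param meta Library metadata data.frame with columns `sample_id` and
#'   `mapped_read_total` (see [library_meta()]).
#' @return For `ctss_tpm`, a numeric matrix of the same shape as the counts;
#'   for `pooled_tpm`, a numeric vector (one value per CTSS).
#' @export
ctss_tpm <- function(ctss, meta) {
  lib <- match_library_sizes(ctss_samples(ctss), meta)
  sweep(ctss$counts, 2, lib, "/") * 1e6
}

#' @rdname ctss_tpm
#' @export
pooled_tpm <- function(ctss, meta) {
  rowSums(ctss_tpm(ctss, meta))
}

#' Library metadata table
#'
#' @param sample_id Character vector of sample identifiers.
#' @param mapped_read_total Positive numeric vector of mapped CAGE read
#'   totals, used as TPM denominators.
#' @param batch,population Optional labels (library preparation batch and
#'   genetic population), used as QTL covariates.
#' @return A data.frame of class `library_meta`.
#' @export
library_meta <- function(sample_id, mapped_read_total,
                         batch = NULL, population = NULL) {
  if (any(mapped_read_total <= 0)) stop("mapped_read_total must be > 0")
  out <- data.frame(sample_id = as.character(sample_id),
                    mapped_read_total = as.numeric(mapped_read_total),
                    stringsAsFactors = FALSE)
  if (!is.null(batch)) out$batch <- as.character(batch)
  if (!is.null(population)) out$population <- as.character(population)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample_id in metadata")
  class(out) <- c("library_meta", "data.frame")
  out
}

# Map sample ids to mapped-read totals, erroring on samples absent from meta.
match_library_sizes <- function(samples, meta) {
  idx <- match(samples, meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from library metadata: ",
         paste(samples[is.na(idx)], collapse = ", "))
  stats::setNames(meta$mapped_read_total[idx], samples)
}

#' Pooled signal track from a CTSS matrix
#'
#' Collapses a per-sample CTSS matrix into a single stranded track of pooled
#' TPM, e.g. for cross-correlation against MNase 5'-end signal.
#'
#' @inheritParams ctss_tpm
#' @return data.frame with columns `chrom`, `pos`, `strand`, `score`.
#' @export
pooled_track <- function(ctss, meta) {
  data.frame(ctss$info, score = pooled_tpm(ctss, meta),
             stringsAsFactors = FALSE)
}
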