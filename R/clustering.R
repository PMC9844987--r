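# CAGE tag clustering: support filtering, single-linkage positional
# clustering, quantification over unfiltered CTSSs, TPM normalization,
# summit detection, and annotation-proximity + expression filtering.

#' Filter CTSSs by sample support
#'
#' Retains CTSSs observed with at least `min_count` reads in at least
#' `min_samples` samples. Support filtering defines which positions seed tag
#' clusters; quantification of the resulting clusters deliberately uses the
#' unfiltered CTSS matrix (see [quantify_clusters()]) so that rare TSS usage
#' within an active promoter is still counted.
#'
#' @param ctss A [ctss_matrix()].
#' @param min_count Minimum read count per supporting sample (default 1).
#' @param min_samples Minimum number of supporting samples (default 5,
#'   i.e. at least 1 read in at least 5 libraries).
#' @return A filtered [ctss_matrix()].
#' @export
support_filter_ctss <- function(ctss, min_count = 1, min_samples = 5) {
  if (min_count < 1 || min_samples < 1)
    stop("min_count and min_samples must be >= 1")
  keep <- rowSums(ctss$counts >= min_count) >= min_samples
  ctss[keep]
}

#' Positional tag clustering of CTSSs
#'
#' Single-linkage clustering of supported CTSSs: consecutive positions on
#' the same chromosome and strand are joined into one tag cluster whenever
#' their distance is at most `max_gap` bp (a distance of exactly `max_gap`
#' merges). Opposite strands never merge.
#'
#' @param ctss A (support-filtered) [ctss_matrix()].
#' @param max_gap Maximum distance in bp between cluster members
#'   (default 60).
#' @return data.frame of cluster extents: `id`, `chrom`, `strand`, `start`,
#'   `end`, `n_ctss`.
#' @export
cluster_ctss <- function(ctss, max_gap = 60) {
  if (max_gap < 0) stop("max_gap must be non-negative")
  info <- ctss$info
  if (!nrow(info))
    return(data.frame(id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), n_ctss = integer(0)))
  grp_key <- paste(info$chrom, info$strand)
  # info is sorted by (chrom, strand, pos); break clusters at strand/chrom
  # changes or position gaps > max_gap
  new_cluster <- c(TRUE, diff(info$pos) > max_gap |
                     grp_key[-1L] != grp_key[-length(grp_key)])
  grp <- cumsum(new_cluster)
  start <- tapply(info$pos, grp, min)
  end <- tapply(info$pos, grp, max)
  first <- !duplicated(grp)
  out <- data.frame(
    chrom = info$chrom[first], strand = info$strand[first],
    start = as.integer(start), end = as.integer(end),
    n_ctss = as.integer(table(grp)), stringsAsFactors = FALSE)
  out$id <- sprintf("%s:%d-%d:%s", out$chrom, out$start, out$end, out$strand)
  rownames(out) <- NULL
  out[, c("id", "chrom", "strand", "start", "end", "n_ctss")]
}

#' Quantify tag clusters from the unfiltered CTSS matrix
#'
#' Sums, per sample, all CTSS counts falling within each cluster extent on
#' the cluster's strand. No support filtering is applied at this stage:
#' positions too rare to seed a cluster still contribute to expression.
#'
#' @param ctss The full (unfiltered) [ctss_matrix()].
#' @param extents data.frame of cluster extents as from [cluster_ctss()].
#' @return A `promoter_set`: list with `clusters` (extent data.frame plus
#'   `width`), `counts` (clusters x samples matrix) and `samples`.
#' @export
quantify_clusters <- function(ctss, extents) {
  for (k in split(extents, paste(extents$chrom, extents$strand))) {
    k <- k[order(k$start), ]
    if (nrow(k) > 1L && any(k$start[-1L] <= k$end[-nrow(k)]))
      stop("overlapping cluster extents on the same chrom and strand")
  }
  q <- GenomicRanges::GRanges(ctss$info$chrom,
                              IRanges::IRanges(ctss$info$pos, width = 1L),
                              strand = ctss$info$strand)
  s <- GenomicRanges::GRanges(extents$chrom,
                              IRanges::IRanges(extents$start, extents$end),
                              strand = extents$strand)
  hits <- GenomicRanges::findOverlaps(q, s)
  counts <- matrix(0, nrow(extents), ncol(ctss$counts),
                   dimnames = list(extents$id, ctss_samples(ctss)))
  if (length(hits)) {
    agg <- rowsum(ctss$counts[S4Vectors::queryHits(hits), , drop = FALSE],
                  S4Vectors::subjectHits(hits))
    counts[as.integer(rownames(agg)), ] <- agg
  }
  clusters <- extents
  clusters$width <- clusters$end - clusters$start + 1L
  out <- list(clusters = clusters, counts = counts,
              samples = ctss_samples(ctss))
  class(out) <- "promoter_set"
  out
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set:", nrow(x$clusters), "clusters x",
      length(x$samples), "samples\n")
  if (!is.null(x$tpm)) cat("  TPM-normalized\n")
  if (!is.null(x$clusters$summit)) cat("  summits computed\n")
  if (!is.null(x$clusters$gene))
    cat("  annotated:", sum(!is.na(x$clusters$gene)), "with gene labels\n")
  invisible(x)
}

#' TPM-normalize cluster counts
#'
#' `TPM[s] = count[s] / mapped_read_total[s] * 1e6`, using each library's
#' total mapped CAGE reads, not the within-cluster total.
#'
#' @param proms A `promoter_set` from [quantify_clusters()].
#' @param meta A [library_meta()] table covering all samples.
#' @return The `promoter_set` with a `tpm` matrix added.
#' @export
tpm_normalize <- function(proms, meta) {
  lib <- match_library_sizes(proms$samples, meta)
  proms$tpm <- sweep(proms$counts, 2, lib, "/") * 1e6
  proms
}

#' Summit (dominant TSS) of a cluster
#'
#' The member CTSS with maximal pooled signal. Ties are broken to the
#' 5'-most position: smallest coordinate on the plus strand, largest on the
#' minus strand.
#'
#' @param pos Integer vector of member CTSS positions.
#' @param pooled Pooled (cross-sample TPM) signal at those positions.
#' @param strand `"+"` or `"-"`.
#' @return The summit position (bp).
#' @export
find_summit <- function(pos, pooled, strand = "+") {
  if (!length(pos)) stop("cluster has no member CTSSs")
  at_max <- pos[pooled == max(pooled)]
  if (strand == "+") min(at_max) else max(at_max)
}

#' Add summits to a promoter set
#'
#' Computes each cluster's dominant TSS from pooled per-CTSS TPM (sum of
#' per-sample TPM across the panel).
#'
#' @param proms A `promoter_set`.
#' @param ctss The full [ctss_matrix()].
#' @param meta A [library_meta()] table.
#' @return The `promoter_set` with a `summit` column.
#' @export
add_summits <- function(proms, ctss, meta) {
  pool <- pooled_tpm(ctss, meta)
  cl <- proms$clusters
  summit <- integer(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    sel <- which(ctss$info$chrom == cl$chrom[i] &
                   ctss$info$strand == cl$strand[i] &
                   ctss$info$pos >= cl$start[i] & ctss$info$pos <= cl$end[i])
    summit[i] <- find_summit(ctss$info$pos[sel], pool[sel], cl$strand[i])
  }
  proms$clusters$summit <- summit
  proms
}

#' Annotation-proximity and expression filtering of clusters
#'
#' Keeps clusters whose summit lies within `upstream_window` bp upstream of
#' an annotated TSS on the same strand (the annotated position itself
#' included), and whose counts reach `min_count` in strictly more than
#' `min_samples_strict` samples. A cluster matching several TSSs is
#' assigned the nearest (ties to the first by coordinate).
#'
#' @param proms A `promoter_set` with summits.
#' @param annotation data.frame with columns `chrom`, `tss` (1-based),
#'   `strand`, `gene` (see [annotation_from_bed()]).
#' @param upstream_window Window upstream of the annotated TSS, bp
#'   (default 1000).
#' @param min_count Count threshold per sample (default 10).
#' @param min_samples_strict Number of samples that must be exceeded
#'   (strict; default 10, i.e. more than 10 samples).
#' @return The filtered `promoter_set` with a `gene` column.
#' @export
annotate_and_filter <- function(proms, annotation, upstream_window = 1000,
                                min_count = 10, min_samples_strict = 10) {
  if (is.null(proms$clusters$summit))
    stop("summits must be computed first (add_summits)")
  cl <- proms$clusters
  gene <- rep(NA_character_, nrow(cl))
  for (i in seq_len(nrow(cl))) {
    ann <- annotation[annotation$chrom == cl$chrom[i] &
                        annotation$strand == cl$strand[i], , drop = FALSE]
    if (!nrow(ann)) next
    s <- cl$summit[i]
    hit <- if (cl$strand[i] == "+")
      s >= ann$tss - upstream_window & s <= ann$tss
    else
      s >= ann$tss & s <= ann$tss + upstream_window
    ann <- ann[hit, , drop = FALSE]
    if (!nrow(ann)) next
    ann <- ann[order(abs(s - ann$tss), ann$tss), , drop = FALSE]
    gene[i] <- ann$gene[1L]
  }
  expressed <- rowSums(proms$counts >= min_count) > min_samples_strict
  keep <- !is.na(gene) & expressed
  if (!any(keep))
    message("annotate_and_filter: no clusters pass; returning empty set")
  proms$clusters <- cbind(cl, gene = gene)[keep, , drop = FALSE]
  rownames(proms$clusters) <- NULL
  proms$counts <- proms$counts[keep, , drop = FALSE]
  if (!is.null(proms$tpm)) proms$tpm <- proms$tpm[keep, , drop = FALSE]
  proms
}

#' Build CAGE-inferred promoters from CTSS data
#'
#' Convenience pipeline: support-filter, cluster, quantify over the
#' unfiltered CTSSs, TPM-normalize, locate summits, and (if an annotation is
#' supplied) apply the annotation-proximity and expression filters.
#'
#' @param ctss A [ctss_matrix()].
#' @param meta A [library_meta()] table.
#' @param annotation Optional TSS annotation (see [annotate_and_filter()]).
#' @param max_gap Clustering distance, bp (default 60).
#' @param min_count,min_samples Support-filter thresholds (defaults 1, 5).
#' @param upstream_window,min_expr_count,min_expr_samples Annotation-filter
#'   parameters (defaults 1000 bp, 10 counts, more than 10 samples).
#' @return A `promoter_set` with counts, TPM and summits.
#' @export
build_promoters <- function(ctss, meta, annotation = NULL, max_gap = 60,
                            min_count = 1, min_samples = 5,
                            upstream_window = 1000, min_expr_count = 10,
                            min_expr_samples = 10) {
  supported <- support_filter_ctss(ctss, min_count, min_samples)
  extents <- cluster_ctss(supported, max_gap)
  proms <- quantify_clusters(ctss, extents)
  proms <- tpm_normalize(proms, meta)
  proms <- add_summits(proms, ctss, meta)
  if (!is.null(annotation))
    proms <- annotate_and_filter(proms, annotation, upstream_window,
                                 min_expr_count, min_expr_samples)
  proms
}

#' Export cluster extents as BED6
#'
#' @param proms A `promoter_set`.
#' @param path Output BED path (0-based half-open on disk).
#' @return `path`, invisibly.
#' @export
promoters_to_bed <- function(proms, path) {
  cl <- proms$clusters
  write_bed6(data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
                        name = cl$id, score = 0, strand = cl$strand),
             path)
}
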