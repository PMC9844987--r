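# TSS architecture within promoters: local-maxima decomposition into core
# promoters, shape metrics (width-normalized Shannon entropy, IQR width),
# significant-contribution filtering, decomposed-promoter correlation, and
# CAGE/MNase positional cross-correlation.

#' Local-maxima decomposition of a multi-modal promoter
#'
#' Splits a tag cluster into candidate core promoters around local maxima of
#' pooled CAGE signal:
#'
#' 1. Local maxima are selected by a greedy scan of member CTSSs in
#'    decreasing pooled signal (ties by ascending coordinate); a CTSS is
#'    accepted if it lies at least `min_sep` bp from every accepted maximum.
#' 2. Each maximum is processed in decreasing signal order with threshold
#'    `t = frac_thr * pooled(maximum)`. Extension proceeds outwards bp by
#'    bp, retaining CTSSs with pooled signal >= t; a stretch of more than
#'    `max_gap` consecutive bp below `t` (missing positions count)
#'    terminates extension, as does any position already claimed by an
#'    earlier (stronger) decomposed promoter. A maximum whose own position
#'    was claimed yields nothing.
#' 3. Non-zero CTSSs within `smooth` bp of a retained CTSS are added
#'    (single pass).
#' 4. Decomposed promoters whose extents are separated by at most `merge`
#'    intervening bp are merged.
#'
#' @param pos Integer vector of member CTSS positions (any order).
#' @param pooled Pooled TPM at those positions (same length).
#' @param min_sep Minimum distance between local maxima, bp (default 20).
#' @param frac_thr Fraction of the local maximum's signal required to
#'   retain a CTSS (default 0.10).
#' @param max_gap Longest tolerated below-threshold stretch, bp
#'   (default 10).
#' @param smooth Smoothing neighborhood for non-zero CTSSs, bp (default 1).
#' @param merge Maximum separation between decomposed promoters that are
#'   merged, bp (default 1).
#' @return list of decomposed promoters ordered by start coordinate; each a
#'   list with `start`, `end`, `local_max_pos`, `members` (CTSS positions).
#' @export
decompose_local_maxima <- function(pos, pooled, min_sep = 20,
                                   frac_thr = 0.10, max_gap = 10,
                                   smooth = 1, merge = 1) {
  if (!length(pos)) stop("empty promoter: no member CTSSs")
  if (length(pooled) != length(pos)) stop("pos and pooled lengths differ")
  if (min_sep <= 0 || frac_thr <= 0 || max_gap <= 0 || smooth <= 0 ||
      merge <= 0)
    stop("decomposition parameters must be > 0")
  if (all(pooled <= 0)) stop("promoter has no pooled signal")
  o <- order(pos)
  pos <- pos[o]; pooled <- pooled[o]
  lo <- min(pos)
  dense <- numeric(max(pos) - lo + 1L)
  dense[pos - lo + 1L] <- pooled
  L <- length(dense)

  # step 1: greedy local maxima
  cand <- order(-pooled, pos)
  maxima <- integer(0)
  for (i in cand) {
    if (pooled[i] <= 0) break
    if (!length(maxima) || all(abs(pos[i] - maxima) >= min_sep))
      maxima <- c(maxima, pos[i])
  }

  # steps 2-3: extension with priority claiming, then smoothing
  claimed <- logical(L)
  dps <- list()
  for (m in maxima) {
    mi <- m - lo + 1L
    if (claimed[mi]) next
    t <- frac_thr * dense[mi]
    keep <- mi
    for (dir in c(1L, -1L)) {
      gap <- 0L
      j <- mi + dir
      while (j >= 1L && j <= L) {
        if (claimed[j]) break
        if (dense[j] >= t) {
          keep <- c(keep, j)
          gap <- 0L
        } else {
          gap <- gap + 1L
          if (gap > max_gap) break
        }
        j <- j + dir
      }
    }
    near <- unique(unlist(lapply(keep, function(k)
      seq(max(1L, k - smooth), min(L, k + smooth)))))
    near <- near[dense[near] > 0 & !claimed[near] & !(near %in% keep)]
    keep <- sort(unique(c(keep, near)))
    claimed[keep] <- TRUE
    dps[[length(dps) + 1L]] <- list(local_max_pos = m,
                                    members = keep + lo - 1L)
  }
  if (!length(dps)) return(list())

  # step 4: merge near-adjacent decomposed promoters
  dps <- dps[order(vapply(dps, function(d) min(d$members), numeric(1)))]
  merged <- list(dps[[1L]])
  for (d in dps[-1L]) {
    last <- merged[[length(merged)]]
    if (min(d$members) - max(last$members) - 1L <= merge) {
      last$members <- c(last$members, d$members)
      # dominant maximum of the merged pair
      if (dense[d$local_max_pos - lo + 1L] >
          dense[last$local_max_pos - lo + 1L])
        last$local_max_pos <- d$local_max_pos
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- d
    }
  }
  lapply(merged, function(d) {
    d$members <- sort(d$members)
    d$start <- min(d$members)
    d$end <- max(d$members)
    d[c("start", "end", "local_max_pos", "members")]
  })
}

#' Decompose all promoters of a set
#'
#' Applies [decompose_local_maxima()] to every cluster, quantifies each
#' decomposed promoter by summing its member CTSS counts, TPM-normalizes,
#' and computes each decomposed promoter's per-sample fraction of its
#' parent's TPM (0 where the parent is 0).
#'
#' @param proms A TPM-normalized `promoter_set` (see [build_promoters()]).
#' @param ctss The full [ctss_matrix()].
#' @param meta A [library_meta()] table.
#' @inheritParams decompose_local_maxima
#' @return A `decomposed_set`: list with `clusters` (data.frame `id`,
#'   `parent_id`, `chrom`, `strand`, `start`, `end`, `width`,
#'   `local_max_pos`), `counts`, `tpm`, `fraction` matrices and `samples`.
#' @export
decompose_promoters <- function(proms, ctss, meta, min_sep = 20,
                                frac_thr = 0.10, max_gap = 10, smooth = 1,
                                merge = 1) {
  if (is.null(proms$tpm)) stop("promoter set must be TPM-normalized")
  pool <- pooled_tpm(ctss, meta)
  rows <- list(); cnts <- list()
  for (i in seq_len(nrow(proms$clusters))) {
    cl <- proms$clusters[i, ]
    sel <- which(ctss$info$chrom == cl$chrom &
                   ctss$info$strand == cl$strand &
                   ctss$info$pos >= cl$start & ctss$info$pos <= cl$end)
    if (!length(sel) || all(pool[sel] <= 0)) next
    dps <- decompose_local_maxima(ctss$info$pos[sel], pool[sel], min_sep,
                                  frac_thr, max_gap, smooth, merge)
    for (k in seq_along(dps)) {
      d <- dps[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s@%d", cl$id, k), parent_id = cl$id,
        chrom = cl$chrom, strand = cl$strand, start = d$start, end = d$end,
        width = d$end - d$start + 1L, local_max_pos = d$local_max_pos,
        stringsAsFactors = FALSE)
      mem <- sel[ctss$info$pos[sel] %in% d$members]
      cnts[[length(cnts) + 1L]] <-
        colSums(ctss$counts[mem, , drop = FALSE])
    }
  }
  if (!length(rows)) stop("no promoter could be decomposed")
  clusters <- do.call(rbind, rows)
  counts <- do.call(rbind, cnts)
  rownames(counts) <- clusters$id
  lib <- match_library_sizes(ctss_samples(ctss), meta)
  tpm <- sweep(counts, 2, lib, "/") * 1e6
  parent_tpm <- proms$tpm[clusters$parent_id, , drop = FALSE]
  fraction <- compute_fractions(tpm, parent_tpm)
  out <- list(clusters = clusters, counts = counts, tpm = tpm,
              fraction = fraction, samples = ctss_samples(ctss))
  class(out) <- "decomposed_set"
  out
}

#' @export
print.decomposed_set <- function(x, ...) {
  cat("Decomposed promoter set:", nrow(x$clusters), "decomposed promoters of",
      length(unique(x$clusters$parent_id)), "promoters\n")
  if (!is.null(x$clusters$significant))
    cat("  significant:", sum(x$clusters$significant), "\n")
  invisible(x)
}

#' Width-normalized Shannon entropy of a TSS profile
#'
#' With `p_i` the pooled-signal fraction at member CTSS `i`,
#' `H = -sum(p_i log2 p_i)`, normalized by `log2(width)` of the promoter so
#' that 0 marks a single sharp TSS and 1 a uniform spread over the full
#' extent. Single-bp promoters have entropy 0 by convention.
#'
#' @param pooled Pooled TPM of the member CTSSs.
#' @param width Promoter width in bp.
#' @return Normalized entropy in `[0, 1]`.
#' @export
shannon_entropy <- function(pooled, width) {
  if (sum(pooled) <= 0) stop("promoter has zero pooled signal")
  if (width < 1) stop("width must be >= 1")
  if (width == 1) return(0)
  p <- pooled[pooled > 0] / sum(pooled)
  -sum(p * log2(p)) / log2(width)
}

#' Interquartile width of a TSS profile
#'
#' Positions are traversed 5' to 3' (ascending on the plus strand,
#' descending on the minus strand); the quartile positions are the first at
#' which the cumulative pooled-signal fraction reaches 0.25 and 0.75, and
#' the width is their distance plus one.
#'
#' @param pos Member CTSS positions.
#' @param pooled Pooled TPM at those positions.
#' @param strand `"+"` or `"-"`.
#' @return IQR width in bp.
#' @export
iqr_width <- function(pos, pooled, strand = "+") {
  if (sum(pooled) <= 0) stop("promoter has zero pooled signal")
  o <- if (strand == "+") order(pos) else order(-pos)
  cum <- cumsum(pooled[o]) / sum(pooled)
  q25 <- pos[o][which(cum >= 0.25)[1L]]
  q75 <- pos[o][which(cum >= 0.75)[1L]]
  abs(q75 - q25) + 1L
}

#' Shape metrics for every promoter of a set
#'
#' @param proms A `promoter_set`.
#' @param ctss The full [ctss_matrix()].
#' @param meta A [library_meta()] table.
#' @param dps Optional `decomposed_set`; adds an `n_decomposed` column.
#' @return data.frame: `parent_id`, `width`, `entropy_norm`, `iqr_width`
#'   and, when `dps` is given, `n_decomposed`.
#' @export
shape_metrics <- function(proms, ctss, meta, dps = NULL) {
  pool <- pooled_tpm(ctss, meta)
  cl <- proms$clusters
  ent <- iqr <- numeric(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    sel <- which(ctss$info$chrom == cl$chrom[i] &
                   ctss$info$strand == cl$strand[i] &
                   ctss$info$pos >= cl$start[i] & ctss$info$pos <= cl$end[i])
    ent[i] <- shannon_entropy(pool[sel], cl$width[i])
    iqr[i] <- iqr_width(ctss$info$pos[sel], pool[sel], cl$strand[i])
  }
  out <- data.frame(parent_id = cl$id, width = cl$width,
                    entropy_norm = ent, iqr_width = iqr,
                    stringsAsFactors = FALSE)
  if (!is.null(dps)) {
    tab <- table(dps$clusters$parent_id)
    out$n_decomposed <- as.integer(tab[out$parent_id])
    out$n_decomposed[is.na(out$n_decomposed)] <- 0L
  }
  out
}

#' Flag decomposed promoters with substantial contribution
#'
#' A decomposed promoter is significant when its fraction of the parent's
#' expression is at least `min_frac` in at least
#' `ceiling(n_samples * min_sample_frac)` samples; a parent is eligible for
#' fraction-level analyses when it carries at least `min_dps` significant
#' decomposed promoters.
#'
#' @param dps A `decomposed_set`.
#' @param min_frac Minimum fraction of parent expression (default 0.05).
#' @param min_sample_frac Minimum proportion of samples (default 0.5).
#' @param min_dps Minimum significant decomposed promoters per eligible
#'   parent (default 2).
#' @return The `decomposed_set` with a logical `significant` column and an
#'   `eligible_parents` character vector element.
#' @export
contribution_filter <- function(dps, min_frac = 0.05, min_sample_frac = 0.5,
                                min_dps = 2) {
  need <- ceiling(length(dps$samples) * min_sample_frac)
  sig <- rowSums(dps$fraction >= min_frac) >= need
  dps$clusters$significant <- unname(sig)
  tab <- table(dps$clusters$parent_id[sig])
  dps$eligible_parents <- names(tab)[tab >= min_dps]
  dps
}

#' Minimum pairwise correlation among decomposed promoters
#'
#' Pearson correlation across samples for every unordered pair of
#' (significant) decomposed promoters of one parent; returns the minimum.
#' Compensatory (anti-correlated) core-promoter usage drives this value
#' negative. Pairs involving a constant expression vector are skipped with
#' a warning; if no pair remains, NA is returned.
#'
#' @param tpm Matrix of decomposed-promoter TPM (rows: >= 2 decomposed
#'   promoters of one parent; columns: samples).
#' @return Minimum pairwise Pearson correlation, or NA.
#' @export
min_pairwise_correlation <- function(tpm) {
  if (nrow(tpm) < 2L) stop("need >= 2 decomposed promoters")
  sds <- apply(tpm, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("skipping pairs with constant expression vectors")
    tpm <- tpm[sds > 0, , drop = FALSE]
  }
  if (nrow(tpm) < 2L) return(NA_real_)
  cm <- stats::cor(t(tpm))
  min(cm[lower.tri(cm)])
}

#' Positional cross-correlation between CAGE and MNase 5'-end signal
#'
#' For each promoter, both tracks are extracted over the summit
#' +/- `half_window` in transcription-direction coordinates (minus-strand
#' windows are reversed), and the Pearson correlation between the CAGE
#' window and the MNase window shifted by each lag is computed. The
#' promoter's weight is the geometric mean of the two windows' total
#' signal; promoters with zero signal in either window are excluded.
#' Positive lags mean MNase signal downstream of the CAGE signal.
#'
#' @param summits data.frame with columns `chrom`, `summit`, `strand`.
#' @param cage,mnase Stranded tracks: data.frames with columns `chrom`,
#'   `pos`, `strand`, `score` (see [pooled_track()]).
#' @param half_window Half window width, bp (default 500).
#' @param max_lag Maximum lag, bp (default 250).
#' @return data.frame with `lag` (-max_lag..max_lag) and `r`, the
#'   weighted mean cross-correlation.
#' @export
mnase_cross_correlation <- function(summits, cage, mnase,
                                    half_window = 500, max_lag = 250) {
  lags <- -max_lag:max_lag
  wsum <- rsum <- numeric(length(lags))
  track_window <- function(track, chrom, strand, center) {
    sel <- track$chrom == chrom & track$strand == strand &
      track$pos >= center - half_window & track$pos <= center + half_window
    v <- numeric(2L * half_window + 1L)
    v[track$pos[sel] - (center - half_window) + 1L] <- track$score[sel]
    if (strand == "-") rev(v) else v
  }
  for (i in seq_len(nrow(summits))) {
    x <- track_window(cage, summits$chrom[i], summits$strand[i],
                      summits$summit[i])
    y <- track_window(mnase, summits$chrom[i], summits$strand[i],
                      summits$summit[i])
    if (sum(x) <= 0 || sum(y) <= 0) next
    w <- sqrt(sum(x) * sum(y))
    L <- length(x)
    for (k in seq_along(lags)) {
      tau <- lags[k]
      xi <- if (tau >= 0) seq_len(L - tau) else (1L - tau):L
      r <- suppressWarnings(stats::cor(x[xi], y[xi + tau]))
      if (!is.na(r)) {
        rsum[k] <- rsum[k] + w * r
        wsum[k] <- wsum[k] + w
      }
    }
  }
  if (all(wsum == 0)) stop("no promoter with signal in both windows")
  data.frame(lag = lags, r = rsum / pmax(wsum, .Machine$double.eps))
}
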