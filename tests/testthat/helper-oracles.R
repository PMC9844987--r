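# Independent brute-force reference implementations used as oracles.
# Deliberately naive: dense position walks, explicit loops, no shared code
# with the package internals.

# Local-maxima decomposition, coded directly from the stated rules.
oracle_decompose <- function(pos, pooled, min_sep = 20, frac_thr = 0.1,
                             max_gap = 10, smooth = 1, merge = 1) {
  o <- order(pos)
  pos <- pos[o]; pooled <- pooled[o]
  val <- function(p) {
    i <- which(pos == p)
    if (length(i)) pooled[i] else 0
  }
  # maxima: repeatedly take the strongest remaining CTSS (ties: leftmost),
  # discarding everything closer than min_sep to an accepted maximum
  remaining <- pos[pooled > 0]
  maxima <- integer(0)
  while (length(remaining)) {
    vals <- vapply(remaining, val, numeric(1))
    m <- min(remaining[vals == max(vals)])
    maxima <- c(maxima, m)
    remaining <- remaining[abs(remaining - m) >= min_sep]
  }
  claimed <- integer(0)
  dps <- list()
  for (m in maxima) {
    if (m %in% claimed) next
    t <- frac_thr * val(m)
    members <- m
    for (dir in c(1, -1)) {
      last_ret <- m
      p <- m + dir
      while (p >= min(pos) - max_gap - 1 && p <= max(pos) + max_gap + 1) {
        if (p %in% claimed) break
        if (val(p) >= t) {
          members <- c(members, p)
          last_ret <- p
        }
        if (abs(p - last_ret) > max_gap) break
        p <- p + dir
      }
    }
    extra <- integer(0)
    for (mm in members) {
      for (d in seq_len(smooth)) {
        for (q in c(mm - d, mm + d)) {
          if (val(q) > 0 && !(q %in% claimed) && !(q %in% members))
            extra <- c(extra, q)
        }
      }
    }
    members <- sort(unique(c(members, extra)))
    claimed <- c(claimed, members)
    dps[[length(dps) + 1]] <- members
  }
  if (!length(dps)) return(list())
  dps <- dps[order(sapply(dps, min))]
  out <- list(dps[[1]])
  for (d in dps[-1]) {
    prev <- out[[length(out)]]
    if (min(d) - max(prev) - 1 <= merge) {
      out[[length(out)]] <- sort(c(prev, d))
    } else {
      out[[length(out) + 1]] <- d
    }
  }
  out
}

# Running-median expected dispersion with explicit window enumeration and
# hand-rolled linear interpolation between anchors.
oracle_expected_dispersion <- function(mean_tpm, log_cv2, ids,
                                       width = 50, step = 25) {
  o <- order(mean_tpm, ids)
  lc <- log_cv2[o]
  n <- length(lc)
  if (n <= width) {
    res <- numeric(n)
    res[o] <- median(lc)
    return(res)
  }
  starts <- seq(1, n - width + 1, by = step)
  if (starts[length(starts)] != n - width + 1)
    starts <- c(starts, n - width + 1)
  ax <- ay <- numeric(length(starts))
  for (k in seq_along(starts)) {
    win <- lc[starts[k]:(starts[k] + width - 1)]
    ax[k] <- starts[k] + (width - 1) / 2
    ay[k] <- median(win)
  }
  exp_sorted <- numeric(n)
  for (r in seq_len(n)) {
    if (r <= ax[1]) {
      exp_sorted[r] <- ay[1]
    } else if (r >= ax[length(ax)]) {
      exp_sorted[r] <- ay[length(ay)]
    } else {
      k <- max(which(ax <= r))
      w <- (r - ax[k]) / (ax[k + 1] - ax[k])
      exp_sorted[r] <- (1 - w) * ay[k] + w * ay[k + 1]
    }
  }
  res <- numeric(n)
  res[o] <- exp_sorted
  res
}

# Random toy promoter: 1-4 planted peaks with random spacings and noise
# positions; returns pos / pooled vectors.
random_toy_promoter <- function() {
  n_peaks <- sample(1:4, 1)
  centers <- cumsum(c(100, sample(5:80, max(0, n_peaks - 1), replace = TRUE)))
  pos <- integer(0); pooled <- numeric(0)
  for (c0 in centers) {
    w <- sample(0:6, 1)
    pk <- c0 + (-w:w)
    v <- round(runif(length(pk), 1, 100) * exp(-abs(-w:w) / 2), 3)
    pos <- c(pos, pk); pooled <- c(pooled, v)
  }
  # sprinkle isolated weak CTSSs and zero positions
  extra <- sample(setdiff(90:(max(centers) + 40), pos),
                  sample(0:5, 1))
  pos <- c(pos, extra)
  pooled <- c(pooled, round(runif(length(extra), 0, 10), 3))
  keep <- !duplicated(pos)
  list(pos = pos[keep], pooled = pooled[keep])
}

# Small literal CTSS matrix builder for hand-traced fixtures.
toy_ctss <- function(pos, counts, chrom = "chr1", strand = "+") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  ctss_matrix(chrom, pos, strand, counts)
}

toy_meta <- function(samples, lib = 1e6) {
  library_meta(samples, rep_len(lib, length(samples)))
}
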