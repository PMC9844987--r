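# Promoter sequence features: CpG observed/expected ratio around the
# summit with high/low CpG status, and binary transcription-factor
# binding-site presence from predicted-site intervals.

#' CpG observed/expected ratio
#'
#' Gardiner-Garden normalization over a window of length `L`:
#' `obs/exp = count(CG) * L / (count(C) * count(G))`, case-insensitive;
#' ambiguous bases contribute to `L` only. Returns 0 when the window has no
#' C or no G.
#'
#' @param seq Character vector of window sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @return Numeric vector of observed/expected ratios.
#' @export
cpg_oe_ratio <- function(seq) {
  if (methods::is(seq, "DNAStringSet") || methods::is(seq, "DNAString"))
    seq <- as.character(seq)
  seq <- toupper(seq)
  if (any(nchar(seq) == 0)) stop("empty sequence")
  s <- Biostrings::DNAStringSet(seq)
  L <- Biostrings::width(s)
  C <- as.numeric(Biostrings::letterFrequency(s, "C"))
  G <- as.numeric(Biostrings::letterFrequency(s, "G"))
  CG <- Biostrings::vcountPattern("CG", s)
  ifelse(C == 0 | G == 0, 0, CG * L / (C * G))
}

#' High/low CpG status
#'
#' High CpG content iff the observed/expected ratio strictly exceeds the
#' threshold (bimodal CpG distributions separate around 0.5).
#'
#' @param ratio Numeric vector from [cpg_oe_ratio()].
#' @param threshold Strict threshold (default 0.5).
#' @return Logical vector: TRUE for high-CpG promoters.
#' @export
classify_cpg <- function(ratio, threshold = 0.5) {
  ratio > threshold
}

#' Sequence windows around promoter summits
#'
#' Extracts the +/- `flank` bp window (2*flank+1 bp) around each summit,
#' clipped at contig ends; actual window lengths are recorded.
#'
#' @param genome Named [Biostrings::DNAStringSet] (names are chromosome
#'   ids), e.g. from [Biostrings::readDNAStringSet()].
#' @param summits data.frame with columns `chrom`, `summit` and ideally an
#'   id column (`feature_id` or `id`) used to name the result.
#' @param flank Flank size, bp (default 500).
#' @return A `DNAStringSet` of windows with a `window_length` metadata
#'   column.
#' @export
summit_windows <- function(genome, summits, flank = 500) {
  idx <- match(summits$chrom, names(genome))
  if (anyNA(idx))
    stop("chromosomes missing from genome: ",
         paste(unique(summits$chrom[is.na(idx)]), collapse = ", "))
  len <- Biostrings::width(genome)[idx]
  start <- pmax(1L, summits$summit - flank)
  end <- pmin(len, summits$summit + flank)
  out <- Biostrings::subseq(genome[idx], start, end)
  ids <- summits$feature_id
  if (is.null(ids)) ids <- summits$id
  if (is.null(ids)) ids <- seq_len(nrow(summits))
  names(out) <- ids
  S4Vectors::mcols(out)$window_length <- end - start + 1L
  out
}

#' Transcription-factor binding-site presence
#'
#' Binary presence/absence of predicted TF binding sites per promoter:
#' entry 1 iff at least one site interval of that TF overlaps the promoter
#' extent by at least 1 bp (strand-agnostic: predicted sites act on
#' double-stranded DNA). With `mode = "count"`, non-overlapping sites are
#' counted per TF by greedy left-to-right selection instead.
#'
#' @param promoters data.frame with columns `id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param sites data.frame of predicted sites with columns `chrom`,
#'   `start`, `end`, `name` (TF identifier) and optionally `score` (see
#'   [read_bed6()]).
#' @param min_score Minimum site score, applied when scores are present
#'   (default 500).
#' @param mode `"presence"` (default) or `"count"`.
#' @return Integer matrix, promoters x TFs.
#' @export
tf_site_presence <- function(promoters, sites, min_score = 500,
                             mode = c("presence", "count")) {
  mode <- match.arg(mode)
  if (!is.null(sites$score) && !all(is.na(sites$score)))
    sites <- sites[is.na(sites$score) | sites$score >= min_score, ,
                   drop = FALSE]
  tfs <- sort(unique(sites$name))
  out <- matrix(0L, nrow(promoters), length(tfs),
                dimnames = list(promoters$id, tfs))
  if (!nrow(sites) || !nrow(promoters)) return(out)
  prom_gr <- GenomicRanges::GRanges(
    promoters$chrom, IRanges::IRanges(promoters$start, promoters$end))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start, sites$end))
  hits <- GenomicRanges::findOverlaps(prom_gr, site_gr, ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (mode == "presence") {
    out[cbind(pi, match(sites$name[si], tfs))] <- 1L
  } else {
    for (key in split(seq_along(pi), paste(pi, sites$name[si]))) {
      p <- pi[key[1L]]
      tf <- sites$name[si[key[1L]]]
      iv <- sites[si[key], c("start", "end")]
      iv <- iv[order(iv$start, iv$end), , drop = FALSE]
      n <- 0L; last_end <- -Inf
      for (j in seq_len(nrow(iv))) {
        if (iv$start[j] > last_end) {
          n <- n + 1L
          last_end <- iv$end[j]
        }
      }
      out[p, tf] <- n
    }
  }
  out
}

#' Sequence feature table for a promoter set
#'
#' CpG observed/expected ratio and high-CpG status in +/- `flank` bp
#' windows around summits, plus (optionally) TF-site presence.
#'
#' @param proms A `promoter_set` with summits.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param sites Optional predicted-site data.frame (see
#'   [tf_site_presence()]).
#' @param flank CpG window flank, bp (default 500).
#' @param min_score Minimum site score (default 500).
#' @return data.frame with `feature_id`, `cpg_oe`, `cpg_high` and one
#'   binary column per TF.
#' @export
sequence_features <- function(proms, genome, sites = NULL, flank = 500,
                              min_score = 500) {
  cl <- proms$clusters
  win <- summit_windows(genome,
                        data.frame(chrom = cl$chrom, summit = cl$summit,
                                   feature_id = cl$id), flank)
  ratio <- cpg_oe_ratio(win)
  out <- data.frame(feature_id = cl$id, cpg_oe = ratio,
                    cpg_high = classify_cpg(ratio),
                    stringsAsFactors = FALSE)
  if (!is.null(sites)) {
    pres <- tf_site_presence(
      data.frame(id = cl$id, chrom = cl$chrom, start = cl$start,
                 end = cl$end), sites, min_score)
    out <- cbind(out, as.data.frame(pres))
  }
  out
}
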