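# File interchange: long-format CTSS TSV, stranded per-sample bedGraph,
# BED6, minimal VCF with GT genotypes, and matrix TSVs. Coordinates are
# 1-based inclusive internally; BED and bedGraph exports are 0-based
# half-open (handled by rtracklayer's GRanges conversion).

#' Read and write CTSS tables in long TSV format
#'
#' The long format has one row per (chrom, pos, strand, sample) with a
#' positive count; columns `chrom`, `pos` (1-based), `strand`, `sample`,
#' `count`. Zero counts are omitted on write and implied on read.
#'
#' @param ctss A [ctss_matrix()].
#' @param path File path.
#' @param samples Optional character vector fixing the sample set/order on
#'   read (samples absent from the file get all-zero counts).
#' @return `write_ctss_tsv` returns `path` invisibly; `read_ctss_tsv`
#'   returns a [ctss_matrix()].
#' @export
write_ctss_tsv <- function(ctss, path) {
  cnt <- ctss$counts
  idx <- which(cnt > 0, arr.ind = TRUE)
  long <- data.frame(ctss$info[idx[, 1L], , drop = FALSE],
                     sample = colnames(cnt)[idx[, 2L]],
                     count = cnt[idx],
                     stringsAsFactors = FALSE)
  long <- long[order(long$chrom, long$strand, long$pos, long$sample), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ctss_tsv
#' @export
read_ctss_tsv <- function(path, samples = NULL) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "sample", "count")
  if (!all(need %in% names(long)))
    stop("CTSS TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(samples)) samples <- sort(unique(long$sample))
  key <- paste(long$chrom, long$strand, long$pos)
  ukey <- !duplicated(key)
  cnt <- matrix(0, sum(ukey), length(samples),
                dimnames = list(NULL, samples))
  ri <- match(key, key[ukey])
  ci <- match(long$sample, samples)
  if (anyNA(ci)) stop("samples in file not in `samples`: ",
                      paste(unique(long$sample[is.na(ci)]), collapse = ", "))
  cnt[cbind(ri, ci)] <- cnt[cbind(ri, ci)] + long$count
  ctss_matrix(long$chrom[ukey], long$pos[ukey], long$strand[ukey], cnt)
}

#' Read and write per-sample stranded CTSS bedGraph tracks
#'
#' One pair of files per sample, `<sample>.plus.bedGraph` and
#' `<sample>.minus.bedGraph`, each a standard 0-based half-open bedGraph of
#' single-bp intervals. Zero-count positions are omitted.
#'
#' @param ctss A [ctss_matrix()].
#' @param dir Directory for the track files (created if needed).
#' @return `write_ctss_bedgraph` returns the written paths invisibly;
#'   `read_ctss_bedgraph` returns a [ctss_matrix()] over the union of
#'   positions found in the files.
#' @export
write_ctss_bedgraph <- function(ctss, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in ctss_samples(ctss)) {
    for (str in c("+", "-")) {
      keep <- ctss$info$strand == str & ctss$counts[, s] > 0
      path <- file.path(dir, paste0(
        s, if (str == "+") ".plus.bedGraph" else ".minus.bedGraph"))
      gr <- GenomicRanges::GRanges(
        ctss$info$chrom[keep],
        IRanges::IRanges(ctss$info$pos[keep], width = 1L),
        score = unname(ctss$counts[keep, s]))
      rtracklayer::export(gr, path, format = "bedGraph")
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' @rdname write_ctss_bedgraph
#' @export
read_ctss_bedgraph <- function(dir) {
  files <- list.files(dir, pattern = "\\.(plus|minus)\\.bedGraph$",
                      full.names = TRUE)
  if (!length(files)) stop("no *.plus/minus.bedGraph files in ", dir)
  base <- basename(files)
  sample <- sub("\\.(plus|minus)\\.bedGraph$", "", base)
  strand <- ifelse(grepl("\\.plus\\.bedGraph$", base), "+", "-")
  samples <- sort(unique(sample))
  recs <- vector("list", length(files))
  for (i in seq_along(files)) {
    gr <- rtracklayer::import(files[i], format = "bedGraph")
    if (!length(gr)) next
    # expand intervals to single-bp records
    pos <- unlist(mapply(seq, GenomicRanges::start(gr), GenomicRanges::end(gr),
                         SIMPLIFY = FALSE))
    score <- rep(gr$score, GenomicRanges::width(gr))
    recs[[i]] <- data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::width(gr)),
      pos = pos, strand = strand[i], sample = sample[i], count = score,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, recs)
  if (is.null(long)) stop("bedGraph files contain no records")
  key <- paste(long$chrom, long$strand, long$pos)
  ukey <- !duplicated(key)
  cnt <- matrix(0, sum(ukey), length(samples), dimnames = list(NULL, samples))
  cnt[cbind(match(key, key[ukey]), match(long$sample, samples))] <- long$count
  ctss_matrix(long$chrom[ukey], long$pos[ukey], long$strand[ukey], cnt)
}

#' Read and write BED6
#'
#' Internal coordinates are 1-based inclusive; files are 0-based half-open.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `name`,
#'   optionally `score` and `strand`.
#' @param path File path.
#' @return `read_bed6` returns a data.frame with 1-based inclusive `start`
#'   and `end`; `write_bed6` returns `path` invisibly.
#' @export
write_bed6 <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start, x$end),
    strand = if (is.null(x$strand)) "*" else x$strand)
  gr$name <- x$name
  gr$score <- if (is.null(x$score)) 0 else x$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path,
                                          "': ", conditionMessage(e)))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (is.null(gr$name)) NA_character_ else gr$name,
    score = if (is.null(gr$score)) NA_real_ else gr$score,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Convert a BED6 annotation to a TSS table
#'
#' The transcription start site of each record is its 5' end: `start` on the
#' plus strand, `end` on the minus strand (1-based inclusive coordinates).
#'
#' @param bed data.frame as returned by [read_bed6()].
#' @return data.frame with columns `chrom`, `tss`, `strand`, `gene`.
#' @export
annotation_from_bed <- function(bed) {
  if (!all(bed$strand %in% c("+", "-")))
    stop("annotation records must be stranded")
  data.frame(chrom = bed$chrom,
             tss = ifelse(bed$strand == "+", bed$start, bed$end),
             strand = bed$strand,
             gene = bed$name,
             stringsAsFactors = FALSE)
}

#' Write genotypes as a minimal VCF v4.2 with GT fields
#'
#' Emits biallelic records with unphased genotypes `0/0`, `0/1`, `1/1`
#' (missing dosage as `./.`). Plain text, suitable for re-reading with any
#' VCF parser.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  info <- geno$info
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(geno$dosage), ncol(geno$dosage))
  ok <- !is.na(geno$dosage)
  gt[ok] <- gt_codes[geno$dosage[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=promvar",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno$dosage)), collapse = "\t"))
  body <- paste(info$chrom, info$pos, info$snp_id, info$ref, info$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Extracts GT fields from biallelic SNV records and converts them to
#' alt-allele dosages in `{0, 1, 2}` (missing as `NA`). Multi-allelic
#' records are dropped with a message.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L &
    nchar(fix$ALT) == 1L
  if (!all(biallelic))
    message("dropping ", sum(!biallelic), " non-biallelic-SNV records")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("[|]", "/", gt)
  dose[clean == "0/0"] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean == "1/1"] <- 2
  genotype_matrix(
    info = data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, stringsAsFactors = FALSE),
    dosage = dose)
}

#' Read and write feature-by-sample matrices as TSV
#'
#' @param m Numeric matrix with feature row names and sample column names.
#' @param path File path.
#' @param id_col Name of the first (feature id) column.
#' @return `read_matrix_tsv` returns a matrix; `write_matrix_tsv` returns
#'   `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
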