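# cis-QTL mapping for three response types: promoter expression (prQTL),
# decomposed-promoter expression (dprQTL) and decomposed-promoter usage
# fraction (frQTL). Additive per-test OLS on alt-allele dosage with
# covariates, BH FDR, lead-SNP selection, relative effect sizes, and
# detection of expression-stabilizing fraction QTLs.

#' Genotype dosage matrix
#'
#' @param info data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per biallelic SNV).
#' @param dosage Numeric matrix (SNPs x samples) of alt-allele dosages in
#'   `{0, 1, 2}`; `NA` marks missing genotypes. Minor allele frequency is
#'   recomputed from non-missing samples.
#' @return An object of class `genotype_matrix` with an added `maf` column.
#' @export
genotype_matrix <- function(info, dosage) {
  dosage <- as.matrix(dosage)
  if (nrow(info) != nrow(dosage))
    stop("info rows and dosage rows must match")
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stop("dosages must be 0, 1, 2 or NA (biallelic only)")
  f <- rowMeans(dosage, na.rm = TRUE) / 2
  info$maf <- pmin(f, 1 - f)
  rownames(dosage) <- info$snp_id
  out <- list(info = info, dosage = dosage)
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotypes:", nrow(x$dosage), "SNVs x", ncol(x$dosage), "samples;",
      "MAF range", sprintf("%.3f-%.3f", min(x$info$maf), max(x$info$maf)),
      "\n")
  invisible(x)
}

#' Fractional contribution of decomposed promoters
#'
#' `fraction = decomposed TPM / parent TPM` per sample; samples where the
#' parent has zero TPM get fraction 0 and are counted in the
#' `n_zero_parent` attribute.
#'
#' @param dp_tpm Decomposed-promoter TPM matrix (rows: decomposed
#'   promoters).
#' @param parent_tpm Parent TPM matrix, row-aligned with `dp_tpm` (row i of
#'   `parent_tpm` is the parent of row i of `dp_tpm`).
#' @return Fraction matrix in `[0, 1]` with attribute `n_zero_parent`.
#' @export
compute_fractions <- function(dp_tpm, parent_tpm) {
  if (!identical(dim(dp_tpm), dim(parent_tpm)) ||
      !identical(colnames(dp_tpm), colnames(parent_tpm)))
    stop("mismatched sample sets between decomposed and parent matrices")
  zero <- parent_tpm == 0
  frac <- ifelse(zero, 0, dp_tpm / ifelse(zero, 1, parent_tpm))
  rownames(frac) <- rownames(dp_tpm)
  attr(frac, "n_zero_parent") <- sum(zero)
  frac
}

#' Expression principal components
#'
#' Scores of the top `k` principal components of the samples-by-features
#' TPM matrix (features centered), used as prQTL covariates to absorb
#' broad expression structure.
#'
#' @param tpm Features x samples TPM matrix.
#' @param k Number of components (default 5).
#' @return Samples x `k` score matrix (columns `PC1..PCk`).
#' @export
expression_pcs <- function(tpm, k = 5) {
  if (k >= ncol(tpm)) stop("k must be smaller than the number of samples")
  pr <- stats::prcomp(t(tpm), center = TRUE, scale. = FALSE)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- colnames(tpm)
  scores
}

#' Covariate matrix from sample metadata
#'
#' One-hot encodes population and batch labels (first level dropped) and
#' appends optional numeric covariates such as expression PCs.
#' Single-level factors are dropped with a warning.
#'
#' @param meta A [library_meta()] table (or any data.frame with optional
#'   `population` and `batch` columns), ordered as the samples.
#' @param pcs Optional numeric matrix of per-sample covariates.
#' @return Numeric samples x p matrix, or NULL if no covariate remains.
#' @export
make_covariates <- function(meta, pcs = NULL) {
  blocks <- list()
  for (col in c("population", "batch")) {
    if (is.null(meta[[col]])) next
    f <- factor(meta[[col]])
    if (nlevels(f) < 2L) {
      warning("covariate '", col, "' has a single level; dropped")
      next
    }
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(col, levels(f)[-1L])
    blocks[[col]] <- mm
  }
  if (!is.null(pcs)) blocks$pcs <- as.matrix(pcs)
  if (!length(blocks)) return(NULL)
  do.call(cbind, blocks)
}

# Single additive OLS: response on dosage + covariates + intercept.
# Returns beta, se, t, p for the dosage coefficient.
fit_dosage_ols <- function(y, d, Z = NULL) {
  X <- cbind(`(Intercept)` = 1, dosage = d, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  df <- length(y) - ncol(X)
  if (df < 1L) stop("not enough samples for the design (need n > p + 1)")
  V <- chol2inv(chol(crossprod(X)))
  beta <- drop(V %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(V))
  t <- beta / se
  c(beta = beta[2L], se = se[2L], t = t[2L],
    p = 2 * stats::pt(-abs(t[2L]), df))
}

#' Map cis QTLs
#'
#' For every feature x SNV pair with the SNV within `window` bp of the
#' feature's summit and MAF at least `min_maf`, fits ordinary least squares
#' of the response on alt-allele dosage plus covariates and an intercept.
#' Samples with missing dosage are dropped per test. P-values come from the
#' t distribution; q-values are Benjamini-Hochberg across all tests of the
#' run (`fdr_mode = "all_tests"`, the MatrixEQTL convention) or across
#' per-feature minimum p-values (`"lead_per_feature"`).
#'
#' @param response Features x samples numeric matrix (TPM for
#'   promoter/decomposed expression, fractions for frQTLs) with feature row
#'   names.
#' @param summits data.frame row-aligned with `response`: columns
#'   `feature_id`, `chrom`, `summit` and optionally `parent_id` (carried
#'   through for fraction QTLs).
#' @param geno A [genotype_matrix()] with the same samples (same order).
#' @param covariates Optional samples x p numeric matrix
#'   (see [make_covariates()]).
#' @param window Maximum SNV-summit distance, bp (default 25000).
#' @param min_maf Minimum minor allele frequency (default 0.10).
#' @param kind Label stored in the results: `"promoter"`, `"decomposed"` or
#'   `"fraction"`.
#' @param fdr_mode FDR family; see above.
#' @return data.frame of class `qtl_result`: `feature_id`, `kind`,
#'   `snp_id`, `chrom`, `pos`, `distance`, `beta`, `se`, `t`, `p`, `q`
#'   (and `parent_id` if supplied). Features with no testable SNV are
#'   skipped with a message.
#' @export
map_cis_qtl <- function(response, summits, geno, covariates = NULL,
                        window = 25000, min_maf = 0.10,
                        kind = c("promoter", "decomposed", "fraction"),
                        fdr_mode = c("all_tests", "lead_per_feature")) {
  kind <- match.arg(kind)
  fdr_mode <- match.arg(fdr_mode)
  if (ncol(response) != ncol(geno$dosage))
    stop("response and genotype sample counts differ")
  if (nrow(summits) != nrow(response))
    stop("summits must be row-aligned with the response matrix")
  if (!is.null(covariates) && nrow(covariates) != ncol(response))
    stop("covariates must have one row per sample")
  ok_maf <- geno$info$maf >= min_maf
  res <- vector("list", nrow(response))
  skipped <- 0L
  for (i in seq_len(nrow(response))) {
    snps <- which(ok_maf & geno$info$chrom == summits$chrom[i] &
                    abs(geno$info$pos - summits$summit[i]) <= window)
    if (!length(snps)) { skipped <- skipped + 1L; next }
    y_all <- response[i, ]
    fits <- matrix(NA_real_, length(snps), 4L,
                   dimnames = list(NULL, c("beta", "se", "t", "p")))
    for (k in seq_along(snps)) {
      d <- geno$dosage[snps[k], ]
      use <- !is.na(d)
      Z <- if (is.null(covariates)) NULL
           else covariates[use, , drop = FALSE]
      fits[k, ] <- fit_dosage_ols(y_all[use], d[use], Z)
    }
    res[[i]] <- data.frame(
      feature_id = summits$feature_id[i], kind = kind,
      snp_id = geno$info$snp_id[snps], chrom = geno$info$chrom[snps],
      pos = geno$info$pos[snps],
      distance = geno$info$pos[snps] - summits$summit[i],
      fits, stringsAsFactors = FALSE)
    if (!is.null(summits$parent_id))
      res[[i]]$parent_id <- summits$parent_id[i]
  }
  if (skipped) message(skipped, " feature(s) without a testable cis SNV")
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable feature x SNV pair")
  if (fdr_mode == "all_tests") {
    out$q <- bh_fdr(out$p)
  } else {
    lead_p <- tapply(out$p, out$feature_id, min)
    lead_q <- stats::setNames(bh_fdr(as.numeric(lead_p)), names(lead_p))
    out$q <- unname(lead_q[out$feature_id])
  }
  rownames(out) <- NULL
  class(out) <- c("qtl_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment; `m` may exceed the number of p-values when only a
#' subset of a larger family is supplied.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size (default `length(p)`).
#' @return q-values, capped at 1.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Lead SNP per feature
#'
#' The most significant association per feature; ties broken by larger
#' `|beta|`, then smaller `|distance|`, then `snp_id`.
#'
#' @param results A `qtl_result` data.frame.
#' @return One row per feature.
#' @export
lead_snp <- function(results) {
  o <- order(results$feature_id, results$p, -abs(results$beta),
             abs(results$distance), results$snp_id)
  out <- results[o, ][!duplicated(results$feature_id[o]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative effect size of a SNP on promoter expression
#'
#' Maximal relative change in mean expression between the reference-
#' homozygote group and the other genotype groups:
#' `max_g |mean_g - mean_0| / mean_0` over `g` in {1, 2}. Groups with fewer
#' than `min_group` samples are excluded; if the dosage-0 group is too
#' small or has zero mean the value is undefined (NA).
#'
#' @param tpm Per-sample promoter TPM (numeric vector).
#' @param dosage Per-sample alt-allele dosage in `{0, 1, 2}`.
#' @param min_group Minimum samples per genotype group (default 3).
#' @return Relative effect size (>= 0), or NA when undefined.
#' @export
relative_effect_size <- function(tpm, dosage, min_group = 3) {
  use <- !is.na(dosage)
  tpm <- tpm[use]; dosage <- dosage[use]
  n0 <- sum(dosage == 0)
  if (n0 < min_group) return(NA_real_)
  m0 <- mean(tpm[dosage == 0])
  if (m0 <= 0) return(NA_real_)
  rel <- c()
  for (g in 1:2) {
    if (sum(dosage == g) >= min_group)
      rel <- c(rel, abs(mean(tpm[dosage == g]) - m0) / m0)
  }
  if (!length(rel)) return(NA_real_)
  max(rel)
}

#' Detect expression-stabilizing fraction QTLs
#'
#' A promoter is flagged stabilizing when one SNP is significantly
#' associated (q <= `q_thr`) with the usage fractions of at least two of
#' its decomposed promoters with effects of strictly opposite sign: the
#' variant switches TSS usage within the promoter while buffering total
#' output.
#'
#' @param results Fraction-QTL `qtl_result` with a `parent_id` column.
#' @param q_thr FDR threshold (default 0.05).
#' @return Character vector of stabilizing parent promoter ids.
#' @export
detect_stabilizing_frqtl <- function(results, q_thr = 0.05) {
  if (is.null(results$parent_id))
    stop("fraction-QTL results must carry a parent_id column")
  sig <- results[results$q <= q_thr, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  key <- paste(sig$parent_id, sig$snp_id)
  flag <- vapply(split(seq_len(nrow(sig)), key), function(idx) {
    b <- sig$beta[idx]
    length(unique(sig$feature_id[idx])) >= 2L && any(b > 0) && any(b < 0)
  }, logical(1))
  sort(unique(sig$parent_id[match(names(flag)[flag], key)]))
}
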