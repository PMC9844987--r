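# Expression variability: squared coefficient of variation of TPM across
# individuals, expected dispersion at a given mean from a running median,
# expression-adjusted dispersion, and variability classes.

#' CV-squared of an expression vector
#'
#' Raw dispersion: `cv2 = var(x) / mean(x)^2` with the n-1 variance
#' denominator, and its log10 transform. Constant vectors (cv2 = 0) are
#' valid input but are flagged downstream and excluded from the
#' running-median adjustment, since log10(0) is undefined.
#'
#' @param tpm Numeric vector of per-sample TPM (length >= 2, positive mean).
#' @return list with `mean`, `cv2`, `log_cv2` (NA when cv2 is 0).
#' @export
compute_cv2 <- function(tpm) {
  if (length(tpm) < 2L) stop("need >= 2 samples")
  m <- mean(tpm)
  if (m <= 0) stop("mean expression must be > 0 (all-zero feature?)")
  cv2 <- stats::var(tpm) / m^2
  list(mean = m, cv2 = cv2,
       log_cv2 = if (cv2 > 0) log10(cv2) else NA_real_)
}

#' Dispersion table for a TPM matrix
#'
#' @param tpm Features x samples TPM matrix with feature row names.
#' @return data.frame with one row per feature: `feature_id`, `mean_tpm`,
#'   `cv2`, `log_cv2` (NA and a warning for constant features).
#' @export
dispersion_table <- function(tpm) {
  if (is.null(rownames(tpm))) rownames(tpm) <- seq_len(nrow(tpm))
  m <- rowMeans(tpm)
  if (any(m <= 0))
    stop("features with non-positive mean expression: ",
         paste(utils::head(rownames(tpm)[m <= 0]), collapse = ", "))
  v <- apply(tpm, 1L, stats::var)
  cv2 <- v / m^2
  if (any(cv2 == 0))
    warning(sum(cv2 == 0), " constant feature(s) flagged (cv2 = 0); ",
            "excluded from dispersion adjustment")
  data.frame(feature_id = rownames(tpm), mean_tpm = m, cv2 = cv2,
             log_cv2 = ifelse(cv2 > 0, log10(cv2), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected dispersion from a running median over mean expression
#'
#' Orders features by mean TPM (ties broken by feature id) and slides
#' windows of `width` consecutive features, starting every `step` features;
#' if the last full window does not end at the final feature, one extra
#' window over the trailing `width` features is added. Each window
#' contributes an anchor at its median rank with value the median log10 CV2
#' of its members. A feature's expected dispersion is linearly interpolated
#' between flanking anchors on the rank axis, with constant extrapolation
#' beyond the outer anchors. Fewer features than `width` yield a single
#' global-median window.
#'
#' @param disp data.frame from [dispersion_table()].
#' @param width Window size in features (default 50).
#' @param step Stride between window starts in features (default 25).
#' @return `disp` with an `expected_log_cv2` column (NA for cv2 = 0
#'   features, which also do not contribute to the windows).
#' @export
expected_dispersion <- function(disp, width = 50, step = 25) {
  if (width < 2) stop("width must be >= 2")
  if (step < 1) stop("step must be >= 1")
  use <- which(!is.na(disp$log_cv2))
  disp$expected_log_cv2 <- NA_real_
  if (!length(use)) return(disp)
  o <- use[order(disp$mean_tpm[use], disp$feature_id[use])]
  lc <- disp$log_cv2[o]
  n <- length(o)
  if (n <= width) {
    disp$expected_log_cv2[o] <- stats::median(lc)
    return(disp)
  }
  starts <- seq(1L, n - width + 1L, by = step)
  if (starts[length(starts)] != n - width + 1L)
    starts <- c(starts, n - width + 1L)
  anchor_rank <- starts + (width - 1) / 2
  anchor_val <- vapply(starts, function(s)
    stats::median(lc[s:(s + width - 1L)]), numeric(1))
  expected <- if (length(starts) == 1L) rep(anchor_val, n) else
    stats::approx(anchor_rank, anchor_val, xout = seq_len(n),
                  rule = 2)$y
  disp$expected_log_cv2[o] <- expected
  disp
}

#' Expression-adjusted dispersion
#'
#' `adjusted = log10 CV2 - expected log10 CV2`, removing the mean-variance
#' dependence so that variability is comparable across expression levels.
#'
#' @param disp data.frame with `log_cv2` and `expected_log_cv2`.
#' @return `disp` with an `adjusted` column.
#' @export
adjust_dispersion <- function(disp) {
  if (is.null(disp$expected_log_cv2))
    stop("expected dispersion must be computed first (expected_dispersion)")
  disp$adjusted <- disp$log_cv2 - disp$expected_log_cv2
  disp
}

#' Variability classes and training labels
#'
#' Assigns quartile classes from the empirical quartiles of the adjusted
#' dispersion (`<= Q1`, `(Q1, Q2]`, `(Q2, Q3]`, `> Q3`), and low/high
#' training labels from fixed thresholds: low iff `adjusted <= low_thr`,
#' high iff `adjusted > high_thr`, otherwise unlabeled.
#'
#' @param disp data.frame with an `adjusted` column.
#' @param low_thr Threshold for low-variability label (default -0.20).
#' @param high_thr Threshold for high-variability label (default 0.25).
#' @return `disp` with `variability_class` (factor Q1_low..Q4_high) and
#'   `label` (low/high/unlabeled) columns.
#' @export
classify_variability <- function(disp, low_thr = -0.20, high_thr = 0.25) {
  if (is.null(disp$adjusted))
    stop("adjusted dispersion must be computed first (adjust_dispersion)")
  a <- disp$adjusted
  qs <- stats::quantile(a, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  cls <- rep(NA_character_, length(a))
  ok <- !is.na(a)
  cls[ok & a <= qs[1]] <- "Q1_low"
  cls[ok & a > qs[1] & a <= qs[2]] <- "Q2"
  cls[ok & a > qs[2] & a <= qs[3]] <- "Q3"
  cls[ok & a > qs[3]] <- "Q4_high"
  disp$variability_class <- factor(cls, c("Q1_low", "Q2", "Q3", "Q4_high"))
  lab <- rep("unlabeled", length(a))
  lab[ok & a <= low_thr] <- "low"
  lab[ok & a > high_thr] <- "high"
  lab[!ok] <- NA_character_
  disp$label <- lab
  disp
}

#' Full dispersion analysis of a TPM matrix
#'
#' Runs [dispersion_table()], [expected_dispersion()],
#' [adjust_dispersion()] and [classify_variability()] in sequence.
#'
#' @inheritParams dispersion_table
#' @inheritParams expected_dispersion
#' @inheritParams classify_variability
#' @return The complete dispersion data.frame.
#' @export
promoter_dispersion <- function(tpm, width = 50, step = 25,
                                low_thr = -0.20, high_thr = 0.25) {
  disp <- dispersion_table(tpm)
  disp <- expected_dispersion(disp, width, step)
  disp <- adjust_dispersion(disp)
  classify_variability(disp, low_thr, high_thr)
}
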