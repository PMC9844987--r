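# Synthetic CAGE panel generator with planted ground truth. Emulates a
# ~100-individual LCL panel: promoters with 1-4 core promoters, per-CTSS
# negative-binomial count noise whose CV2 decreases with mean expression,
# Hardy-Weinberg genotypes, and planted expression / fraction /
# compensatory-switch QTL effects. Every downstream stage of the pipeline
# can be validated against the returned truth tables.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a 108-individual LCL CAGE
#' panel. Latent per-promoter mean expression (log10 TPM) is uniform over
#' `mean_log_expression` +/- `log10_range / 2`, so that the default span is
#' three orders of magnitude; per-sample biological variation adds Normal
#' noise with sd `between_sample_sd` on log10 expression, shared across
#' cores unless `core_noise_sd > 0` decorrelates core usage. CTSS counts
#' around each core center follow a discretized Gaussian (truncated at
#' +/- 4 sd) and negative-binomial sampling with size `nb_size`
#' (`Inf` = Poisson).
#'
#' @param n_samples Number of individuals (>= 8; default 108).
#' @param n_promoters Number of promoters (default 100).
#' @param cores_per_promoter Probability weights for 1-4 core promoters
#'   per promoter.
#' @param core_offsets Spacing between adjacent core centers, bp
#'   (default 40).
#' @param positional_sd Positional sd of CTSSs around a core center, bp;
#'   0 gives a sharp single-bp core (default 2).
#' @param mean_log_expression Center of the promoter mean log10 TPM
#'   distribution (default 1).
#' @param log10_range Total span of promoter mean log10 TPM (default 3).
#' @param between_sample_sd Per-sample sd of log10 total expression
#'   (default 0.15).
#' @param core_noise_sd Per-core, per-sample log-scale noise decorrelating
#'   core usage (default 0 = cores covary fully).
#' @param nb_size Negative-binomial size; `Inf` gives Poisson counts
#'   (default 2).
#' @param library_size Mapped reads per sample (default 2e6).
#' @param maf Alt-allele frequency of simulated SNVs in (0, 0.5]
#'   (default 0.3).
#' @param n_snps_per_promoter cis SNVs per promoter (default 3).
#' @param qtl_effects List of [planted_effect()]s.
#' @param seed Integer seed; identical seeds give byte-identical panels.
#' @param deterministic If TRUE, counts are the exact expected values
#'   (possibly fractional) instead of random draws; a zero-noise mode used
#'   to verify ground-truth recovery.
#' @param chrom Chromosome name (default "chrS1").
#' @param promoter_spacing Distance between promoter centers, bp; the
#'   default 60 kb keeps 25 kb cis windows disjoint.
#' @param frac_shape Dirichlet (gamma) shape for baseline core fractions.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 108, n_promoters = 100,
                       cores_per_promoter = c(0.45, 0.30, 0.15, 0.10),
                       core_offsets = 40, positional_sd = 2,
                       mean_log_expression = 1, log10_range = 3,
                       between_sample_sd = 0.15, core_noise_sd = 0,
                       nb_size = 2, library_size = 2e6, maf = 0.3,
                       n_snps_per_promoter = 3, qtl_effects = list(),
                       seed = 1, deterministic = FALSE, chrom = "chrS1",
                       promoter_spacing = 60000, frac_shape = 5) {
  cfg <- as.list(environment())
  if (n_samples < 8) stop("n_samples must be >= 8")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (core_offsets < 0 || positional_sd < 0 || promoter_spacing < 0)
    stop("spacings must be >= 0")
  if (nb_size <= 0) stop("nb_size must be > 0 (Inf for Poisson)")
  if (library_size <= 0) stop("library_size must be > 0")
  if (length(cores_per_promoter) != 4 || any(cores_per_promoter < 0))
    stop("cores_per_promoter must be 4 non-negative weights")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Independent `Binomial(2, maf)` draws per sample and SNV.
#'
#' @param n_samples Number of samples.
#' @param maf Alt-allele frequency in (0, 0.5].
#' @param n_snps Number of SNVs.
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return Integer dosage matrix, SNVs x samples.
#' @export
simulate_genotypes <- function(n_samples, maf, n_snps, seed = NULL) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rbinom(n_snps * n_samples, 2L, maf), n_snps, n_samples)
}

#' A planted QTL effect
#'
#' Effect of one SNV on one promoter. `expression` effects add
#' `beta * dosage` to each sample's log10 total promoter expression;
#' `fraction` effects add `beta * dosage` on the logit scale to the target
#' core's usage fraction (other cores rescaled); `compensatory_switch`
#' effects apply `+beta` and `-beta` (logit scale) to two target cores,
#' switching usage between them while leaving total promoter expression
#' invariant by construction.
#'
#' @param promoter Promoter id (e.g. `"prom_001"`) or index.
#' @param kind `"expression"`, `"fraction"` or `"compensatory_switch"`.
#' @param beta Effect per alt allele (log10 scale for expression, logit
#'   scale for fraction kinds).
#' @param cores Target core indices (fraction: 1; compensatory_switch: 2).
#' @param snp SNP id; defaults to the promoter's first cis SNV.
#' @return list of class `planted_effect`.
#' @export
planted_effect <- function(promoter, kind = c("expression", "fraction",
                                              "compensatory_switch"),
                           beta, cores = 1L, snp = NULL) {
  kind <- match.arg(kind)
  if (kind == "compensatory_switch" && length(cores) < 2)
    stop("compensatory_switch must target at least 2 cores")
  structure(list(promoter = promoter, kind = kind, beta = beta,
                 cores = as.integer(cores), snp = snp),
            class = "planted_effect")
}

#' Simulate latent panel truth
#'
#' Draws the latent state of a panel: promoter/core geometry, baseline core
#' fractions, per-sample log10 total expression and core fractions, and
#' cis genotypes. Planted QTL effects in the configuration are applied via
#' [plant_qtl_effects()] by [simulate_panel()]; calling this directly
#' yields an effect-free truth.
#'
#' @param config A [sim_config()].
#' @return list of class `sim_truth` with elements `promoters`, `cores`,
#'   `samples`, `log10_total` (promoters x samples), `fractions`
#'   (core rows x samples, summing to 1 within each promoter),
#'   `genotypes` (a [genotype_matrix()] whose info carries `promoter_id`),
#'   and `effects` (initially empty).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  np <- config$n_promoters
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    library_size = config$library_size,
    batch = rep_len(c("batch1", "batch2"), n),
    population = rep(c("popA", "popB"), each = ceiling(n / 2))[seq_len(n)],
    stringsAsFactors = FALSE)
  promoter_id <- sprintf("prom_%03d", seq_len(np))
  center <- 50000L + (seq_len(np) - 1L) * as.integer(config$promoter_spacing)
  strand <- rep_len(c("+", "-"), np)
  n_cores <- integer(np)
  cores <- list()
  log10_total <- matrix(NA_real_, np, n,
                        dimnames = list(promoter_id, samples$sample_id))
  fr_rows <- list()
  geno_info <- list()
  geno_dose <- list()
  half <- config$log10_range / 2
  for (p in seq_len(np)) {
    n_cores[p] <- sample.int(4L, 1L, prob = config$cores_per_promoter)
    centers <- center[p] + (seq_len(n_cores[p]) - 1L) *
      as.integer(config$core_offsets)
    w <- stats::rgamma(n_cores[p], shape = config$frac_shape)
    w <- w / sum(w)
    cores[[p]] <- data.frame(promoter_id = promoter_id[p],
                             core = seq_len(n_cores[p]), center = centers,
                             sd = config$positional_sd, baseline_frac = w,
                             stringsAsFactors = FALSE)
    base <- stats::runif(1, config$mean_log_expression - half,
                         config$mean_log_expression + half)
    log10_total[p, ] <- base + stats::rnorm(n, 0, config$between_sample_sd)
    f <- matrix(w, n_cores[p], n)
    if (config$core_noise_sd > 0) {
      f <- exp(log(f) + matrix(stats::rnorm(n_cores[p] * n, 0,
                                            config$core_noise_sd),
                               n_cores[p], n))
      f <- sweep(f, 2, colSums(f), "/")
    }
    fr_rows[[p]] <- f
    ns <- config$n_snps_per_promoter
    if (ns > 0) {
      offs <- sample(c(-20000:-1000, 1000:20000), ns)
      geno_info[[p]] <- data.frame(
        snp_id = sprintf("%s_snp%d", promoter_id[p], seq_len(ns)),
        chrom = config$chrom, pos = center[p] + offs, ref = "A", alt = "G",
        promoter_id = promoter_id[p], stringsAsFactors = FALSE)
      geno_dose[[p]] <- simulate_genotypes(n, config$maf, ns)
    }
  }
  dose <- do.call(rbind, geno_dose)
  colnames(dose) <- samples$sample_id
  fractions <- do.call(rbind, fr_rows)
  cores_df <- do.call(rbind, cores)
  rownames(fractions) <- paste0(cores_df$promoter_id, "_core",
                                cores_df$core)
  colnames(fractions) <- samples$sample_id
  out <- list(
    promoters = data.frame(promoter_id = promoter_id, chrom = config$chrom,
                           strand = strand, center = center,
                           n_cores = n_cores, stringsAsFactors = FALSE),
    cores = cores_df, samples = samples, log10_total = log10_total,
    fractions = fractions,
    genotypes = genotype_matrix(do.call(rbind, geno_info), dose),
    effects = list())
  class(out) <- "sim_truth"
  out
}

#' Plant QTL effects into a simulated truth
#'
#' Deterministically modifies the latent per-sample expression totals and
#' core fractions according to each [planted_effect()] and the carriers'
#' dosages. Compensatory switches leave each sample's total promoter
#' expression unchanged for every genotype class by construction (only
#' fractions move).
#'
#' @param truth A `sim_truth` from [simulate_truth()].
#' @param effects List of [planted_effect()]s.
#' @return The modified `sim_truth`, with resolved effects appended to
#'   `truth$effects`.
#' @export
plant_qtl_effects <- function(truth, effects) {
  stopifnot(inherits(truth, "sim_truth"))
  eps <- 1e-12
  for (e in effects) {
    stopifnot(inherits(e, "planted_effect"))
    pid <- if (is.numeric(e$promoter))
      truth$promoters$promoter_id[e$promoter] else e$promoter
    pi <- match(pid, truth$promoters$promoter_id)
    if (is.na(pi)) stop("unknown promoter: ", pid)
    snp <- if (is.null(e$snp)) paste0(pid, "_snp1") else e$snp
    si <- match(snp, truth$genotypes$info$snp_id)
    if (is.na(si)) stop("unknown SNP: ", snp)
    d <- truth$genotypes$dosage[si, ]
    crows <- which(truth$cores$promoter_id == pid)
    if (any(e$cores > length(crows)))
      stop("promoter ", pid, " has only ", length(crows), " cores")
    if (e$kind == "expression") {
      truth$log10_total[pi, ] <- truth$log10_total[pi, ] + e$beta * d
    } else {
      if (length(crows) < 2)
        stop("fraction effects need a promoter with >= 2 cores")
      f <- truth$fractions[crows, , drop = FALSE]
      f <- pmin(pmax(f, eps), 1 - eps)
      if (e$kind == "fraction") {
        c1 <- e$cores[1L]
        f1 <- f[c1, ]
        f1p <- stats::plogis(stats::qlogis(f1) + e$beta * d)
        scale <- (1 - f1p) / (1 - f1)
        f <- sweep(f, 2, scale, "*")
        f[c1, ] <- f1p
      } else { # compensatory_switch
        c1 <- e$cores[1L]; c2 <- e$cores[2L]
        f[c1, ] <- stats::plogis(stats::qlogis(f[c1, ]) + e$beta * d)
        f[c2, ] <- stats::plogis(stats::qlogis(f[c2, ]) - e$beta * d)
        f <- sweep(f, 2, colSums(f), "/")
      }
      truth$fractions[crows, ] <- f
    }
    e$snp <- snp; e$promoter <- pid
    truth$effects[[length(truth$effects) + 1L]] <- e
  }
  truth
}

# Discretized Gaussian positional pmf, truncated at +/- 4 sd.
positional_pmf <- function(sd) {
  if (sd == 0) return(stats::setNames(1, 0))
  off <- -ceiling(4 * sd):ceiling(4 * sd)
  w <- stats::dnorm(off, 0, sd)
  stats::setNames(w / sum(w), off)
}

#' Simulate a CAGE CTSS panel with ground truth
#'
#' Draws the latent truth ([simulate_truth()]), applies the configured
#' planted effects ([plant_qtl_effects()]), then emits per-CTSS counts:
#' the expected count of sample `s` at an offset around core `k` of
#' promoter `p` is
#' `library_size * 10^log10_total[p,s] / 1e6 * fraction[k,s] * pmf(offset)`,
#' and observed counts are negative-binomial around it (or exactly equal to
#' it in deterministic mode). An annotation record places each promoter's
#' TSS at its most-expressed core center.
#'
#' @param config A [sim_config()].
#' @return list with `ctss` (a [ctss_matrix()]), `truth` (`sim_truth`),
#'   `annotation` (data.frame `chrom`, `tss`, `strand`, `gene`) and `meta`
#'   (a [library_meta()]).
#' @export
simulate_panel <- function(config) {
  truth <- simulate_truth(config)
  if (length(config$qtl_effects))
    truth <- plant_qtl_effects(truth, config$qtl_effects)
  emit_ctss_panel(truth, config)
}

#' Emit CTSS counts from a simulated truth
#'
#' The count-emission stage of [simulate_panel()], exposed separately so
#' that effects derived from an inspected truth (e.g. logit effects matched
#' to each promoter's baseline fractions) can be planted with
#' [plant_qtl_effects()] before emission.
#'
#' @param truth A `sim_truth`, possibly with planted effects.
#' @param config The [sim_config()] the truth was drawn from.
#' @return As [simulate_panel()].
#' @export
emit_ctss_panel <- function(truth, config) {
  n <- config$n_samples
  lib <- truth$samples$library_size
  pmf <- positional_pmf(config$positional_sd)
  off <- as.integer(names(pmf))
  np <- nrow(truth$promoters)
  pos_l <- cnt_l <- vector("list", np)
  nkeep <- integer(np)
  tss <- integer(np)
  pid <- truth$cores$promoter_id
  for (p in seq_len(np)) {
    crows <- which(pid == truth$promoters$promoter_id[p])
    total <- lib * 10^truth$log10_total[p, ] / 1e6
    pos_all <- rep(truth$cores$center[crows], each = length(off)) +
      rep(off, length(crows))
    mu <- truth$fractions[crows, , drop = FALSE] %x% pmf
    mu <- mu * rep(total, each = nrow(mu))
    cnt <- if (config$deterministic) mu else if (is.infinite(config$nb_size))
      matrix(stats::rpois(length(mu), mu), nrow(mu)) else
      matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
             nrow(mu))
    main_core <- crows[which.max(rowMeans(
      truth$fractions[crows, , drop = FALSE]))]
    tss[p] <- truth$cores$center[main_core]
    agg <- rowsum(cnt, pos_all)
    keep <- rowSums(agg) > 0
    nkeep[p] <- sum(keep)
    pos_l[[p]] <- as.integer(rownames(agg))[keep]
    cnt_l[[p]] <- agg[keep, , drop = FALSE]
  }
  counts <- do.call(rbind, cnt_l)
  colnames(counts) <- truth$samples$sample_id
  ctss <- ctss_matrix(rep(truth$promoters$chrom, nkeep),
                      unlist(pos_l),
                      rep(truth$promoters$strand, nkeep),
                      counts)
  annotation <- data.frame(
    chrom = truth$promoters$chrom, tss = tss,
    strand = truth$promoters$strand,
    gene = paste0("gene_", truth$promoters$promoter_id),
    stringsAsFactors = FALSE)
  meta <- library_meta(truth$samples$sample_id,
                       truth$samples$library_size,
                       truth$samples$batch, truth$samples$population)
  list(ctss = ctss, truth = truth, annotation = annotation, meta = meta)
}

#' Simulate an MNase-like 5'-end track
#'
#' Places a Gaussian bump of nucleosome-dyad 5'-end signal at a fixed
#' offset downstream of each promoter summit (in transcription direction),
#' mimicking a positioned +1 nucleosome.
#'
#' @param summits data.frame with columns `chrom`, `summit`, `strand`.
#' @param offset Planted summit-to-dyad distance, bp (default 120).
#' @param sd Positional sd ("fuzziness") of the dyad, bp (default 20).
#' @param total Expected total signal per promoter (default 1e4).
#' @param deterministic If TRUE (default) scores are exact expectations,
#'   otherwise Poisson draws.
#' @return Stranded track data.frame: `chrom`, `pos`, `strand`, `score`.
#' @export
simulate_mnase_track <- function(summits, offset = 120, sd = 20,
                                 total = 1e4, deterministic = TRUE) {
  pmf <- positional_pmf(sd)
  off <- as.integer(names(pmf))
  recs <- lapply(seq_len(nrow(summits)), function(i) {
    dir <- if (summits$strand[i] == "+") 1L else -1L
    center <- summits$summit[i] + dir * offset
    score <- total * pmf
    if (!deterministic) score <- stats::rpois(length(score), score)
    data.frame(chrom = summits$chrom[i], pos = center + off,
               strand = summits$strand[i], score = as.numeric(score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  agg <- stats::aggregate(score ~ chrom + pos + strand, out, sum)
  agg[order(agg$chrom, agg$strand, agg$pos), ]
}

#' Logit-scale effect matching a target linear fraction slope
#'
#' Fraction effects are planted on the logit scale, but QTL mapping
#' estimates a linear per-allele slope on the fraction itself. This helper
#' inverts the relationship: it returns the logit-scale `beta` whose
#' implied population OLS slope of `fraction ~ dosage` under
#' Hardy-Weinberg dosages equals `slope`.
#'
#' @param slope Target per-allele linear slope on the fraction scale.
#' @param baseline Baseline fraction of the target core (default 0.5).
#' @param maf Alt-allele frequency of the SNV (default 0.3).
#' @return Logit-scale beta.
#' @export
logit_beta_for_slope <- function(slope, baseline = 0.5, maf = 0.3) {
  if (slope == 0) return(0)
  pd <- stats::dbinom(0:2, 2, maf)
  implied <- function(b) {
    f <- stats::plogis(stats::qlogis(baseline) + b * (0:2))
    md <- sum(pd * (0:2))
    sum(pd * (0:2 - md) * f) / sum(pd * (0:2 - md)^2)
  }
  stats::uniroot(function(b) implied(b) - slope,
                 interval = c(-50, 50), tol = 1e-10)$root
}
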