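test_that("support filtering keeps CTSSs seen in enough samples", {
  x <- toy_ctss(c(10L, 20L, 30L),
                rbind(c(1, 0, 0, 0, 1),
                      c(1, 1, 1, 1, 1),
                      c(5, 9, 2, 1, 3)))
  f <- support_filter_ctss(x, min_count = 1, min_samples = 5)
  expect_equal(f$info$pos, c(20L, 30L))
  # identity configuration returns the input unchanged
  expect_equal(support_filter_ctss(x, 1, 1), x)
  expect_error(support_filter_ctss(x, 0, 1), "min_count")
})

test_that("tag clustering is single-linkage within max_gap on one strand", {
  x <- toy_ctss(c(100L, 155L, 300L), cbind(c(1, 1, 1)))
  cl <- cluster_ctss(x, max_gap = 60)
  expect_equal(cl$start, c(100L, 300L))
  expect_equal(cl$end, c(155L, 300L))

  # distance of exactly max_gap merges
  x2 <- toy_ctss(c(100L, 160L), cbind(c(1, 1)))
  expect_equal(nrow(cluster_ctss(x2, 60)), 1L)
  x3 <- toy_ctss(c(100L, 161L), cbind(c(1, 1)))
  expect_equal(nrow(cluster_ctss(x3, 60)), 2L)

  # identical positions on opposite strands never merge
  x4 <- ctss_matrix("chr1", c(100L, 100L), c("+", "-"),
                    matrix(1, 2, 1, dimnames = list(NULL, "s1")))
  expect_equal(nrow(cluster_ctss(x4, 60)), 2L)
  expect_error(cluster_ctss(x, max_gap = -1), "non-negative")
})

test_that("quantification sums all unfiltered CTSS counts in the extent", {
  x <- toy_ctss(c(10L, 11L, 12L),
                rbind(c(2, 0), c(1, 1), c(0, 3)))
  ext <- data.frame(id = "c1", chrom = "chr1", strand = "+",
                    start = 10L, end = 12L, n_ctss = 3L)
  proms <- quantify_clusters(x, ext)
  expect_equal(unname(proms$counts[1, ]), c(3, 4))

  # an unsupported CTSS (failed the support filter) still counts
  y <- toy_ctss(c(10L, 11L, 12L),
                rbind(c(5, 5), c(1, 0), c(4, 6)))
  supported <- support_filter_ctss(y, min_count = 2, min_samples = 2)
  expect_false(11L %in% supported$info$pos)
  proms2 <- quantify_clusters(y, cluster_ctss(supported, 60))
  expect_equal(unname(proms2$counts[1, ]), c(10, 11))

  # empty extent yields all-zero counts
  ext0 <- data.frame(id = "c0", chrom = "chr1", strand = "+",
                     start = 100L, end = 110L, n_ctss = 0L)
  expect_equal(unname(quantify_clusters(x, ext0)$counts[1, ]), c(0, 0))

  # overlapping extents on the same strand are rejected
  bad <- rbind(ext, data.frame(id = "c2", chrom = "chr1", strand = "+",
                               start = 12L, end = 20L, n_ctss = 1L))
  expect_error(quantify_clusters(x, bad), "overlapping")
})

test_that("TPM normalization divides by mapped totals times 1e6", {
  x <- toy_ctss(10L, matrix(c(50, 0), 1, dimnames = list(NULL, c("a", "b"))))
  proms <- quantify_clusters(x, cluster_ctss(x, 60))
  meta <- library_meta(c("a", "b"), c(2e6, 1e6))
  proms <- tpm_normalize(proms, meta)
  expect_equal(unname(proms$tpm[1, ]), c(25, 0))

  m2 <- library_meta(c("a", "b"), c(10, 10))
  expect_equal(unname(tpm_normalize(quantify_clusters(
    toy_ctss(10L, matrix(c(2, 3), 1, dimnames = list(NULL, c("a", "b")))),
    data.frame(id = "c", chrom = "chr1", strand = "+", start = 10L,
               end = 10L, n_ctss = 1L)), m2)$tpm[1, ]), c(2e5, 3e5))

  expect_error(tpm_normalize(proms, library_meta("a", 1e6)), "b")
})

test_that("summits take the pooled maximum with 5'-most tie-break", {
  expect_equal(find_summit(c(10, 11, 12), c(5, 9, 1), "+"), 11)
  expect_equal(find_summit(c(10, 12), c(5, 5), "+"), 10)
  expect_equal(find_summit(c(10, 12), c(5, 5), "-"), 12)
  expect_error(find_summit(integer(0), numeric(0)), "no member")
})

test_that("annotation window and strict expression filter are enforced", {
  n <- 108
  mk <- function(n_expr) {
    cnt <- matrix(0, 1, n, dimnames = list(NULL, sprintf("s%03d", 1:n)))
    cnt[1, seq_len(n_expr)] <- 10
    toy_ctss(5000L, cnt)
  }
  meta <- toy_meta(sprintf("s%03d", 1:n))
  run <- function(ctss, tss) {
    proms <- add_summits(tpm_normalize(
      quantify_clusters(ctss, cluster_ctss(ctss, 60)), meta), ctss, meta)
    ann <- data.frame(chrom = "chr1", tss = tss, strand = "+",
                      gene = "g1")
    annotate_and_filter(proms, ann)
  }
  # summit 980 bp upstream of the TSS, expressed in 11 samples: kept
  expect_equal(nrow(run(mk(11), 5980L)$clusters), 1L)
  expect_equal(run(mk(11), 5980L)$clusters$gene, "g1")
  # summit 1200 bp upstream: outside the window
  expect_equal(nrow(run(mk(11), 6200L)$clusters), 0L)
  # expressed in exactly 10 samples: strict inequality drops it
  expect_equal(nrow(run(mk(10), 5980L)$clusters), 0L)
  # downstream of the TSS (not upstream) is dropped too
  expect_equal(nrow(run(mk(11), 4990L)$clusters), 0L)
})

test_that("clustering partitions supported CTSSs and conserves counts", {
  pan <- simulate_panel(sim_config(n_samples = 12, n_promoters = 15,
                                   seed = 7))
  supported <- support_filter_ctss(pan$ctss, 1, 5)
  ext <- cluster_ctss(supported, 60)
  # every supported CTSS belongs to exactly one cluster
  hits <- vapply(seq_len(nrow(supported$info)), function(i) {
    sum(ext$chrom == supported$info$chrom[i] &
          ext$strand == supported$info$strand[i] &
          ext$start <= supported$info$pos[i] &
          ext$end >= supported$info$pos[i])
  }, numeric(1))
  expect_true(all(hits == 1))
  # quantification conservation over cluster extents
  proms <- quantify_clusters(pan$ctss, ext)
  inside <- vapply(seq_len(nrow(pan$ctss$info)), function(i) {
    any(ext$chrom == pan$ctss$info$chrom[i] &
          ext$strand == pan$ctss$info$strand[i] &
          ext$start <= pan$ctss$info$pos[i] &
          ext$end >= pan$ctss$info$pos[i])
  }, logical(1))
  expect_equal(colSums(proms$counts), colSums(pan$ctss$counts[inside, ]))
  # idempotence: clustering the clusters' member CTSSs again reproduces
  # identical extents
  in_ext <- vapply(seq_len(nrow(supported$info)), function(i) {
    any(ext$chrom == supported$info$chrom[i] &
          ext$strand == supported$info$strand[i] &
          ext$start <= supported$info$pos[i] &
          ext$end >= supported$info$pos[i])
  }, logical(1))
  ext2 <- cluster_ctss(supported[in_ext], 60)
  expect_equal(ext2$start, ext$start)
  expect_equal(ext2$end, ext$end)
})

test_that("zero-noise extents contain all planted core positions", {
  cfg <- sim_config(n_samples = 12, n_promoters = 15, seed = 11,
                    deterministic = TRUE, positional_sd = 0,
                    mean_log_expression = 1.5, log10_range = 1)
  pan <- simulate_panel(cfg)
  proms <- build_promoters(pan$ctss, pan$meta)
  for (p in seq_len(nrow(pan$truth$promoters))) {
    cores <- pan$truth$cores[pan$truth$cores$promoter_id ==
                               pan$truth$promoters$promoter_id[p], ]
    covered <- vapply(cores$center, function(cc) {
      any(proms$clusters$chrom == pan$truth$promoters$chrom[p] &
            proms$clusters$strand == pan$truth$promoters$strand[p] &
            proms$clusters$start <= cc & proms$clusters$end >= cc)
    }, logical(1))
    expect_true(all(covered))
  }
})
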