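test_that("window quantification counts half-open windows and normalizes to 1e7", {
  peaks <- make_peaks(data.frame(chrom = "chr1", start = 900L, end = 1100L,
                                 summit = 1000L, peak_id = "p"))
  # 8 tags inside [750, 1250), others outside
  lib <- tag_library(list(chr1 = c(rep(1000L, 6), 751L, 1249L, 1250L, 749L),
                          chr2 = rep(5L, 4)),
                     "s1", "wt")
  m <- quantify(peaks, list(lib), window = 500L)
  expect_equal(unname(m$counts[1, 1]), 8L)
  # library of 5e6 tags -> 8 tags = 16.0 normalized
  lib2 <- lib; lib2$total_tags <- 5e6
  m2 <- m; m2$total_tags <- 5e6
  expect_equal(unname(normalized_counts(m2)[1, 1]), 16.0)
  # no tags on the peak's chromosome
  p2 <- make_peaks(data.frame(chrom = "chrX", start = 0L, end = 100L))
  expect_equal(unname(quantify(p2, list(lib), 500L)$counts[1, 1]), 0L)
})

test_that("disjoint tiling windows conserve the per-chromosome tag total", {
  set.seed(31)
  pos <- sort(sample.int(100000, 5000))
  lib <- tag_library(list(chr1 = pos), "s1", "wt")
  centers <- seq(500L, 99500L, by = 1000L)
  tiles <- make_peaks(data.frame(chrom = "chr1", start = centers - 500L,
                                 end = centers + 500L, summit = centers,
                                 peak_id = paste0("w", centers)))
  m <- quantify(tiles, list(lib), window = 1000L)
  expect_equal(sum(m$counts), sum(pos >= 0 & pos < 100000))
})

test_that("NB Wald test is null-centred on identical counts and validates input", {
  counts <- matrix(rep(c(50L, 80L, 120L, 60L), each = 4), ncol = 4,
                   byrow = TRUE,
                   dimnames = list(paste0("f", 1:4), NULL))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        condition = c("wt", "wt", "ko", "ko"))
  m <- count_matrix(counts, samples)
  res <- nb_wald_test(m, "wt", "ko")
  expect_equal(res$log2fc, rep(0, 4), tolerance = 1e-6)
  expect_true(all(res$p > 0.99))
  expect_error(nb_wald_test(m, "wt", "nope"), "unknown condition")
  m1 <- count_matrix(counts[, 1:3], samples[1:3, ])
  expect_error(nb_wald_test(m1, "wt", "ko"), "'ko' has < 2 samples")
})

test_that("swapping condition labels negates log2fc and preserves p", {
  g <- generate_counts(32, stats::setNames(c(rep(0, 150), rep(1.5, 50)),
                                           sprintf("f%03d", 1:200)),
                       n_reps = 3)
  r1 <- nb_wald_test(g$matrix, "wt", "ko")
  r2 <- nb_wald_test(g$matrix, "ko", "wt")
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  # permutation of sample columns within conditions changes nothing
  perm <- c(2, 1, 3, 5, 4, 6)
  mp <- count_matrix(g$matrix$counts[, perm], g$matrix$samples[perm, ],
                     total_tags = g$matrix$total_tags[perm])
  r3 <- nb_wald_test(mp, "wt", "ko")
  expect_equal(r1$p, r3$p, tolerance = 1e-8)
})

test_that("BH adjustment agrees with the step-up oracle on random p-vectors", {
  set.seed(33)
  for (n in c(5, 37, 100)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("differential verdicts use strict fold and significance thresholds", {
  res <- data.frame(feature_id = paste0("f", 1:4),
                    baseMean = 100, se = 0.1, stat = 0, p = 0.01,
                    log2fc = c(1.2, 1.2, 1.0, -1.4),
                    padj = c(0.01, 0.2, 0.01, 0.04))
  class(res) <- c("DiffResult", "data.frame")
  v <- call_differential_peaks(res)$verdict
  expect_equal(as.character(v), c("up", "unchanged", "unchanged", "down"))
})

test_that("planted 4-fold effects are recovered with high power", {
  lfc <- stats::setNames(c(rep(2, 250), rep(-2, 250), rep(0, 500)),
                         sprintf("f%04d", 1:1000))
  g <- generate_counts(34, lfc, n_reps = 3, base_mean = 100,
                       dispersion = 0.05)
  res <- call_differential_peaks(nb_wald_test(g$matrix, "wt", "ko"))
  called <- as.character(res$verdict)
  expect_gte(mean(called[1:250] == "up"), 0.9)
  expect_gte(mean(called[251:500] == "down"), 0.9)
  expect_lte(mean(called[501:1000] != "unchanged"), 0.02)
})

test_that("the NB test agrees with an independent DESeq2 analysis", {
  lfc <- stats::setNames(c(rep(2, 100), rep(-2, 100), rep(0, 300)),
                         sprintf("f%03d", 1:500))
  g <- generate_counts(71, lfc, n_reps = 3, base_mean = 100,
                       dispersion = 0.05)
  mine <- call_differential_peaks(nb_wald_test(g$matrix, "wt", "ko"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      g$matrix$counts,
      data.frame(condition = factor(g$matrix$samples$condition,
                                    levels = c("wt", "ko"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
  })
  ref <- DESeq2::results(dds)
  expect_gt(cor(mine$log2fc, ref$log2FoldChange), 0.99)
  ref_call <- !is.na(ref$padj) & ref$padj < 0.05 & abs(ref$log2FoldChange) > 1
  my_call <- mine$verdict != "unchanged"
  jaccard <- sum(ref_call & my_call) / sum(ref_call | my_call)
  expect_gt(jaccard, 0.9)
})
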