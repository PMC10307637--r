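mk_k27 <- function(peaks, wt, ko, libsize = 1e7) {
  counts <- cbind(wt_rep1 = wt, wt_rep2 = wt, ko_rep1 = ko, ko_rep2 = ko)
  rownames(counts) <- peaks$peak_id
  count_matrix(counts,
               data.frame(sample_id = colnames(counts),
                          condition = c("wt", "wt", "ko", "ko")),
               window = 1000L, total_tags = rep(libsize, 4))
}

test_that("activity floor keeps peaks active in at least one condition", {
  peaks <- make_peaks(data.frame(chrom = "chr1",
                                 start = c(0L, 1000L, 2000L),
                                 end = c(500L, 1500L, 2500L),
                                 peak_id = c("a", "b", "c")))
  # tags-per-1e7 with libsize 1e7: normalized == raw counts
  m <- mk_k27(peaks, wt = c(20L, 16L, 0L), ko = c(3L, 16L, 30L))
  act <- select_active_enhancers(peaks, m, floor = 16)
  expect_equal(act$peak_id, c("a", "c"))  # b fails the strict > in both
  expect_error(select_active_enhancers(peaks[1:2, ], m), "do not match")
})

test_that("the four-class truth table is exhaustive and exclusive", {
  peaks <- make_peaks(data.frame(chrom = "chr1",
                                 start = (0:4) * 1000L,
                                 end = (0:4) * 1000L + 500L,
                                 peak_id = paste0("p", 1:5)))
  diff <- data.frame(feature_id = paste0("p", 1:5), baseMean = 100,
                     log2fc = c(-2, 2, -2, 2, 0), se = 0.1, stat = 0,
                     p = c(rep(1e-4, 4), 0.9),
                     padj = c(rep(1e-3, 4), 0.95))
  class(diff) <- c("DiffResult", "data.frame")
  diff <- call_differential_peaks(diff)
  # TF binds p1, p2, p5
  tf <- make_peaks(data.frame(chrom = "chr1", start = c(100L, 1100L, 4100L),
                              end = c(300L, 1300L, 4300L),
                              peak_id = paste0("t", 1:3)))
  rec <- classify_enhancers(peaks, diff, tf)
  expect_equal(as.character(rec$enh_class),
               c("direct_activated", "direct_repressed",
                 "indirect_activated", "indirect_repressed", "unclassified"))
  expect_false(any(is.na(rec$enh_class)))  # exhaustive
  expect_error(classify_enhancers(peaks, diff[1:3, ], tf), "missing")
})

test_that("stitching joins peaks within the stitch distance only", {
  mk <- function(gap) make_peaks(data.frame(
    chrom = "chr1", start = c(0L, 1000L + gap), end = c(1000L, 2000L + gap),
    score = c(5, 5), peak_id = c("a", "b")))
  expect_equal(nrow(suppressWarnings(call_super_enhancers(mk(10000L)))), 1L)
  expect_equal(nrow(suppressWarnings(call_super_enhancers(mk(20000L)))), 2L)
})

test_that("the rank-signal elbow flags exactly the planted high regions", {
  fx <- super_enhancer_fixture(n_regions = 30, n_super = 2)
  se <- call_super_enhancers(fx$peaks)
  expect_equal(sum(se$is_super), 2L)
  expect_setequal(unlist(strsplit(se$constituents[se$is_super], ",")),
                  fx$peaks$peak_id[fx$truth])
  # flags invariant to input order, and stitched signal is conserved
  shuf <- fx$peaks[sample(nrow(fx$peaks)), ]
  attr(shuf, "genome") <- "synth1"; class(shuf) <- class(fx$peaks)
  se2 <- call_super_enhancers(shuf)
  expect_equal(se2$is_super[order(se2$rank)], se$is_super[order(se$rank)])
  expect_equal(sum(se$total_signal), sum(fx$peaks$score))
})

test_that("degenerate signal profiles yield no super-enhancers", {
  fx <- super_enhancer_fixture(n_regions = 20)
  eq <- fx$peaks; eq$score <- rep(7, nrow(eq))
  attr(eq, "genome") <- "synth1"; class(eq) <- class(fx$peaks)
  expect_equal(sum(call_super_enhancers(eq)$is_super), 0L)
  expect_warning(call_super_enhancers(fx$peaks[1:2, ]), "fewer than 3")
})

test_that("class-gene report reproduces the hypergeometric tail exactly", {
  rec <- data.frame(
    peak_id = paste0("p", 1:10),
    enh_class = factor(rep("direct_activated", 10),
                       levels = c("direct_activated", "direct_repressed",
                                  "indirect_activated", "indirect_repressed",
                                  "unclassified")),
    nearest_gene = paste0("g", 1:10))
  class(rec) <- c("EnhancerRecord", "data.frame")
  down <- c(paste0("g", 1:5), paste0("g", 90:99))
  rep1 <- class_gene_report(rec, up_genes = character(), down_genes = down,
                            universe = 100)
  da <- rep1[rep1$enh_class == "direct_activated", ]
  expect_equal(da$n_down, 5L)
  expect_equal(da$frac_down, 0.5)
  expect_equal(da$fisher_p_down, oracle_hyper_upper(5, 15, 10, 100),
               tolerance = 1e-12)
  # full containment -> fraction 1; disjoint -> p not small
  rep2 <- class_gene_report(rec, up_genes = paste0("g", 1:10),
                            down_genes = character(), universe = 50)
  expect_equal(rep2$frac_up[rep2$enh_class == "direct_activated"], 1)
  rep3 <- class_gene_report(rec, up_genes = c("z1", "z2"),
                            down_genes = character(), universe = 1000)
  expect_gte(rep3$fisher_p_up[rep3$enh_class == "direct_activated"], 0.5)
  expect_error(class_gene_report(rec, "g1", "g1", 100), "disjoint")
})

test_that("overlap summaries validate inputs", {
  expect_equal(overlap_summary(200, 0)$percent, 0)
  expect_error(overlap_summary(0, 0), "> 0")
  expect_error(overlap_summary(10, 11), "outside")
})
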