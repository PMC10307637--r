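rep_set <- function(summits, scores = rep(10, length(summits)), name = "r",
                    width = 200L) {
  make_peaks(data.frame(chrom = "chr1", start = summits - width %/% 2L,
                        end = summits + width %/% 2L, summit = summits,
                        score = scores,
                        peak_id = paste0(name, "_", seq_along(summits))),
             name = name)
}

test_that("identical replicates pass, replicate-private peaks drop", {
  s <- c(1000L, 5000L, 9000L)
  out <- reproducible_peaks(list(rep_set(s, name = "a"), rep_set(s, name = "b")),
                            rank_fraction = 1)
  expect_equal(nrow(out), 3L)
  out2 <- reproducible_peaks(list(rep_set(s, name = "a"),
                                  rep_set(s[1:2], name = "b")),
                             rank_fraction = 1)
  expect_equal(nrow(out2), 2L)
  expect_error(reproducible_peaks(list(rep_set(s))), ">= 2 replicates")
})

test_that("summit jitter within the distance is kept, beyond is dropped", {
  a <- rep_set(c(1000L, 5000L), name = "a")
  near <- rep_set(c(1000L + 80L, 5000L - 90L), name = "b")
  far <- rep_set(c(1000L + 150L, 5000L - 200L), name = "b")
  expect_equal(nrow(reproducible_peaks(list(a, near), summit_dist = 100L,
                                       rank_fraction = 1)), 2L)
  expect_equal(nrow(reproducible_peaks(list(a, far), summit_dist = 100L,
                                       rank_fraction = 1)), 0L)
})

test_that("rank filter excludes weak partners and output merges evidence", {
  a <- rep_set(c(1000L, 5000L), scores = c(100, 1), name = "a")
  b <- rep_set(c(1020L, 5020L), scores = c(90, 2), name = "b")
  out <- reproducible_peaks(list(a, b), rank_fraction = 0.5)
  expect_equal(nrow(out), 1L)
  # signal-weighted summit between the two partners, mean score
  expect_true(out$summit >= 1000L && out$summit <= 1020L)
  expect_equal(out$score, 95)
  expect_equal(out$start, min(a$start[1], b$start[1]))
  expect_equal(out$end, max(a$end[1], b$end[1]))
})

test_that("reproducible loci are invariant to replicate ordering", {
  set.seed(21)
  s1 <- sort(sample.int(100000, 40)) * 10L
  keep <- sort(sample.int(40, 30))
  a <- rep_set(s1, scores = runif(40, 1, 100), name = "a")
  b <- rep_set(s1[keep] + sample(-50:50, 30, TRUE),
               scores = runif(30, 1, 100), name = "b")
  o1 <- reproducible_peaks(list(a, b), rank_fraction = 1)
  o2 <- reproducible_peaks(list(b, a), rank_fraction = 1)
  expect_equal(o1$summit, o2$summit, tolerance = 1e-8)
  expect_equal(sort(o1$score), sort(o2$score))
})

test_that("merging unions transitively overlapping records with max score", {
  x <- make_peaks(data.frame(chrom = "chr1", start = c(0L, 500L),
                             end = c(100L, 600L), score = c(1, 2),
                             peak_id = c("x1", "x2")))
  y <- make_peaks(data.frame(chrom = "chr1", start = c(1000L, 1500L),
                             end = c(1100L, 1600L), score = c(3, 4),
                             peak_id = c("y1", "y2")))
  expect_equal(nrow(merge_pairwise_sets(list(x, y))), 4L)
  expect_equal(nrow(merge_pairwise_sets(list(x, x))), 2L)
  # chain a-b overlap, b-c overlap -> one record spanning all three
  chain <- list(
    make_peaks(data.frame(chrom = "chr1", start = 0L, end = 100L, score = 1,
                          peak_id = "a")),
    make_peaks(data.frame(chrom = "chr1", start = 50L, end = 150L, score = 5,
                          peak_id = "b")),
    make_peaks(data.frame(chrom = "chr1", start = 140L, end = 240L, score = 2,
                          peak_id = "c")))
  m <- merge_pairwise_sets(chain)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 240L))
  expect_equal(m$score, 5)  # max constituent
  # abutting half-open records stay separate
  ab <- list(make_peaks(data.frame(chrom = "chr1", start = 0L, end = 100L,
                                   peak_id = "a")),
             make_peaks(data.frame(chrom = "chr1", start = 100L, end = 200L,
                                   peak_id = "b")))
  expect_equal(nrow(merge_pairwise_sets(ab)), 2L)
})

test_that("strain-differential sets recover planted strain-specific loci", {
  set.seed(22)
  shared <- (1:100) * 100000L
  # planted strain-specific loci midway between grid points, well separated
  only_a <- shared[seq(1, 99, 2)] + 50000L
  only_b <- shared[seq(2, 100, 2)] + 50000L
  mk_reps <- function(loci, nm) list(
    rep_set(loci, scores = runif(length(loci), 10, 100), name = paste0(nm, 1)),
    rep_set(loci + sample(-20:20, length(loci), TRUE),
            scores = runif(length(loci), 10, 100), name = paste0(nm, 2)))
  sd_res <- strain_differential(mk_reps(c(shared, only_a), "a"),
                                mk_reps(c(shared, only_b), "b"),
                                rank_fraction = 1)
  # exact recovery of the planted strain-specific loci
  expect_equal(nrow(sd_res$differential_a), length(only_a))
  expect_equal(nrow(sd_res$differential_b), length(only_b))
  expect_true(all(abs(sort(sd_res$differential_a$summit) - sort(only_a)) <= 20))
  # differential sets are disjoint from the other strain's reproducible set
  expect_equal(overlap_peaks(sd_res$differential_a,
                             sd_res$reproducible_b)$n_a_overlapping, 0L)
  expect_equal(overlap_peaks(sd_res$differential_b,
                             sd_res$reproducible_a)$n_a_overlapping, 0L)
  # identical strains -> both empty
  same <- strain_differential(mk_reps(shared, "a"), mk_reps(shared, "b"),
                              rank_fraction = 1)
  expect_equal(nrow(same$differential_a), 0L)
  expect_equal(nrow(same$differential_b), 0L)
})
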