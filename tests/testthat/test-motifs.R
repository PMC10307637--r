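test_that("PWM scores are log2 odds with background and pseudocount rules", {
  # columns equal to background score zero bits
  flat <- pwm(matrix(0.25, 4, 4), pseudocount = 0)
  expect_equal(pwm_score(flat, "ACGT"), 0)
  # each perfectly matched position over uniform background adds log2(4)
  # bits; a total score of 4 bits is a 2^4 = 16-fold likelihood ratio
  sharp <- pwm(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                     c(1, 0, 0, 0), c(0, 0, 0, 1)), pseudocount = 0)
  expect_equal(pwm_score(sharp, "ACAT"), 4 * log2(4))
  expect_equal(2^4, 16)
  # ambiguous base contributes zero bits
  expect_equal(pwm_score(sharp, "ACAN"), 3 * log2(4))
  # reverse-complement symmetry
  p <- test_pwm("ACGTTG")
  win <- "ACGTTG"
  expect_equal(pwm_score(pwm_revcomp(p), revcomp(win)), pwm_score(p, win))
  expect_error(pwm_score(p, "ACG"), "length")
})

test_that("pwm objects validate and normalize their inputs", {
  expect_error(pwm(matrix(1, 3, 6)), "4 rows")
  expect_error(pwm(matrix(1, 4, 3)), ">= 4")
  counts <- matrix(c(8, 0, 0, 0), 4, 5)
  expect_equal(colSums(pwm(counts)$probs), rep(1, 5))
})

test_that("scanning finds planted matches and matches the naive oracle", {
  p <- test_pwm("ACGTACGA")
  set.seed(51)
  bases <- sample(c("A", "C", "G", "T"), 300, TRUE)
  bases[38:45] <- strsplit("ACGTACGA", "")[[1]]  # plant at 0-based 37
  seq <- paste(bases, collapse = "")
  hits <- scan_sequence(p, seq, threshold = 4)
  expect_true(any(hits$start == 37 & hits$strand == "+"))
  # all-N sequence yields nothing above a positive threshold
  expect_equal(nrow(scan_sequence(p, strrep("N", 100), 4)), 0L)
  # very low threshold reports every window on both strands
  expect_equal(nrow(scan_sequence(p, seq, -1e6)), 2 * (300 - 8 + 1))
  # sequence shorter than the motif
  expect_equal(nrow(scan_sequence(p, "ACG", 4)), 0L)
  # oracle equivalence on a random 2 kb sequence at multiple thresholds
  seq2k <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  for (thr in c(2, 4, 6)) {
    got <- scan_sequence(p, seq2k, thr)
    want <- oracle_scan(p, seq2k, thr)
    got <- got[order(got$start, got$strand), ]
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("exact signed-rank p equals full sign enumeration up to n = 12", {
  set.seed(52)
  cases <- c(lapply(c(3, 5, 8, 12), function(n) rnorm(n)),
             list(c(1, 2, 3),                      # all positive
                  c(1, -1, 2, -2, 3, 3),           # ties in |d|
                  c(0, 0, 1.5, -2, 4)))            # zeros dropped
  for (d in cases) {
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_signed_rank(d),
                 tolerance = 1e-12)
  }
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p, 0.25)
  expect_equal(wilcoxon_signed_rank(rep(0, 10))$p, 1)
  # agreement with the stats implementation when no ties, larger n
  d <- rnorm(20)
  expect_equal(wilcoxon_signed_rank(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("motif enrichment reproduces exact binomial tails", {
  p <- test_pwm("ACGTACGA")
  base <- strrep("T", 60)
  with_motif <- paste0(strrep("T", 20), "ACGTACGA", strrep("T", 32))
  targets <- rep(with_motif, 10)
  background <- c(rep(with_motif, 5), rep(base, 5))
  res <- motif_enrichment(targets, background, list(p), threshold = 4)
  expect_equal(res$pct_target, 100)
  expect_equal(res$pct_bkgd, 50)
  expect_equal(res$p, 0.5^10, tolerance = 1e-12)
  # no target matches -> p = 1; matched rates -> p not small
  res0 <- motif_enrichment(rep(base, 10), background, list(p))
  expect_equal(res0$p, 1)
  expect_error(motif_enrichment(character(), background, list(p)), "empty")
})

test_that("conserved-motif mapping projects through alignments", {
  p <- test_pwm("ACGTACGA")
  seq_a <- paste0(strrep("T", 20), "ACGTACGA", strrep("G", 20))
  ma <- scan_sequence(p, seq_a, 4)
  # identity alignment, identical sequence: conserved at the same start
  id_map <- alignment_map(seq_a, seq_a)
  cons <- map_conserved_motifs(ma, seq_a, id_map, list(p))
  expect_equal(nrow(cons), nrow(ma))
  expect_equal(cons$b_start, cons$start)
  # symmetric on identity alignments
  cons_rev <- map_conserved_motifs(cons, seq_a, id_map, list(p))
  expect_equal(nrow(cons_rev), nrow(cons))
  # 2-base insertion in b upstream of the motif shifts the projection
  seq_b <- paste0(strrep("T", 20), "CC", "ACGTACGA", strrep("G", 20))
  gapped_a <- paste0(strrep("T", 20), "--", "ACGTACGA", strrep("G", 20))
  map_ins <- alignment_map(gapped_a, seq_b)
  cons2 <- map_conserved_motifs(ma, seq_b, map_ins, list(p))
  expect_equal(nrow(cons2), nrow(ma))
  expect_equal(cons2$b_start[cons2$start == 20], 22L)
  # motif with most positions unaligned is not conserved
  a_aln <- seq_a  # no gaps on the a side
  b_aln <- paste0(strrep("T", 20), "ACG", strrep("-", 5), strrep("G", 20))
  gap_b_seq <- gsub("-", "", b_aln)
  map_gap <- alignment_map(a_aln, b_aln)
  m_fake <- data.frame(pwm = p$name, start = 20L, end = 28L, strand = "+",
                       score = 9, stringsAsFactors = FALSE)
  expect_equal(nrow(map_conserved_motifs(m_fake, gap_b_seq, map_gap,
                                         list(p))), 0L)
  # matches beyond the alignment error out
  m_out <- data.frame(pwm = p$name, start = 100L, end = 108L, strand = "+",
                      score = 9, stringsAsFactors = FALSE)
  expect_error(map_conserved_motifs(m_out, seq_a, map_gap, list(p)),
               "beyond")
})

test_that("the convenience aligner recovers an exact alignment map", {
  a <- "ACGTACGTTTTTGGGCCC"
  b <- "ACGTACGTTTTTAAGGGCCC"  # 2-base insertion
  m <- align_sequences(a, b)
  expect_equal(m$a_len, nchar(a))
  expect_equal(nrow(m$pairs), nchar(a))
  expect_true(all(diff(m$pairs$a_pos) > 0) && all(diff(m$pairs$b_pos) > 0))
})

test_that("motif-mutation association recovers the planted causal motif", {
  causal <- test_pwm("ACGTACGA", name = "CAUSAL")
  decoys <- lapply(1:20, function(i)
    random_pwm(500 + i, name = sprintf("DECOY%02d", i)))
  sp <- generate_strain_pairs(53, n_loci = 100, causal_pwm = causal,
                              mutation_rate = 0.8)
  assoc <- motif_mutation_association(sp$pairs, c(list(causal), decoys))
  res <- assoc$results
  best <- res$motif[which.max(abs(res$signed_logp))]
  expect_equal(best, "CAUSAL")
  # disruption lowers the negative-strain score: positive signed_logp
  expect_gt(res$signed_logp[res$motif == "CAUSAL"], 0)
  expect_false(res$underpowered[res$motif == "CAUSAL"])
  expect_error(motif_mutation_association(
    variant_pair_set(data.frame(locus_id = "l", positive_seq = "A",
                                negative_seq = "A"))[0, , drop = FALSE],
    list(causal)), "no pairs")
})

test_that("motif clusters are connected components above the r threshold", {
  set.seed(54)
  base1 <- rnorm(60); base2 <- rnorm(60)
  D <- cbind(m1 = base1 + rnorm(60, 0, 0.2),
             m2 = base1 + rnorm(60, 0, 0.2),
             m3 = base2 + rnorm(60, 0, 0.2),
             m4 = base2 + rnorm(60, 0, 0.2))
  fake <- list(results = data.frame(
    motif = colnames(D), n_informative = 60L, W = 1, p = 0.5,
    padj = 0.5, signed_logp = c(1, 2, -1, -2), expressed = NA,
    underpowered = FALSE, stringsAsFactors = FALSE),
    score_diffs = D)
  cl <- cluster_motifs(fake)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster_signed_logp[1], 1.5)
  # all-independent vectors stay singletons
  D2 <- matrix(rnorm(240), 60, 4, dimnames = list(NULL, colnames(D)))
  fake$score_diffs <- D2
  expect_equal(length(unique(cluster_motifs(fake)$cluster)), 4L)
  # single linkage chains A-B and B-C into one cluster without r(A,C) > r
  n <- 400
  A <- rnorm(n); C <- rnorm(n)
  B <- sqrt(0.55) * scale(A)[, 1] + sqrt(0.55) * scale(C)[, 1]
  D3 <- cbind(mA = A, mB = B, mC = C)
  fake3 <- list(results = data.frame(
    motif = colnames(D3), n_informative = n, W = 1, p = 0.5, padj = 0.5,
    signed_logp = 0, expressed = NA, underpowered = FALSE,
    stringsAsFactors = FALSE), score_diffs = D3)
  R <- cor(D3)
  expect_true(R["mA", "mB"] > 0.6 && R["mB", "mC"] > 0.6 &&
                R["mA", "mC"] <= 0.6)  # a genuine chain under this seed
  expect_equal(length(unique(cluster_motifs(fake3)$cluster)), 1L)
  # constant vector becomes a singleton with a warning
  D4 <- cbind(m1 = rnorm(60), m2 = rep(1, 60))
  fake4 <- list(results = fake$results[1:2, ], score_diffs = D4)
  fake4$results$motif <- colnames(D4)
  expect_warning(out <- cluster_motifs(fake4), "constant")
  expect_equal(length(unique(out$cluster)), 2L)
})

test_that("JASPAR and FASTA round-trip through their writers", {
  pwms <- list(test_pwm("ACGTAC", name = "M1"),
               random_pwm(55, length = 10, name = "M2"))
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, f)
  back <- read_jaspar(f)
  expect_equal(names(back), c("M1", "M2"))
  expect_equal(back$M2$probs, pwms[[2]]$probs, tolerance = 1e-5)
  seqs <- c(l1 = "ACGTACGT", l2 = "GGGCCCAA")
  ff <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, ff)
  expect_equal(read_fasta(ff), seqs)
})
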