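# Brute-force oracles kept independent of the implementation paths they check.

# all-pairs interval overlap (0-based half-open), >= min_bp shared bases
oracle_overlap_flags <- function(a, b, min_bp = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        (min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])) >= min_bp
    }, TRUE))
  }, TRUE)
}

# nearest TSS by absolute summit distance, ties to smaller gene_id
oracle_nearest <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(NA_character_)
    d <- abs(peaks$summit[i] - g$tss)
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, "")
}

# hypergeometric upper tail P(X >= k) by direct summation of the pmf
oracle_hyper_upper <- function(k, K, n, N) {
  kk <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# naive per-window motif scan on both strands
oracle_scan <- function(p, seq, threshold) {
  L <- ncol(p$probs)
  n <- nchar(seq)
  out <- list()
  if (n >= L) {
    for (s in 1:(n - L + 1)) {
      win <- substr(seq, s, s + L - 1)
      fs <- pwm_score(p, win)
      rs <- pwm_score(pwm_revcomp(p), win)
      if (fs > threshold)
        out[[length(out) + 1]] <- data.frame(start = s - 1L, strand = "+",
                                             score = fs)
      if (rs > threshold)
        out[[length(out) + 1]] <- data.frame(start = s - 1L, strand = "-",
                                             score = rs)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), strand = character(),
                                      score = numeric()))
  do.call(rbind, out)
}

# BH step-up adjusted p-values from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

make_peaks <- function(df, genome = "synth1", name = "t") {
  peak_set(df, name = name, genome = genome)
}

# sharp test PWM: consensus ACGTACGT-style, adjustable length
test_pwm <- function(consensus = "ACGTAC", name = "TEST", pseudocount = 0.001) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- sapply(idx, function(i) { v <- rep(0, 4); v[i] <- 1; v })
  pwm(m, name = name, pseudocount = pseudocount)
}
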