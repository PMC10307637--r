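#' Exact / approximate Wilcoxon signed-rank test
#'
#' Paired signed-rank test on a vector of differences. Zeros are dropped;
#' absolute values are midranked. For n <= `exact_n` the null distribution
#' of the positive-rank sum is computed exactly by dynamic programming over
#' sign assignments (equivalent to enumerating all 2^n of them, ties
#' included); beyond that a normal approximation with continuity and tie
#' correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_n largest n for the exact distribution (default 25).
#' @return list with `n` (nonzero differences), `W` (positive-rank sum),
#'   `p` (two-sided), `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_n = 25L) {
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(n = 0L, W = NA_real_, p = 1, method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_n) {
    # DP over doubled ranks (midranks are half-integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)  # f[w+1] = #assignments with doubled rank sum w
    f[1] <- 1
    for (ri in r2) {
      g <- numeric(total + 1)
      g[1:(total + 1 - ri)] <- f[1:(total + 1 - ri)]
      f <- f + c(rep(0, ri), g[1:(total + 1 - ri)])
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(n = n, W = W, p = p, method = method)
}

#' Known-motif enrichment in target vs GC-matched background sequences
#'
#' For each PWM, the fraction of target sequences containing at least one
#' match above `threshold` bits is compared with the fraction in a
#' GC-matched background: target GC content is binned into deciles and,
#' within each bin, background sequences are sampled (seeded, with
#' replacement when the bin is shallow) to mirror the target bin counts.
#' Significance is the one-sided binomial upper tail with the matched
#' background fraction as success probability.
#'
#' @param targets,background character vectors of sequences.
#' @param pwms list of `pwm` objects.
#' @param threshold match threshold in bits (default 4).
#' @param seed seed for the GC-matched background sampling.
#' @return data frame with `pwm`, `pct_target`, `pct_bkgd`, `n_target`,
#'   `n_bkgd`, `p`, sorted by p.
#' @export
motif_enrichment <- function(targets, background, pwms, threshold = 4,
                             seed = 1L) {
  if (!length(targets)) stop("motif_enrichment: empty target set")
  if (length(background) < length(targets))
    warning("motif_enrichment: background smaller than target set")
  gc_t <- vapply(targets, gc_content, 0, USE.NAMES = FALSE)
  gc_b <- vapply(background, gc_content, 0, USE.NAMES = FALSE)
  breaks <- unique(stats::quantile(gc_t, probs = seq(0, 1, 0.1), na.rm = TRUE))
  if (length(breaks) < 2) breaks <- c(0, 1)  # all targets share one GC value
  bin_t <- cut(gc_t, breaks, include.lowest = TRUE)
  bin_b <- cut(gc_b, breaks, include.lowest = TRUE)
  matched <- with_preserved_seed(seed, {
    idx <- unlist(lapply(levels(bin_t), function(lv) {
      nt <- sum(bin_t == lv, na.rm = TRUE)
      pool <- which(bin_b == lv)
      if (!nt) return(integer(0))
      if (!length(pool)) pool <- seq_along(background)  # fall back to all
      sample(pool, nt, replace = length(pool) < nt)
    }))
    background[idx]
  })
  has_match <- function(seqs, p)
    vapply(seqs, function(s) best_pwm_score(p, s) > threshold, TRUE,
           USE.NAMES = FALSE)
  rows <- lapply(pwms, function(p) {
    kt <- sum(has_match(targets, p))
    kb <- sum(has_match(matched, p))
    p0 <- kb / length(matched)
    pval <- stats::pbinom(kt - 1, length(targets), p0, lower.tail = FALSE)
    data.frame(pwm = p$name,
               pct_target = 100 * kt / length(targets),
               pct_bkgd = 100 * p0,
               n_target = length(targets), n_bkgd = length(matched),
               p = pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Build an alignment map between two sequences
#'
#' The map records pairs of aligned (non-gap) 0-based positions; columns
#' are strictly increasing in both coordinates.
#'
#' @param a_aln,b_aln gapped alignment strings of equal length ("-" = gap).
#' @param a_len,b_len ungapped sequence lengths (derived when NULL).
#' @return object of class `AlignmentMap`: data frame `pairs` with
#'   `a_pos`, `b_pos`, plus `a_len`, `b_len`.
#' @export
alignment_map <- function(a_aln, b_aln, a_len = NULL, b_len = NULL) {
  ca <- strsplit(a_aln, "")[[1]]
  cb <- strsplit(b_aln, "")[[1]]
  if (length(ca) != length(cb))
    stop("alignment_map: gapped strings differ in length")
  ia <- cumsum(ca != "-") - 1L
  ib <- cumsum(cb != "-") - 1L
  keep <- ca != "-" & cb != "-"
  pairs <- data.frame(a_pos = ia[keep], b_pos = ib[keep])
  structure(list(pairs = pairs,
                 a_len = if (is.null(a_len)) sum(ca != "-") else a_len,
                 b_len = if (is.null(b_len)) sum(cb != "-") else b_len),
            class = "AlignmentMap")
}

#' Read an alignment map from a 3-column TSV of aligned blocks
#'
#' Columns `a_start`, `b_start`, `length`: each row is an ungapped aligned
#' block (0-based starts).
#'
#' @param path TSV file path.
#' @return an `AlignmentMap`.
#' @export
read_alignment_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("a_start", "b_start", "length") %in% names(df)))
    stop("read_alignment_map: need a_start, b_start, length columns")
  pairs <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    data.frame(a_pos = df$a_start[i] + 0:(df$length[i] - 1),
               b_pos = df$b_start[i] + 0:(df$length[i] - 1))))
  pairs <- pairs[order(pairs$a_pos), ]
  if (any(diff(pairs$a_pos) <= 0) || any(diff(pairs$b_pos) <= 0))
    stop("read_alignment_map: blocks must be strictly increasing in both coordinates")
  structure(list(pairs = pairs, a_len = max(pairs$a_pos) + 1L,
                 b_len = max(pairs$b_pos) + 1L),
            class = "AlignmentMap")
}

#' Globally align two sequences (convenience for building alignment maps)
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -2, gap
#' opening 5 and gap extension 2, returning the [alignment_map()].
#' Intended for constructing small fixtures; no significance estimates.
#'
#' @param a,b DNA sequences.
#' @return an `AlignmentMap`.
#' @export
align_sequences <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
  alignment_map(as.character(Biostrings::alignedPattern(aln)),
                as.character(Biostrings::alignedSubject(aln)),
                a_len = nchar(a), b_len = nchar(b))
}

#' Map motif matches through an alignment and keep conserved ones
#'
#' A match in sequence a is conserved in sequence b when at least half of
#' its positions are aligned (non-gap) and b carries a match of the same
#' PWM, on either strand, whose start lies within `tolerance` bases of the
#' match's projected start (the b-coordinate of its first aligned position
#' minus that position's offset within the motif).
#'
#' @param matches_a data frame from [scan_sequence()] on sequence a.
#' @param seq_b the homologous sequence.
#' @param map an `AlignmentMap` from a to b.
#' @param pwms list of `pwm` objects covering every PWM named in
#'   `matches_a`.
#' @param threshold match threshold in bits for scanning b.
#' @param tolerance allowed distance (bases) between projected and
#'   observed start in b (default 3).
#' @return the conserved subset of `matches_a`, with `b_start` added.
#' @export
map_conserved_motifs <- function(matches_a, seq_b, map, pwms,
                                 threshold = 4, tolerance = 3L) {
  if (!nrow(matches_a)) {
    matches_a$b_start <- integer(0)
    return(matches_a)
  }
  if (any(matches_a$end > map$a_len))
    stop("map_conserved_motifs: match beyond the alignment map range")
  pwms <- stats::setNames(pwms, vapply(pwms, `[[`, "", "name"))
  b_by_pwm <- lapply(pwms, function(p) scan_sequence(p, seq_b, threshold))
  a2b <- rep(NA_integer_, map$a_len)
  a2b[map$pairs$a_pos + 1L] <- map$pairs$b_pos
  keep <- logical(nrow(matches_a))
  b_start <- rep(NA_integer_, nrow(matches_a))
  for (i in seq_len(nrow(matches_a))) {
    s <- matches_a$start[i]; e <- matches_a$end[i]
    L <- e - s
    bpos <- a2b[(s + 1L):e]
    aligned <- which(!is.na(bpos))
    if (length(aligned) < L / 2) next
    proj <- bpos[aligned[1]] - (aligned[1] - 1L)
    mb <- b_by_pwm[[matches_a$pwm[i]]]
    if (is.null(mb) || !nrow(mb)) next
    hit <- which(abs(mb$start - proj) <= tolerance)
    if (length(hit)) {
      keep[i] <- TRUE
      b_start[i] <- mb$start[hit[which.min(abs(mb$start[hit] - proj))]]
    }
  }
  out <- matches_a[keep, , drop = FALSE]
  out$b_start <- b_start[keep]
  out
}

#' Variant pair set: homologous sequences from bound and unbound strains
#'
#' @param loci data frame with `locus_id`, `positive_seq` (bound strain)
#'   and `negative_seq` (unbound strain).
#' @return object of class `VariantPairSet`.
#' @export
variant_pair_set <- function(loci) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("locus_id", "positive_seq", "negative_seq")
  if (!all(req %in% names(loci)))
    stop("variant_pair_set: need columns ", paste(req, collapse = ", "))
  if (!nrow(loci)) stop("variant_pair_set: need >= 1 locus")
  structure(loci[, req], class = c("VariantPairSet", "data.frame"))
}

#' Associate motif mutations with strain-differential binding
#'
#' For each PWM, computes per locus the difference in best PWM score
#' (maximum over windows and strands) between the bound-strain and the
#' unbound-strain sequence, drops zero differences, and applies the
#' two-sided Wilcoxon signed-rank test; p-values are BH-adjusted across
#' motifs. `signed_logp` is `sign(median difference) * -log10(p)`, so
#' positive values indicate motifs whose disruption tracks loss of
#' binding. Motifs with fewer than 6 informative loci are flagged
#' underpowered. When an expression table is supplied, each motif is
#' flagged `expressed` if its cognate TF (PWM name matched
#' case-insensitively to gene ids or symbols) has mean TPM > `tpm_filter`
#' in `focal_group`.
#'
#' @param pairs a `VariantPairSet`.
#' @param pwms list of `pwm` objects.
#' @param expression optional `ExpressionTable` for the expressed flag.
#' @param focal_group group whose TPM gates the expressed flag.
#' @param tpm_filter TPM threshold (default 2).
#' @return list with `results` (data frame: motif, n_informative, W, p,
#'   padj, signed_logp, expressed, underpowered) and `score_diffs`
#'   (loci x motifs matrix of score differences, for clustering).
#' @export
motif_mutation_association <- function(pairs, pwms, expression = NULL,
                                       focal_group = NULL, tpm_filter = 2) {
  if (!nrow(pairs)) stop("motif_mutation_association: no pairs")
  pwm_names <- vapply(pwms, `[[`, "", "name")
  D <- matrix(NA_real_, nrow(pairs), length(pwms),
              dimnames = list(pairs$locus_id, pwm_names))
  for (j in seq_along(pwms)) {
    p <- pwms[[j]]
    D[, j] <- vapply(seq_len(nrow(pairs)), function(i)
      best_pwm_score(p, pairs$positive_seq[i]) -
        best_pwm_score(p, pairs$negative_seq[i]), 0)
  }
  D[!is.finite(D)] <- 0
  rows <- lapply(seq_along(pwms), function(j) {
    d <- D[, j]
    w <- wilcoxon_signed_rank(d)
    nz <- d[d != 0]
    s <- if (length(nz)) sign(stats::median(nz)) else 0
    data.frame(motif = pwm_names[j], n_informative = w$n,
               W = if (is.na(w$W)) NA_real_ else w$W, p = w$p,
               signed_logp = s * -log10(max(w$p, .Machine$double.xmin)),
               underpowered = w$n < 6, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res$expressed <- NA
  if (!is.null(expression)) {
    if (is.null(focal_group)) focal_group <- expression$samples$group[1]
    mt <- group_mean_tpm(expression, focal_group)[, 1]
    keys <- toupper(names(mt))
    res$expressed <- vapply(res$motif, function(m) {
      hit <- which(keys == toupper(m))
      length(hit) > 0 && mt[hit[1]] > tpm_filter
    }, TRUE, USE.NAMES = FALSE)
  }
  res <- res[, c("motif", "n_informative", "W", "p", "padj",
                 "signed_logp", "expressed", "underpowered")]
  list(results = res, score_diffs = D)
}

#' Cluster motifs by correlated score differences
#'
#' Motifs whose per-locus score-difference vectors correlate with Pearson
#' r above `r_threshold` are linked; clusters are the connected components
#' (single linkage). The cluster-level statistic is the mean of member
#' `signed_logp` values, and a cluster is biologically relevant when at
#' least one member's cognate TF is expressed.
#'
#' @param assoc output of [motif_mutation_association()].
#' @param r_threshold correlation threshold (default 0.6, strict `>`).
#' @return the `results` data frame with `cluster`,
#'   `cluster_signed_logp` and `cluster_relevant` columns added.
#' @export
cluster_motifs <- function(assoc, r_threshold = 0.6) {
  res <- assoc$results
  D <- assoc$score_diffs
  m <- ncol(D)
  sds <- apply(D, 2, stats::sd)
  if (any(sds == 0, na.rm = TRUE))
    warning("cluster_motifs: constant score-difference vector(s); ",
            "affected motifs become singletons")
  suppressWarnings(R <- stats::cor(D))
  R[!is.finite(R)] <- 0
  adj <- R > r_threshold
  diag(adj) <- TRUE
  # connected components by BFS
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (v in seq_len(m)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  res$cluster <- comp[match(res$motif, colnames(D))]
  agg <- tapply(res$signed_logp, res$cluster, mean)
  res$cluster_signed_logp <- as.numeric(agg[as.character(res$cluster)])
  if (all(is.na(res$expressed))) {
    res$cluster_relevant <- NA
  } else {
    rel <- tapply(res$expressed, res$cluster, function(x) any(x, na.rm = TRUE))
    res$cluster_relevant <- as.logical(rel[as.character(res$cluster)])
  }
  res
}

#' Write a motif association table as TSV
#'
#' Fixed column order: motif, n, W, p, padj, signed_logp, cluster,
#' cluster_signed_logp, expressed.
#'
#' @param results data frame from [cluster_motifs()] (or the `results`
#'   element of [motif_mutation_association()]).
#' @param path output file.
#' @export
write_motif_results <- function(results, path) {
  df <- data.frame(motif = results$motif, n = results$n_informative,
                   W = results$W, p = results$p, padj = results$padj,
                   signed_logp = results$signed_logp)
  for (col in c("cluster", "cluster_signed_logp", "expressed"))
    if (!is.null(results[[col]])) df[[col]] <- results[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
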