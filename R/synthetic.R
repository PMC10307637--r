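#' Generate a synthetic peak universe with paired gene annotations
#'
#' Places non-overlapping peaks on a regular grid (with jitter) across
#' `n_chroms` chromosomes and pairs each peak with one gene, positioning
#' the TSS so that an exact, configurable fraction of peaks is distal
#' (> 3,000 bp from every TSS): proximal peaks get a TSS 200-2,000 bp from
#' the summit, distal peaks a TSS midway to the next grid point (half the
#' grid spacing away, > 3 kb by construction).
#'
#' @param seed RNG seed; output is a pure function of (seed, arguments).
#' @param n_peaks total peaks (default 2,000).
#' @param n_chroms chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 1e7).
#' @param distal_fraction fraction of peaks made distal (default 0.8).
#' @param peak_width peak width in bp (default 400).
#' @param genome genome label stamped on the output.
#' @return list with `peaks` (`PeakSet`), `genes` (`GeneAnnotation`) and
#'   `truth` (data frame: peak_id, distal, paired_gene).
#' @export
generate_peak_universe <- function(seed, n_peaks = 2000L, n_chroms = 2L,
                                   chrom_length = 1e7, distal_fraction = 0.8,
                                   peak_width = 400L, genome = "synth1") {
  if (n_peaks == 0)
    return(list(peaks = peak_set(data.frame(), genome = genome),
                genes = gene_annotation(data.frame(
                  gene_id = character(), chrom = character(),
                  tss = integer(), length = integer())),
                truth = data.frame()))
  per_chrom <- ceiling(n_peaks / n_chroms)
  spacing <- floor(chrom_length / per_chrom)
  if (spacing < max(peak_width + 200, 8000))
    stop("generate_peak_universe: infeasible packing; increase chrom_length ",
         "or reduce n_peaks (grid spacing ", spacing, " bp is too small)")
  with_preserved_seed(seed, {
    rows <- list(); generows <- list()
    k <- 0L
    for (ch in seq_len(n_chroms)) {
      n_here <- min(per_chrom, n_peaks - (ch - 1L) * per_chrom)
      if (n_here <= 0) break
      center <- as.integer((seq_len(n_here) - 0.5) * spacing)
      jit <- as.integer(round(stats::runif(n_here, -spacing / 8, spacing / 8)))
      summit <- center + jit
      ids <- sprintf("peak_%05d", k + seq_len(n_here))
      rows[[ch]] <- data.frame(
        chrom = paste0("chr", ch),
        start = summit - peak_width %/% 2L,
        end = summit + peak_width %/% 2L,
        peak_id = ids, summit = summit, stringsAsFactors = FALSE)
      k <- k + n_here
    }
    peaks_df <- do.call(rbind, rows)
    n <- nrow(peaks_df)
    n_distal <- round(distal_fraction * n)
    distal <- rep(FALSE, n)
    distal[sample.int(n, n_distal)] <- TRUE
    off <- integer(n)
    prox_off <- as.integer(round(stats::runif(n, 200, 2000))) *
      sample(c(-1L, 1L), n, replace = TRUE)
    off[!distal] <- prox_off[!distal]
    # distal TSS at the midpoint of the (jittered) gap to the next peak, so
    # it stays > 3 kb from both flanking summits and the count is exact
    for (ch in unique(peaks_df$chrom)) {
      ii <- which(peaks_df$chrom == ch)
      s <- peaks_df$summit[ii]
      nxt <- c(s[-1], s[length(s)] + spacing)
      off[ii][distal[ii]] <- as.integer((nxt - s) %/% 2L)[distal[ii]]
    }
    genes_df <- data.frame(
      gene_id = sprintf("gene_%05d", seq_len(n)),
      chrom = peaks_df$chrom,
      tss = peaks_df$summit + off,
      length = as.integer(round(exp(stats::runif(n, log(500), log(5000))))),
      stringsAsFactors = FALSE)
    genes_df$tss <- pmax(genes_df$tss, 0L)
    list(peaks = peak_set(peaks_df, name = "synthetic_peaks", genome = genome),
         genes = gene_annotation(genes_df),
         truth = data.frame(peak_id = peaks_df$peak_id, distal = distal,
                            paired_gene = genes_df$gene_id,
                            stringsAsFactors = FALSE))
  })
}

#' Plant the four enhancer classes onto a peak universe
#'
#' Assigns each peak a planted class (the four TF-binding x H3K27ac-change
#' combinations, or null) and derives the planted H3K27ac log2 fold change
#' (knockout over wild type) and TF-bound status. Activated classes lose
#' acetylation in the knockout (negative log2fc), repressed classes gain
#' it. A fraction of null peaks is also TF-bound, so binding alone never
#' separates the classes.
#'
#' @param seed RNG seed.
#' @param peak_ids character vector of peak ids.
#' @param class_fractions named fractions for the four classes (remainder
#'   is null).
#' @param effect_log2fc magnitude of the planted H3K27ac change (default 2,
#'   i.e. 4-fold).
#' @param null_bound_fraction fraction of null peaks that are TF-bound.
#' @return data frame: peak_id, planted_class, planted_lfc, tf_bound.
#' @export
plant_enhancer_classes <- function(seed, peak_ids,
                                   class_fractions = c(
                                     direct_activated = 0.10,
                                     direct_repressed = 0.10,
                                     indirect_activated = 0.10,
                                     indirect_repressed = 0.10),
                                   effect_log2fc = 2,
                                   null_bound_fraction = 0.2) {
  n <- length(peak_ids)
  counts <- round(class_fractions * n)
  with_preserved_seed(seed, {
    cls <- rep("null", n)
    idx <- sample.int(n)
    at <- 0L
    for (cl in names(counts)) {
      if (counts[cl] > 0) cls[idx[at + seq_len(counts[cl])]] <- cl
      at <- at + counts[cl]
    }
    lfc <- numeric(n)
    lfc[cls %in% c("direct_activated", "indirect_activated")] <- -effect_log2fc
    lfc[cls %in% c("direct_repressed", "indirect_repressed")] <- effect_log2fc
    bound <- cls %in% c("direct_activated", "direct_repressed")
    nulls <- which(cls == "null")
    bound[sample(nulls, round(null_bound_fraction * length(nulls)))] <- TRUE
    data.frame(peak_id = peak_ids, planted_class = cls, planted_lfc = lfc,
               tf_bound = bound, stringsAsFactors = FALSE)
  })
}

#' Generate negative-binomial counts with planted fold changes
#'
#' Per-feature baseline means are log-normal around `base_mean`; the
#' planted log2 fold change applies to the second condition. Library size
#' factors are log-normal, and `total_tags` is set so the tags-per-1e7
#' normalized view of a feature with baseline mean `base_mean` sits near
#' `2 * base_mean`. Dispersion 0 gives Poisson counts.
#'
#' @param seed RNG seed.
#' @param planted_log2fc numeric vector, one per feature, named by feature
#'   id (names become rownames).
#' @param n_reps replicates per condition (default 2).
#' @param conditions two condition labels (fold change applies to the
#'   second).
#' @param base_mean baseline mean count (default 100).
#' @param dispersion NB dispersion alpha (default 0.05).
#' @param mean_sdlog spread of per-feature baseline means on the log scale.
#' @param libsize_sdlog spread of library size factors on the log scale.
#' @return list with `matrix` (a `CountMatrix`) and `truth` (data frame of
#'   per-feature baseline mean and planted log2fc).
#' @export
generate_counts <- function(seed, planted_log2fc, n_reps = 2L,
                            conditions = c("wt", "ko"), base_mean = 100,
                            dispersion = 0.05, mean_sdlog = 0.5,
                            libsize_sdlog = 0.15) {
  nfeat <- length(planted_log2fc)
  ids <- names(planted_log2fc)
  if (is.null(ids)) ids <- sprintf("feat_%05d", seq_len(nfeat))
  with_preserved_seed(seed, {
    mu0 <- base_mean * exp(stats::rnorm(nfeat, 0, mean_sdlog))
    sf <- exp(stats::rnorm(2L * n_reps, 0, libsize_sdlog))
    counts <- matrix(0L, nfeat, 2L * n_reps)
    cond <- rep(conditions, each = n_reps)
    for (j in seq_len(ncol(counts))) {
      mu <- mu0 * sf[j]
      if (cond[j] == conditions[2]) mu <- mu * 2^planted_log2fc
      counts[, j] <- rnbinom_disp(nfeat, mu, dispersion)
    }
    rownames(counts) <- ids
    samples <- data.frame(
      sample_id = paste0(cond, "_rep", rep(seq_len(n_reps), 2)),
      condition = cond, stringsAsFactors = FALSE)
    m <- count_matrix(counts, samples,
                      total_tags = round(5e6 * sf))
    list(matrix = m,
         truth = data.frame(feature_id = ids, base_mean = mu0,
                            planted_lfc = unname(planted_log2fc),
                            stringsAsFactors = FALSE))
  })
}

#' Derive a TF binding peak set (with replicates) from planted truth
#'
#' Builds replicate ChIP-seq-style peak calls for the TF: every planted
#' TF-bound peak appears in each replicate with a jittered summit and
#' log-normal signal; a fraction of irreproducible peaks is added to each
#' replicate at random positions so the reproducibility filter has work to
#' do.
#'
#' @param seed RNG seed.
#' @param peaks the `PeakSet` the truth refers to.
#' @param tf_bound logical vector, one per peak.
#' @param n_reps replicates (default 2).
#' @param summit_jitter max summit jitter per replicate (bp).
#' @param irreproducible_fraction extra replicate-private peaks, as a
#'   fraction of the bound count.
#' @param width TF peak width.
#' @return list of `PeakSet` replicates.
#' @export
generate_tf_replicates <- function(seed, peaks, tf_bound, n_reps = 2L,
                                   summit_jitter = 30L,
                                   irreproducible_fraction = 0.1,
                                   width = 200L) {
  bound <- which(tf_bound)
  with_preserved_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      summit <- peaks$summit[bound] +
        sample(seq(-summit_jitter, summit_jitter), length(bound), replace = TRUE)
      score <- exp(stats::rnorm(length(bound), log(50), 0.4))
      df <- data.frame(chrom = peaks$chrom[bound],
                       start = summit - width %/% 2L,
                       end = summit + width %/% 2L,
                       summit = summit, score = score,
                       stringsAsFactors = FALSE)
      n_extra <- round(irreproducible_fraction * length(bound))
      if (n_extra > 0) {
        # replicate-private noise peaks, placed off-grid between real peaks
        pick <- sample(seq_len(nrow(peaks)), n_extra)
        esummit <- peaks$summit[pick] + 4000L + r * 500L
        df <- rbind(df, data.frame(chrom = peaks$chrom[pick],
                                   start = esummit - width %/% 2L,
                                   end = esummit + width %/% 2L,
                                   summit = esummit,
                                   score = exp(stats::rnorm(n_extra, log(10), 0.3))))
      }
      df <- df[order(df$chrom, df$start), ]
      df$peak_id <- sprintf("tf_rep%d_%05d", r, seq_len(nrow(df)))
      peak_set(df, name = paste0("tf_rep", r), genome = set_genome(peaks))
    })
  })
}

#' Scatter count-matrix tags into per-sample tag libraries
#'
#' Places each counted tag at a position uniform within the counting
#' window around its peak's summit, so window quantification recovers the
#' planted counts exactly, and pads each library with off-peak background
#' tags up to the matrix's `total_tags`.
#'
#' @param seed RNG seed.
#' @param peaks `PeakSet` matching the matrix features.
#' @param m a `CountMatrix` with planted counts.
#' @param window counting window the tags must fall in (bp).
#' @param chrom_length chromosome length for background tags.
#' @return list of `TagLibrary`, one per sample.
#' @export
generate_tag_libraries <- function(seed, peaks, m, window = 1000L,
                                   chrom_length = 1e7) {
  half <- window %/% 2L
  with_preserved_seed(seed, {
    lapply(seq_len(ncol(m$counts)), function(j) {
      k <- m$counts[, j]
      pos <- peaks$summit[rep.int(seq_along(k), k)] +
        sample(seq(-half + 1L, half - 2L), sum(k), replace = TRUE)
      chrom <- peaks$chrom[rep.int(seq_along(k), k)]
      n_bg <- max(0, m$total_tags[j] - sum(k))
      if (n_bg > 0) {
        # background tags midway between grid peaks, outside every window
        bg_chrom <- sample(unique(peaks$chrom), n_bg, replace = TRUE)
        bg_pos <- integer(n_bg)
        for (ch in unique(bg_chrom)) {
          ii <- bg_chrom == ch
          anchors <- peaks$summit[peaks$chrom == ch]
          a <- sample(anchors, sum(ii), replace = TRUE)
          bg_pos[ii] <- a + 3500L + sample.int(500L, sum(ii), replace = TRUE)
        }
        chrom <- c(chrom, bg_chrom); pos <- c(pos, bg_pos)
      }
      tag_library(split(pos, chrom),
                  sample_id = m$samples$sample_id[j],
                  condition = m$samples$condition[j])
    })
  })
}

#' Constructed super-enhancer fixture with a known elbow
#'
#' Peaks placed far apart (one per stitched region) with a hockey-stick
#' signal profile: `n_super` high signals well above a shallow tail, so
#' the rank-signal elbow flags exactly the planted regions.
#'
#' @param n_regions total regions (default 50).
#' @param n_super planted super-enhancers (default 2).
#' @param genome genome label.
#' @return list with `peaks` (`PeakSet`) and `truth` (logical vector,
#'   TRUE for planted supers, aligned with the peaks).
#' @export
super_enhancer_fixture <- function(n_regions = 50L, n_super = 2L,
                                   genome = "synth1") {
  signal <- c(seq(1000, 900, length.out = n_super),
              seq(10, 1, length.out = n_regions - n_super))
  start <- (seq_len(n_regions) - 1L) * 50000L
  peaks <- peak_set(data.frame(
    chrom = "chr1", start = start, end = start + 1000L,
    peak_id = sprintf("se_%03d", seq_len(n_regions)),
    score = signal, stringsAsFactors = FALSE),
    name = "se_fixture", genome = genome)
  list(peaks = peaks, truth = c(rep(TRUE, n_super),
                                rep(FALSE, n_regions - n_super)))
}

#' Mutate the strongest match of a PWM in a sequence
#'
#' Replaces the bases at the highest-information positions of the best
#' motif match with each position's least likely base, destroying the
#' match.
#'
#' @param seq DNA string containing a match.
#' @param p the `pwm` to disrupt.
#' @param n_positions number of positions to mutate (default 3).
#' @return the mutated sequence.
#' @export
disrupt_motif <- function(seq, p, n_positions = 3L) {
  L <- pwm_length(p)
  code <- seq_codes(seq)
  fwd <- scan_one_strand(pwm_logodds(p), code, L)
  rev <- scan_one_strand(pwm_logodds(pwm_revcomp(p)), code, L)
  if (max(fwd, -Inf) >= max(rev, -Inf)) {
    at <- which.max(fwd); mat <- p$probs
  } else {
    at <- which.max(rev); mat <- pwm_revcomp(p)$probs
  }
  info <- apply(mat, 2, max)
  target <- order(info, decreasing = TRUE)[seq_len(min(n_positions, L))]
  chars <- strsplit(seq, "")[[1]]
  for (t in target)
    chars[at + t - 1L] <- DNA_BASES[which.min(mat[, t])]
  paste(chars, collapse = "")
}

#' Generate strain sequence pairs with motif-disrupting variants
#'
#' Emulates strain-differential TF binding loci: each positive (bound
#' strain) sequence is random DNA with the causal motif's consensus
#' planted at a random interior position; the negative (unbound strain)
#' homolog carries background SNPs and, with probability `mutation_rate`,
#' disrupting substitutions at the causal motif.
#'
#' @param seed RNG seed.
#' @param n_loci number of locus pairs (default 100).
#' @param causal_pwm the `pwm` whose disruption drives the labels.
#' @param mutation_rate probability the causal site is disrupted in the
#'   negative sequence (default 0.8).
#' @param seq_len sequence length (default 200).
#' @param snp_rate per-base background substitution rate (default 0.01).
#' @return list with `pairs` (a `VariantPairSet`) and `truth` (data frame:
#'   locus_id, causal_mutated, motif_start).
#' @export
generate_strain_pairs <- function(seed, n_loci = 100L, causal_pwm,
                                  mutation_rate = 0.8, seq_len = 200L,
                                  snp_rate = 0.01) {
  cons <- pwm_consensus(causal_pwm)
  L <- nchar(cons)
  with_preserved_seed(seed, {
    pos_seq <- character(n_loci); neg_seq <- character(n_loci)
    mutated <- logical(n_loci); at <- integer(n_loci)
    for (i in seq_len(n_loci)) {
      s <- random_dna(seq_len)
      at[i] <- sample.int(seq_len - L - 20L, 1) + 10L
      substr(s, at[i], at[i] + L - 1L) <- cons
      pos_seq[i] <- s
      neg <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(seq_len) < snp_rate)
      for (h in hit) neg[h] <- sample(setdiff(DNA_BASES, neg[h]), 1)
      neg <- paste(neg, collapse = "")
      mutated[i] <- stats::runif(1) < mutation_rate
      if (mutated[i]) neg <- disrupt_motif(neg, causal_pwm)
      neg_seq[i] <- neg
    }
    ids <- sprintf("locus_%04d", seq_len(n_loci))
    list(pairs = variant_pair_set(data.frame(
           locus_id = ids, positive_seq = pos_seq, negative_seq = neg_seq,
           stringsAsFactors = FALSE)),
         truth = data.frame(locus_id = ids, causal_mutated = mutated,
                            motif_start = at - 1L, stringsAsFactors = FALSE))
  })
}

#' Generate a random informative PWM
#'
#' Columns are drawn from a sparse Dirichlet, biased toward one dominant
#' base per position, giving decoy motifs realistic information content.
#'
#' @param seed RNG seed.
#' @param length motif length (default 8).
#' @param name motif name.
#' @param concentration dominant-base weight (larger = sharper motif).
#' @return a `pwm`.
#' @export
random_pwm <- function(seed, length = 8L, name = "random",
                       concentration = 8) {
  with_preserved_seed(seed, {
    cols <- sapply(seq_len(length), function(i) {
      a <- rep(0.5, 4)
      a[sample.int(4, 1)] <- concentration
      g <- stats::rgamma(4, a)
      g / sum(g)
    })
    pwm(cols, name = name)
  })
}

#' Generate a synthetic expression table with planted structure
#'
#' Emulates the cell-type comparison: a focal cell type (two conditions,
#' `focal` and `focal_ko`) and `n_other_groups` comparison subtypes.
#' Signature genes are elevated `signature_fold`-fold in both focal
#' conditions; DEGs change `deg_fold`-fold between `focal` and `focal_ko`
#' (half up in the knockout, half down). Counts are negative binomial.
#'
#' @param seed RNG seed.
#' @param n_genes total genes (default 5,000).
#' @param n_signature planted signature genes (default 300).
#' @param n_deg planted DEGs (default 400).
#' @param n_other_groups comparison cell types (default 7).
#' @param n_reps replicates per group (default 3).
#' @param base_mean baseline mean count.
#' @param dispersion NB dispersion (default 0.1).
#' @param signature_fold planted focal elevation (default 50).
#' @param deg_fold planted knockout fold change (default 4).
#' @return list with `table` (an `ExpressionTable`) and `truth` (data
#'   frame: gene_id, signature, deg in up/down/none).
#' @export
generate_expression <- function(seed, n_genes = 5000L, n_signature = 300L,
                                n_deg = 400L, n_other_groups = 7L,
                                n_reps = 3L, base_mean = 100,
                                dispersion = 0.1, signature_fold = 50,
                                deg_fold = 4) {
  if (n_signature + n_deg > n_genes)
    stop("generate_expression: n_signature + n_deg must be <= n_genes")
  groups <- c("focal", "focal_ko", paste0("other", seq_len(n_other_groups)))
  with_preserved_seed(seed, {
    ids <- sprintf("gene_%05d", seq_len(n_genes))
    lengths <- as.integer(round(exp(stats::runif(n_genes, log(500), log(5000)))))
    mu0 <- base_mean * exp(stats::rnorm(n_genes, 0, 0.8))
    sig_idx <- seq_len(n_signature)
    deg_idx <- n_signature + seq_len(n_deg)
    deg_dir <- rep(c("up", "down"), length.out = n_deg)
    # planted effects need measurable baselines; signature genes start from
    # a modest baseline so their elevation does not dominate the library
    mu0[sig_idx] <- 20 * exp(stats::rnorm(n_signature, 0, 0.3))
    mu0[deg_idx] <- pmax(mu0[deg_idx], 50)
    mu_of <- function(g) {
      mu <- mu0
      if (g %in% c("focal", "focal_ko")) {
        mu[sig_idx] <- mu[sig_idx] * signature_fold
      }
      if (g == "focal_ko") {
        mu[deg_idx[deg_dir == "up"]] <- mu[deg_idx[deg_dir == "up"]] * deg_fold
        mu[deg_idx[deg_dir == "down"]] <- mu[deg_idx[deg_dir == "down"]] / deg_fold
      }
      mu
    }
    cols <- list(); samp <- list()
    for (g in groups) {
      mu <- mu_of(g)
      for (r in seq_len(n_reps)) {
        sf <- exp(stats::rnorm(1, 0, 0.1))
        cols[[length(cols) + 1L]] <- rnbinom_disp(n_genes, mu * sf, dispersion)
        samp[[length(samp) + 1L]] <- data.frame(
          sample_id = paste0(g, "_rep", r), group = g,
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- ids
    table <- compute_tpm(counts, lengths, do.call(rbind, samp))
    deg <- rep("none", n_genes)
    deg[deg_idx] <- deg_dir
    list(table = table,
         truth = data.frame(gene_id = ids,
                            signature = seq_len(n_genes) %in% sig_idx,
                            deg = deg, stringsAsFactors = FALSE))
  })
}
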