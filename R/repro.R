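#' Replicate-consistent peak filtering
#'
#' A deterministic reproducibility filter over replicate peak calls,
#' playing the role the IDR cutoff plays in replicate ChIP-seq/ATAC-seq
#' analysis: a peak survives only when every pairwise replicate comparison
#' contains a matching peak (summits within `summit_dist` bases on the same
#' chromosome) and every member of the matched group lies within the top
#' `rank_fraction` of its own replicate when ranked by signal (`score`).
#'
#' Surviving groups are collapsed to a single record: interval = union of
#' member intervals, summit = signal-weighted mean of member summits,
#' score = mean member score.
#'
#' @param replicates list of >= 2 `PeakSet`s from the same condition.
#' @param summit_dist maximum summit-to-summit distance for a match (bp).
#' @param rank_fraction fraction of top-ranked peaks (by score, rank 1 =
#'   strongest) eligible in each replicate.
#' @param name,genome labels for the output set; genome defaults to the
#'   first replicate's label.
#' @return a `PeakSet` of reproducible peaks.
#' @export
reproducible_peaks <- function(replicates, summit_dist = 100L,
                               rank_fraction = 0.9,
                               name = "reproducible", genome = NULL) {
  if (length(replicates) < 2)
    stop("reproducible_peaks: need >= 2 replicates; for a single replicate ",
         "pass it through unfiltered explicitly")
  for (i in seq_along(replicates)[-1])
    check_same_genome(replicates[[1]], replicates[[i]])
  if (is.null(genome)) genome <- set_genome(replicates[[1]])

  eligible <- lapply(replicates, function(r) {
    if (!nrow(r)) return(r)
    rk <- rank(-r$score, ties.method = "first")
    keep <- rk <= ceiling(rank_fraction * nrow(r))
    r[keep, , drop = FALSE]
  })
  anchor <- eligible[[1]]
  if (!nrow(anchor))
    return(peak_set(data.frame(), name = name, genome = genome))

  groups <- vector("list", nrow(anchor))
  for (i in seq_len(nrow(anchor))) {
    members <- list(anchor[i, , drop = FALSE])
    ok <- TRUE
    for (j in seq_along(eligible)[-1]) {
      r <- eligible[[j]]
      cand <- which(r$chrom == anchor$chrom[i] &
                    abs(r$summit - anchor$summit[i]) <= summit_dist)
      if (!length(cand)) { ok <- FALSE; break }
      best <- cand[which.min(abs(r$summit[cand] - anchor$summit[i]))]
      members[[j]] <- r[best, , drop = FALSE]
    }
    if (!ok) next
    m <- do.call(rbind, members)
    # strict all-pairs check: every pair of matched summits within summit_dist
    if (max(m$summit) - min(m$summit) > summit_dist) next
    groups[[i]] <- m
  }
  groups <- groups[!vapply(groups, is.null, TRUE)]
  if (!length(groups))
    return(peak_set(data.frame(), name = name, genome = genome))
  merged <- do.call(rbind, lapply(groups, function(m) {
    w <- if (sum(m$score) > 0) m$score / sum(m$score) else rep(1 / nrow(m), nrow(m))
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               summit = as.integer(round(sum(w * m$summit))),
               score = mean(m$score), stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  merged$peak_id <- paste0(name, "_", seq_len(nrow(merged)))
  peak_set(merged, name = name, genome = genome)
}

#' Merge peak sets, unioning overlapping records
#'
#' Overlapping (transitively chained) peaks across all input sets collapse
#' into single records spanning their union; the merged score is the
#' maximum constituent score (preserving the strongest evidence at the
#' locus) and the merged summit is the summit of that strongest
#' constituent.
#'
#' @param sets list of >= 1 `PeakSet`s on the same genome label.
#' @param name label for the merged set.
#' @return a `PeakSet`.
#' @export
merge_pairwise_sets <- function(sets, name = "merged") {
  if (!length(sets)) stop("merge_pairwise_sets: need >= 1 set")
  for (i in seq_along(sets)[-1]) check_same_genome(sets[[1]], sets[[i]])
  genome <- set_genome(sets[[1]])
  all <- do.call(rbind, lapply(sets, as.data.frame))
  if (is.null(all) || !nrow(all))
    return(peak_set(data.frame(), name = name, genome = genome))
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  # min.gapwidth = 0: abutting half-open intervals do not merge
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  best <- tapply(seq_len(nrow(all)), grp, function(idx) idx[which.max(all$score[idx])])
  merged <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    score = all$score[unlist(best)],
    summit = all$summit[unlist(best)],
    stringsAsFactors = FALSE)
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  merged$peak_id <- paste0(name, "_", seq_len(nrow(merged)))
  peak_set(merged, name = name, genome = genome)
}

#' Strain-differential peak sets
#'
#' Defines, for two strains (or conditions), the peaks reproducible in one
#' strain with zero overlap against the peaks reproducible in the other —
#' the input loci for motif-mutation association.
#'
#' @param replicates_a,replicates_b lists of replicate `PeakSet`s per strain.
#' @param strain_a,strain_b labels.
#' @param ... passed to [reproducible_peaks()].
#' @return list with `reproducible_a`, `reproducible_b`, `differential_a`,
#'   `differential_b` (each a `PeakSet`) and the strain labels.
#' @export
strain_differential <- function(replicates_a, replicates_b,
                                strain_a = "strainA", strain_b = "strainB",
                                ...) {
  ra <- reproducible_peaks(replicates_a, name = paste0(strain_a, "_repro"), ...)
  rb <- reproducible_peaks(replicates_b, name = paste0(strain_b, "_repro"), ...)
  subset_nonoverlapping <- function(x, y, nm) {
    if (!nrow(x)) return(peak_set(data.frame(), name = nm, genome = set_genome(x)))
    flags <- overlap_peaks(x, y, min_bp = 1L)$flags
    out <- x[!flags, , drop = FALSE]
    attr(out, "name") <- nm
    attr(out, "genome") <- set_genome(x)
    class(out) <- class(x)
    out
  }
  list(strain_a = strain_a, strain_b = strain_b,
       reproducible_a = ra, reproducible_b = rb,
       differential_a = subset_nonoverlapping(ra, rb, paste0(strain_a, "_only")),
       differential_b = subset_nonoverlapping(rb, ra, paste0(strain_b, "_only")))
}
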