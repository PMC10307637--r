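#' Flag peaks of one set overlapping another
#'
#' For each peak in `a`, reports whether some peak in `b` shares at least
#' `min_bp` bases with it (intervals are 0-based half-open, so abutting
#' intervals do not overlap). Also reports the symmetric counts in both
#' directions.
#'
#' @param a,b `PeakSet`s on the same genome label.
#' @param min_bp minimum shared bases to count as an overlap (default 1).
#' @return list with `flags` (logical, one per peak of `a`, named by
#'   peak_id), `n_a_overlapping`, `n_b_overlapping`.
#' @export
overlap_peaks <- function(a, b, min_bp = 1L) {
  check_same_genome(a, b)
  if (min_bp < 1) stop("overlap_peaks: min_bp must be >= 1")
  flag_one_way <- function(x, y) {
    if (!nrow(x) || !nrow(y)) return(stats::setNames(rep(FALSE, nrow(x)), x$peak_id))
    hits <- GenomicRanges::findOverlaps(peaks_granges(x), peaks_granges(y),
                                        minoverlap = as.integer(min_bp))
    f <- rep(FALSE, nrow(x))
    f[unique(S4Vectors::queryHits(hits))] <- TRUE
    stats::setNames(f, x$peak_id)
  }
  fa <- flag_one_way(a, b)
  fb <- flag_one_way(b, a)
  list(flags = fa, n_a_overlapping = sum(fa), n_b_overlapping = sum(fb))
}

#' Assign each peak its nearest gene by summit-to-TSS distance
#'
#' Distance is signed: `summit - tss`. Nearest is by absolute distance,
#' restricted to genes on the peak's chromosome; ties break to the
#' lexicographically smaller `gene_id`. Peaks on chromosomes with no
#' annotated gene get `gene_id = NA` and are counted in `n_unassigned`
#' rather than dropped.
#'
#' @param peaks a `PeakSet`.
#' @param genes a `GeneAnnotation`.
#' @return data frame with `peak_id`, `gene_id`, `distance` (signed,
#'   summit minus TSS; NA when unassigned).
#' @export
nearest_gene <- function(peaks, genes) {
  res <- data.frame(peak_id = peaks$peak_id,
                    gene_id = NA_character_,
                    distance = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!nrow(peaks)) return(res)
  for (chr in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(g)) next
    # order genes by TSS then gene_id so equidistant ties resolve by id
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    for (i in pi) {
      d <- peaks$summit[i] - g$tss
      ad <- abs(d)
      cand <- which(ad == min(ad))
      best <- cand[order(g$gene_id[cand])][1]
      res$gene_id[i] <- g$gene_id[best]
      res$distance[i] <- d[best]
    }
  }
  res
}

#' Keep peaks distal to all transcription start sites
#'
#' Retains peaks whose summit lies strictly more than `min_tss_distance`
#' bases from the nearest TSS (default 3,000 bp, the conventional cutoff
#' separating promoter-proximal from distal regulatory elements). Peaks on
#' chromosomes without genes cannot be assigned a distance and are dropped
#' with a warning.
#'
#' @param peaks a `PeakSet`.
#' @param genes a `GeneAnnotation`.
#' @param min_tss_distance distance threshold in bases (strict `>`).
#' @return filtered `PeakSet`.
#' @export
filter_distal <- function(peaks, genes, min_tss_distance = 3000L) {
  if (!nrow(peaks)) return(peaks)
  ng <- nearest_gene(peaks, genes)
  unassigned <- is.na(ng$distance)
  if (any(unassigned))
    warning(sum(unassigned), " peak(s) on chromosomes without genes dropped")
  keep <- !unassigned & abs(ng$distance) > min_tss_distance
  out <- peaks[keep, , drop = FALSE]
  attr(out, "name") <- attr(peaks, "name")
  attr(out, "genome") <- attr(peaks, "genome")
  class(out) <- class(peaks)
  out
}
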