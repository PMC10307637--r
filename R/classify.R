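#' Select active enhancers by an H3K27ac activity floor
#'
#' Keeps peaks whose normalized H3K27ac signal (tags per 1e7 in a window
#' around the peak center) exceeds `floor` in at least one condition;
#' strictly greater than, default floor 16 normalized tags.
#'
#' @param peaks a `PeakSet` (typically distal ATAC peaks).
#' @param h3k27ac a `CountMatrix` quantified over exactly these peaks.
#' @param floor activity floor on the tags-per-1e7 scale.
#' @return the retained `PeakSet`, with per-condition mean normalized
#'   signal attached as attribute `condition_means`.
#' @export
select_active_enhancers <- function(peaks, h3k27ac, floor = 16) {
  if (!identical(rownames(h3k27ac$counts), peaks$peak_id))
    stop("select_active_enhancers: count matrix features do not match peak set")
  norm <- normalized_counts(h3k27ac)
  cond <- h3k27ac$samples$condition
  cm <- sapply(unique(cond), function(g)
    rowMeans(norm[, cond == g, drop = FALSE]))
  keep <- apply(cm, 1, max) > floor
  out <- peaks[keep, , drop = FALSE]
  attr(out, "name") <- paste0(attr(peaks, "name"), "_active")
  attr(out, "genome") <- set_genome(peaks)
  class(out) <- class(peaks)
  attr(out, "condition_means") <- cm[keep, , drop = FALSE]
  out
}

#' Classify enhancers by TF binding and differential H3K27ac
#'
#' The four-class taxonomy of enhancer regulation by a transcription
#' factor, from the joint pattern of TF binding and the H3K27ac change in
#' the knockout: a bound enhancer losing acetylation is consistent with
#' direct activation by the factor; a bound enhancer gaining acetylation
#' with direct repression; the unbound counterparts with indirect
#' regulation. Peaks with unchanged H3K27ac stay unclassified.
#'
#' @param active a `PeakSet` of active enhancers.
#' @param diff a `DiffResult` with `verdict` (from
#'   [call_differential_peaks()]) covering every peak of `active`;
#'   `up`/`down` refer to the knockout relative to wild type.
#' @param tf_peaks `PeakSet` of TF binding sites (wild type).
#' @param genes optional `GeneAnnotation` for nearest-gene assignment.
#' @return data frame of class `EnhancerRecord`: peak coordinates,
#'   `tf_bound`, `diff_verdict`, `enh_class`, and `nearest_gene` /
#'   `tss_distance` when `genes` is given.
#' @export
classify_enhancers <- function(active, diff, tf_peaks, genes = NULL) {
  idx <- match(active$peak_id, diff$feature_id)
  if (anyNA(idx))
    stop("classify_enhancers: peaks missing from differential results: ",
         paste(utils::head(active$peak_id[is.na(idx)], 5), collapse = ", "))
  if (is.null(diff$verdict))
    stop("classify_enhancers: run call_differential_peaks() first")
  verdict <- as.character(diff$verdict)[idx]
  bound <- overlap_peaks(active, tf_peaks, min_bp = 1L)$flags
  cls <- rep("unclassified", nrow(active))
  cls[bound & verdict == "down"] <- "direct_activated"
  cls[bound & verdict == "up"] <- "direct_repressed"
  cls[!bound & verdict == "down"] <- "indirect_activated"
  cls[!bound & verdict == "up"] <- "indirect_repressed"
  rec <- data.frame(peak_id = active$peak_id, chrom = active$chrom,
                    start = active$start, end = active$end,
                    summit = active$summit,
                    tf_bound = unname(bound), diff_verdict = verdict,
                    log2fc = diff$log2fc[idx], padj = diff$padj[idx],
                    enh_class = factor(cls, levels = c(
                      "direct_activated", "direct_repressed",
                      "indirect_activated", "indirect_repressed",
                      "unclassified")),
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    ng <- nearest_gene(active, genes)
    rec$nearest_gene <- ng$gene_id
    rec$tss_distance <- ng$distance
  }
  class(rec) <- c("EnhancerRecord", "data.frame")
  rec
}

#' Call super-enhancers by stitching and a rank-signal elbow
#'
#' ROSE-style super-enhancer detection: peaks within `stitch_bp` of each
#' other (edge to edge) are stitched into regions (optionally excluding
#' peaks within `tss_exclusion` bp of a TSS first); regions are ranked by
#' summed constituent signal; with both the rank axis and the signal axis
#' scaled to \[0, 1\], the elbow is the last point at which the slope of
#' the signal-vs-rank curve is <= 1, and regions with signal above the
#' elbow are flagged super.
#'
#' @param peaks a `PeakSet` scored with H3K27ac signal in `score`.
#' @param stitch_bp stitching distance (default 12,500 bp).
#' @param tss_exclusion drop peaks whose summit is within this many bp of a
#'   TSS before stitching (default 0 = keep all); needs `genes`.
#' @param genes `GeneAnnotation`, only used when `tss_exclusion > 0`.
#' @return data frame of class `SuperEnhancer`: region coordinates,
#'   `n_constituents`, `constituents` (comma-separated peak ids),
#'   `total_signal`, `rank` (1 = highest signal), `is_super`.
#' @export
call_super_enhancers <- function(peaks, stitch_bp = 12500L,
                                 tss_exclusion = 0L, genes = NULL) {
  p <- as.data.frame(peaks)
  if (tss_exclusion > 0) {
    if (is.null(genes)) stop("call_super_enhancers: tss_exclusion needs genes")
    ng <- nearest_gene(peaks, genes)
    p <- p[is.na(ng$distance) | abs(ng$distance) > tss_exclusion, , drop = FALSE]
  }
  if (!nrow(p))
    return(structure(data.frame(), class = c("SuperEnhancer", "data.frame")))
  p <- p[order(p$chrom, p$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(stitch_bp) + 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(ov)
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_constituents = as.integer(table(factor(grp, levels = seq_along(red)))),
    constituents = vapply(seq_along(red), function(i)
      paste(p$peak_id[grp == i], collapse = ","), ""),
    total_signal = vapply(seq_along(red), function(i)
      sum(p$score[grp == i]), 0),
    stringsAsFactors = FALSE)
  regions$rank <- as.integer(rank(-regions$total_signal, ties.method = "first"))
  regions$is_super <- FALSE
  n <- nrow(regions)
  if (n < 3) {
    warning("call_super_enhancers: fewer than 3 stitched regions; ",
            "elbow undefined, no super-enhancers flagged")
  } else {
    cutoff <- elbow_cutoff(regions$total_signal)
    if (is.finite(cutoff)) regions$is_super <- regions$total_signal > cutoff
  }
  regions <- regions[order(regions$rank), , drop = FALSE]
  rownames(regions) <- NULL
  class(regions) <- c("SuperEnhancer", "data.frame")
  regions
}

# Elbow of the ascending rank-vs-signal curve with both axes scaled to
# [0,1]: signal value at the last point where the discrete slope is <= 1.
# Returns Inf (nothing above) when the curve is degenerate (all equal) or
# the slope never exceeds 1.
elbow_cutoff <- function(signal) {
  y <- sort(signal)
  n <- length(y)
  rng <- y[n] - y[1]
  if (rng <= 0) return(Inf)
  ys <- (y - y[1]) / rng
  xs <- (seq_len(n) - 1) / (n - 1)
  slope <- diff(ys) / diff(xs)  # slope of segment i -> i+1
  below <- which(slope <= 1)
  if (!length(below) || max(below) == n - 1) return(Inf)
  y[max(below) + 1]
}

#' Per-class nearest-gene report with DEG overlap enrichment
#'
#' For each enhancer class, collects the deduplicated nearest genes of its
#' members, counts how many are up- or downregulated genes, and reports
#' one-tailed Fisher (hypergeometric upper-tail) enrichment p-values per
#' direction against an explicitly supplied gene universe.
#'
#' @param records an `EnhancerRecord` data frame with `nearest_gene`.
#' @param up_genes,down_genes disjoint character vectors of DEG ids.
#' @param universe total number of genes in the testable universe (no
#'   default: it must be stated to make the p-values reproducible).
#' @return data frame of class `ClassGeneReport`, one row per class.
#' @export
class_gene_report <- function(records, up_genes, down_genes, universe) {
  if (is.null(records$nearest_gene))
    stop("class_gene_report: records lack nearest_gene; pass genes to classify_enhancers")
  if (length(intersect(up_genes, down_genes)))
    stop("class_gene_report: up and down DEG sets must be disjoint")
  classes <- levels(records$enh_class)
  rows <- lapply(classes, function(cl) {
    genes <- unique(stats::na.omit(records$nearest_gene[records$enh_class == cl]))
    n <- length(genes)
    nu <- length(intersect(genes, up_genes))
    nd <- length(intersect(genes, down_genes))
    if (universe < max(n, length(up_genes), length(down_genes)))
      stop("class_gene_report: universe smaller than a set margin")
    data.frame(enh_class = cl, n_genes = n, n_up = nu, n_down = nd,
               frac_up = if (n) nu / n else NA_real_,
               frac_down = if (n) nd / n else NA_real_,
               fisher_p_up = if (n) hyper_upper_tail(nu, length(up_genes), n, universe) else NA_real_,
               fisher_p_down = if (n) hyper_upper_tail(nd, length(down_genes), n, universe) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ClassGeneReport", "data.frame")
  out
}

# P(X >= k) for X ~ Hypergeometric(N, K, n): one-tailed Fisher enrichment.
hyper_upper_tail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overlap percentage summary
#'
#' The percentage of a peak set overlapping another, as reported in
#' figure-level summaries: `100 * a_overlapping / a_total`, with the
#' nearest-integer rounding used in prose alongside the exact value.
#'
#' @param a_total total peak count (> 0).
#' @param a_overlapping number overlapping (0 <= x <= total).
#' @return list with `percent` (exact) and `percent_rounded`.
#' @export
overlap_summary <- function(a_total, a_overlapping) {
  if (a_total <= 0) stop("overlap_summary: a_total must be > 0")
  if (a_overlapping < 0 || a_overlapping > a_total)
    stop("overlap_summary: a_overlapping outside [0, a_total]")
  pct <- 100 * a_overlapping / a_total
  list(percent = pct, percent_rounded = round(pct))
}

#' Write enhancer records as BED6 (class in the name field) and TSV
#'
#' @param records an `EnhancerRecord`.
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_enhancer_records <- function(records, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    out <- sprintf("%s\t%d\t%d\t%s\t0\t.", records$chrom, records$start,
                   records$end,
                   paste0(records$peak_id, "|", records$enh_class))
    writeLines(out, bed_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(records), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
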