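#' Construct a tag library
#'
#' A tag library stores the 5' positions of sequenced fragments for one
#' sample, per chromosome, sorted; `total_tags` is the library size used
#' for tags-per-1e7 normalization.
#'
#' @param positions named list (by chromosome) of integer position vectors.
#' @param sample_id,condition labels.
#' @return object of class `TagLibrary`.
#' @export
tag_library <- function(positions, sample_id, condition) {
  positions <- lapply(positions, function(p) sort(as.integer(p)))
  structure(list(sample_id = sample_id, condition = condition,
                 positions = positions,
                 total_tags = sum(lengths(positions))),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary '%s' (%s): %d tags on %d chromosome(s)\n",
              x$sample_id, x$condition, x$total_tags, length(x$positions)))
  invisible(x)
}

#' Read a tag library from a two-column TSV (chrom, position)
#'
#' @param path TSV with header columns `chrom`, `position`.
#' @param sample_id,condition labels (sample_id defaults to file name).
#' @return a `TagLibrary`.
#' @export
read_tag_library <- function(path, sample_id = basename(path), condition = "NA") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "position") %in% names(df)))
    stop("read_tag_library: need columns chrom, position")
  tag_library(split(df$position, df$chrom), sample_id, condition)
}

#' @rdname read_tag_library
#' @param lib a `TagLibrary`.
#' @export
write_tag_library <- function(lib, path) {
  df <- data.frame(chrom = rep(names(lib$positions), lengths(lib$positions)),
                   position = unlist(lib$positions, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count matrix
#'
#' @param counts integer matrix, features x samples, rownames = feature ids.
#' @param samples data frame with `sample_id`, `condition`; one row per column.
#' @param window counting window in bp (recorded, not re-applied).
#' @param total_tags per-sample library sizes for the tags-per-1e7
#'   normalized view; defaults to column sums.
#' @return object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, samples, window = NA_integer_,
                         total_tags = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("count_matrix: negative counts")
  if (nrow(samples) != ncol(counts))
    stop("count_matrix: samples rows must match count columns")
  if (is.null(total_tags)) total_tags <- colSums(counts)
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = as.data.frame(samples),
                 window = window, total_tags = as.numeric(total_tags)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d features x %d samples (window %s bp)\n",
              nrow(x$counts), ncol(x$counts), x$window))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized counts (tags per 1e7 library tags)
#'
#' @param m a `CountMatrix`.
#' @return numeric matrix on the tags-per-1e7 scale.
#' @export
normalized_counts <- function(m) {
  tt <- ifelse(m$total_tags > 0, m$total_tags, NA_real_)
  sweep(m$counts, 2, 1e7 / tt, `*`)
}

#' Count tags in fixed windows around peak summits
#'
#' For each peak and sample, counts tag positions within
#' `[summit - window/2, summit + window/2)` (half-open; odd windows round
#' the half-width down). Raw integers are stored; the tags-per-1e7 view is
#' available via [normalized_counts()].
#'
#' @param peaks a `PeakSet`.
#' @param libs list of `TagLibrary`.
#' @param window window width in bp (500 for TF ChIP-seq, 1000 for
#'   H3K27ac/ATAC annotation by convention).
#' @return a `CountMatrix`.
#' @export
quantify <- function(peaks, libs, window = 500L) {
  if (window <= 0) stop("quantify: window must be > 0")
  half <- window %/% 2L
  counts <- matrix(0L, nrow = nrow(peaks), ncol = length(libs),
                   dimnames = list(peaks$peak_id, NULL))
  for (j in seq_along(libs)) {
    lib <- libs[[j]]
    if (lib$total_tags == 0)
      warning("quantify: empty library ", lib$sample_id)
    for (chr in unique(peaks$chrom)) {
      pos <- lib$positions[[chr]]
      if (is.null(pos) || !length(pos)) next
      pi <- which(peaks$chrom == chr)
      lo <- peaks$summit[pi] - half
      hi <- peaks$summit[pi] + half  # [lo, hi)
      counts[pi, j] <- findInterval(hi - 1L, pos) - findInterval(lo - 1L, pos)
    }
  }
  samples <- data.frame(
    sample_id = vapply(libs, `[[`, "", "sample_id"),
    condition = vapply(libs, `[[`, "", "condition"),
    stringsAsFactors = FALSE)
  count_matrix(counts, samples, window = window,
               total_tags = vapply(libs, `[[`, 0, "total_tags"))
}
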