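#' Construct a PeakSet
#'
#' A `PeakSet` is the package's unit container for peak calls: a data frame
#' with one row per peak and columns `chrom`, `start`, `end` (0-based,
#' half-open), `peak_id`, `score` (normalized tag density, tags per 1e7
#' library tags), `strand` and `summit` (absolute position, inside the
#' interval). The set carries a `name` and a `genome` build label so that
#' cross-set operations can refuse to mix builds.
#'
#' @param peaks data frame with at least `chrom`, `start`, `end`. Missing
#'   `peak_id` is filled with `name_1..n`; missing `summit` defaults to the
#'   interval midpoint; missing `score` to 0 and `strand` to ".".
#' @param name label for the set.
#' @param genome genome build label (e.g. "synth1").
#' @return object of class `PeakSet`.
#' @export
peak_set <- function(peaks, name = "peaks", genome = "unknown") {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), peak_id = character(),
                        score = numeric(), strand = character(),
                        summit = integer(), stringsAsFactors = FALSE)
  }
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols))
    stop("peak_set: missing columns: ", paste(missing_cols, collapse = ", "))
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  if (is.null(peaks$peak_id))
    peaks$peak_id <- if (nrow(peaks)) paste0(name, "_", seq_len(nrow(peaks))) else character()
  peaks$peak_id <- as.character(peaks$peak_id)
  if (is.null(peaks$score)) peaks$score <- numeric(nrow(peaks))
  if (is.null(peaks$strand)) peaks$strand <- rep(".", nrow(peaks))
  if (is.null(peaks$summit))
    peaks$summit <- as.integer((peaks$start + peaks$end) %/% 2L)
  peaks$summit <- as.integer(peaks$summit)
  peaks <- peaks[, c("chrom", "start", "end", "peak_id", "score", "strand", "summit"),
                 drop = FALSE]
  validate_peaks(peaks)
  structure(peaks, name = name, genome = genome,
            class = c("PeakSet", "data.frame"))
}

validate_peaks <- function(p) {
  if (!nrow(p)) return(invisible(TRUE))
  if (any(is.na(p$start) | is.na(p$end)))
    stop("peak_set: non-numeric start/end")
  if (any(p$start < 0)) stop("peak_set: negative start coordinate")
  bad <- which(p$end <= p$start)
  if (length(bad))
    stop("peak_set: end <= start for peak(s) ",
         paste(utils::head(p$peak_id[bad], 5), collapse = ", "))
  if (anyDuplicated(p$peak_id))
    stop("peak_set: duplicate peak_id(s): ",
         paste(utils::head(unique(p$peak_id[duplicated(p$peak_id)]), 5), collapse = ", "))
  out <- which(p$summit < p$start | p$summit >= p$end)
  if (length(out))
    stop("peak_set: summit outside interval for peak(s) ",
         paste(utils::head(p$peak_id[out], 5), collapse = ", "))
  if (any(p$score < 0, na.rm = TRUE)) stop("peak_set: negative score")
  invisible(TRUE)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s' (%s): %d peaks on %d chromosome(s)\n",
              attr(x, "name"), attr(x, "genome"), nrow(x),
              length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

set_genome <- function(x) attr(x, "genome")

check_same_genome <- function(a, b) {
  ga <- set_genome(a); gb <- set_genome(b)
  if (!identical(ga, gb))
    stop(sprintf("genome label mismatch: '%s' vs '%s'", ga, gb))
  invisible(TRUE)
}

# GRanges view of a PeakSet (internal; keeps GenomicRanges behind the surface)
peaks_granges <- function(p) {
  GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end),
    peak_id = p$peak_id)
}

#' Read peaks from a BED file
#'
#' Accepts BED3/BED6 with an optional 7th column holding the summit as an
#' offset from `start` (narrowPeak convention). Coordinates are kept 0-based
#' half-open exactly as stored. When no summit column is present the summit
#' defaults to the interval midpoint.
#'
#' @param path BED file path.
#' @param name,genome labels for the resulting [peak_set()].
#' @return a `PeakSet`.
#' @export
read_bed <- function(path, name = basename(path), genome = "unknown") {
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) return(peak_set(data.frame(), name = name, genome = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("read_bed: malformed line ", which(nf < 3)[1], " (fewer than 3 fields)")
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("read_bed: non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = start, end = end, stringsAsFactors = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("read_bed: end <= start at line ", bad[1])
  getcol <- function(i) ifelse(nf >= i, vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, ""), NA_character_)
  if (any(nf >= 4)) df$peak_id <- getcol(4L)
  if (any(nf >= 5)) df$score <- suppressWarnings(as.numeric(getcol(5L)))
  if (any(nf >= 6)) df$strand <- getcol(6L)
  if (any(nf >= 7)) {
    off <- suppressWarnings(as.integer(getcol(7L)))
    df$summit <- ifelse(is.na(off), (df$start + df$end) %/% 2L, df$start + off)
  }
  if (!is.null(df$score)) df$score[is.na(df$score)] <- 0
  if (!is.null(df$strand)) df$strand[is.na(df$strand) | !(df$strand %in% c("+", "-"))] <- "."
  peak_set(df, name = name, genome = genome)
}

#' Write a PeakSet to BED
#'
#' Writes BED6 plus a 7th column with the summit offset from start, the
#' format [read_bed()] round-trips losslessly.
#'
#' @param x a `PeakSet`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  out <- sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%d",
                 df$chrom, df$start, df$end, df$peak_id, df$score,
                 df$strand, df$summit - df$start)
  writeLines(out, path)
  invisible(path)
}

#' Construct a gene annotation table
#'
#' Gene annotations carry one TSS per gene (`tss`, a single base position,
#' 0-based) and a transcript length in bases used for TPM normalization.
#'
#' @param genes data frame with `gene_id`, `chrom`, `tss`, `length` and
#'   optionally `symbol` (defaults to `gene_id`) and `strand`.
#' @return data frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "tss", "length")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene_annotation: missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$strand)) genes$strand <- rep(".", nrow(genes))
  genes$tss <- as.integer(genes$tss)
  genes$length <- as.integer(genes$length)
  if (any(genes$length <= 0)) stop("gene_annotation: non-positive length")
  if (anyDuplicated(genes$gene_id)) stop("gene_annotation: duplicate gene_id")
  genes <- genes[, c("gene_id", "symbol", "chrom", "tss", "length", "strand")]
  class(genes) <- c("GeneAnnotation", "data.frame")
  genes
}

#' Read gene annotations from TSV
#'
#' Expects a header line with columns `gene_id`, `chrom`, `tss`, `length`
#' (plus optional `symbol`, `strand`).
#'
#' @param path TSV file path.
#' @return a `GeneAnnotation` data frame.
#' @export
read_gene_annotation <- function(path) {
  gene_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_gene_annotation
#' @param genes a `GeneAnnotation`.
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
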