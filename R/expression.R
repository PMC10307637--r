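#' Build an expression table with TPM
#'
#' Transcripts-per-million: for each sample, the per-gene count rate
#' (count / transcript length) scaled so the sample sums to 1e6.
#'
#' @param counts integer matrix, genes x samples, rownames = gene ids.
#' @param lengths transcript lengths in bases, one per gene (or a
#'   `GeneAnnotation` to take lengths from, matched by gene_id).
#' @param samples data frame with `sample_id`, `group`; one row per column.
#' @return object of class `ExpressionTable` with elements `counts`,
#'   `tpm`, `lengths`, `samples`.
#' @export
compute_tpm <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (inherits(lengths, "GeneAnnotation"))
    lengths <- lengths$length[match(rownames(counts), lengths$gene_id)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts))
    stop("compute_tpm: one length per gene required")
  if (any(is.na(lengths) | lengths <= 0))
    stop("compute_tpm: lengths must be positive")
  if (nrow(samples) != ncol(counts))
    stop("compute_tpm: samples rows must match count columns")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("compute_tpm: all-zero sample(s): ",
         paste(samples$sample_id[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2, 1e6 / tot, `*`)
  colnames(tpm) <- colnames(counts) <- samples$sample_id
  structure(list(counts = counts, tpm = tpm, lengths = lengths,
                 samples = as.data.frame(samples)),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

group_mean_tpm <- function(table, groups = unique(table$samples$group)) {
  sapply(groups, function(g)
    rowMeans(table$tpm[, table$samples$group == g, drop = FALSE]))
}

#' Call differentially expressed genes
#'
#' Runs the negative-binomial Wald test ([nb_wald_test()]) on raw counts
#' between two groups, then applies the DEG rule: `padj < alpha`,
#' `|log2fc| > log2(fc)`, and mean `log2(TPM + 1)` above `floor` in at
#' least one of the two groups (the expression floor screens out calls
#' driven by near-zero expression).
#'
#' @param table an `ExpressionTable`.
#' @param g1,g2 group labels; fold change is g2 over g1.
#' @param fc fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param floor threshold on group-mean `log2(TPM + 1)` (default 2; use 4
#'   for stricter contrasts).
#' @return the `DiffResult` table with a `verdict` column (up / down /
#'   unchanged) incorporating the expression floor.
#' @export
call_degs <- function(table, g1, g2, fc = 2, alpha = 0.05, floor = 2) {
  grp <- table$samples$group
  for (g in c(g1, g2))
    if (!any(grp == g)) stop("call_degs: unknown group '", g, "'")
  cm <- count_matrix(table$counts,
                     data.frame(sample_id = table$samples$sample_id,
                                condition = grp))
  res <- nb_wald_test(cm, g1, g2)
  res <- call_differential_peaks(res, fc_threshold = fc, alpha = alpha)
  mt <- group_mean_tpm(table, c(g1, g2))
  expr_ok <- apply(log2(mt + 1), 1, max) > floor
  res$verdict[!expr_ok] <- "unchanged"
  attr(res, "expression_floor") <- floor
  res
}

#' Define cell-type signature genes
#'
#' A gene belongs to the focal cell type's signature when its mean TPM in
#' the focal group strictly exceeds `fold` times the average of the
#' per-group mean TPMs across the other groups (a pseudocount of 0.01 TPM
#' in the denominator keeps genes silent elsewhere well-defined).
#'
#' @param table an `ExpressionTable`.
#' @param focal_group label of the focal cell type.
#' @param other_groups labels to average over (default: all other groups).
#' @param fold fold-ratio threshold (default 10, strict `>`).
#' @param pseudocount TPM added to the denominator (default 0.01).
#' @return character vector of signature gene ids, with the fold ratios as
#'   the `ratio` attribute.
#' @export
define_signature <- function(table, focal_group,
                             other_groups = NULL, fold = 10,
                             pseudocount = 0.01) {
  grp <- unique(table$samples$group)
  if (!focal_group %in% grp)
    stop("define_signature: unknown focal group '", focal_group, "'")
  if (is.null(other_groups)) other_groups <- setdiff(grp, focal_group)
  if (!length(other_groups)) stop("define_signature: need >= 1 other group")
  mt <- group_mean_tpm(table, c(focal_group, other_groups))
  focal <- mt[, 1]
  others <- rowMeans(mt[, -1, drop = FALSE])
  ratio <- focal / (others + pseudocount)
  sel <- ratio > fold
  structure(rownames(table$counts)[sel],
            ratio = ratio[sel])
}

#' Gene-set overlap with one-tailed Fisher enrichment
#'
#' Hypergeometric upper-tail probability of observing at least the actual
#' overlap between two gene sets drawn from a universe of `universe` genes.
#'
#' @param a,b character vectors of gene ids.
#' @param universe universe size (must be >= the union of the sets).
#' @return list with `overlap`, `frac_a`, `frac_b`, `p`.
#' @export
gene_set_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b)
  if (universe < length(unique(c(a, b))))
    stop("gene_set_overlap: universe smaller than the union of the sets")
  k <- length(intersect(a, b))
  p <- hyper_upper_tail(k, length(b), length(a), universe)
  list(overlap = k,
       frac_a = if (length(a)) k / length(a) else NA_real_,
       frac_b = if (length(b)) k / length(b) else NA_real_,
       p = min(p, 1))
}

#' Read / write expression count tables
#'
#' TSV with columns `gene_id`, `length`, then one column per sample; the
#' group of each sample is parsed from a `sample:group` header or supplied.
#'
#' @param path TSV file path.
#' @param groups optional character vector of group labels per sample
#'   column (otherwise parsed after the last ":" in each header).
#' @return an `ExpressionTable`.
#' @export
read_expression_table <- function(path, groups = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "length") %in% names(df)))
    stop("read_expression_table: need gene_id and length columns")
  samp_cols <- setdiff(names(df), c("gene_id", "length"))
  counts <- as.matrix(df[, samp_cols, drop = FALSE])
  rownames(counts) <- df$gene_id
  if (is.null(groups)) {
    groups <- sub("^.*:", "", samp_cols)
    samp_ids <- sub(":[^:]*$", "", samp_cols)
  } else samp_ids <- samp_cols
  compute_tpm(counts, df$length,
              data.frame(sample_id = samp_ids, group = groups,
                         stringsAsFactors = FALSE))
}

#' @rdname read_expression_table
#' @param table an `ExpressionTable`.
#' @export
write_expression_table <- function(table, path) {
  df <- data.frame(gene_id = rownames(table$counts),
                   length = table$lengths, check.names = FALSE)
  cn <- paste0(table$samples$sample_id, ":", table$samples$group)
  df[cn] <- as.data.frame(table$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write one-id-per-line gene sets
#' @param path text file, one gene id per line.
#' @return character vector.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  unique(x[nzchar(x)])
}

#' @rdname read_gene_set
#' @param genes character vector of ids.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
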