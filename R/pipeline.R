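#' Default pipeline configuration
#'
#' All thresholds of the analysis with their standard defaults: distal
#' cutoff 3,000 bp; H3K27ac window 1,000 bp and TF window 500 bp; activity
#' floor 16 normalized tags; fold change 2 at adjusted p 0.05; expression
#' floor 2 on log2(TPM+1); signature fold 10; PWM match threshold 4 bits;
#' motif-cluster correlation 0.6; TF expression filter 2 TPM; stitching
#' distance 12,500 bp.
#'
#' @param ... overrides for individual fields.
#' @return named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    distal_bp = 3000L, k27_window = 1000L, tf_window = 500L,
    activity_floor = 16, fc = 2, alpha = 0.05, expr_floor = 2,
    signature_fold = 10, pwm_threshold = 4, cluster_r = 0.6,
    tpm_filter = 2, stitch_bp = 12500L,
    seed = 1L, outdir = "pipeline_out",
    inputs = list())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(config) {
  needed <- c("distal_bp", "k27_window", "activity_floor", "fc", "alpha",
              "expr_floor", "signature_fold", "pwm_threshold", "cluster_r",
              "tpm_filter", "stitch_bp", "seed")
  miss <- needed[!vapply(needed, function(f)
    !is.null(config[[f]]), TRUE)]
  if (length(miss))
    stop("pipeline config missing field(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Write a complete synthetic input bundle to disk
#'
#' Runs every generator at the given seed and writes the standard-format
#' inputs the pipeline consumes — ATAC peak BED, gene annotation TSV, TF
#' replicate peak BEDs, per-sample H3K27ac tag TSVs, expression count TSV,
#' strain-pair FASTAs, a JASPAR PWM library (one causal motif and decoys)
#' — alongside the planted-truth JSON and a config YAML.
#'
#' @param seed RNG seed for all generators.
#' @param outdir output directory (created).
#' @param preset "default" (2,000 peaks, 5,000 genes) or "tiny" (300
#'   peaks, 800 genes) scale.
#' @return invisibly, the list of generated objects and file paths.
#' @export
simulate_bundle <- function(seed, outdir, preset = "default") {
  scales <- list(
    default = list(n_peaks = 2000L, n_genes = 5000L, n_sig = 300L,
                   n_deg = 400L, n_loci = 100L, n_decoys = 20L),
    tiny = list(n_peaks = 300L, n_genes = 800L, n_sig = 60L,
                n_deg = 80L, n_loci = 40L, n_decoys = 8L))
  if (!preset %in% names(scales))
    stop("simulate_bundle: unknown preset '", preset, "'; available: ",
         paste(names(scales), collapse = ", "))
  sc <- scales[[preset]]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("simulate_bundle: cannot create ", outdir)

  uni <- generate_peak_universe(seed, n_peaks = sc$n_peaks)
  planted <- plant_enhancer_classes(seed + 1L, uni$peaks$peak_id)
  k27 <- generate_counts(seed + 2L, stats::setNames(planted$planted_lfc,
                                                    planted$peak_id))
  tf_reps <- generate_tf_replicates(seed + 3L, uni$peaks, planted$tf_bound)
  libs <- generate_tag_libraries(seed + 4L, uni$peaks, k27$matrix,
                                 window = 1000L)
  expr <- generate_expression(seed + 5L, n_genes = sc$n_genes,
                              n_signature = sc$n_sig, n_deg = sc$n_deg)
  causal <- pwm(rbind(A = c(9, 0, 0, 9, 0, 0, 1, 1),
                      C = c(0, 9, 0, 0, 0, 9, 1, 1),
                      G = c(0, 0, 9, 0, 0, 0, 7, 1),
                      T = c(0, 0, 0, 0, 9, 0, 0, 6)), name = "CAUSAL")
  decoys <- lapply(seq_len(sc$n_decoys), function(i)
    random_pwm(seed + 100L + i, name = sprintf("DECOY%02d", i)))
  strain <- generate_strain_pairs(seed + 6L, n_loci = sc$n_loci,
                                  causal_pwm = causal)

  paths <- list(
    atac_peaks = file.path(outdir, "atac_peaks.bed"),
    genes = file.path(outdir, "genes.tsv"),
    tf_reps = file.path(outdir, sprintf("tf_rep%d.bed", seq_along(tf_reps))),
    tags = file.path(outdir, paste0("h3k27ac_",
                                    k27$matrix$samples$sample_id, ".tsv")),
    expression = file.path(outdir, "expression.tsv"),
    positive = file.path(outdir, "strain_positive.fa"),
    negative = file.path(outdir, "strain_negative.fa"),
    pwms = file.path(outdir, "motifs.jaspar"),
    truth = file.path(outdir, "truth.json"),
    config = file.path(outdir, "config.yaml"))

  write_bed(uni$peaks, paths$atac_peaks)
  write_gene_annotation(uni$genes, paths$genes)
  for (i in seq_along(tf_reps)) write_bed(tf_reps[[i]], paths$tf_reps[i])
  for (j in seq_along(libs)) write_tag_library(libs[[j]], paths$tags[j])
  write_expression_table(expr$table, paths$expression)
  write_fasta(stats::setNames(strain$pairs$positive_seq,
                              strain$pairs$locus_id), paths$positive)
  write_fasta(stats::setNames(strain$pairs$negative_seq,
                              strain$pairs$locus_id), paths$negative)
  write_jaspar(c(list(causal), decoys), paths$pwms)
  truth <- list(seed = seed, preset = preset,
                peak_universe = uni$truth, planted_classes = planted,
                counts = k27$truth, expression = expr$truth,
                strain = strain$truth)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  cfg <- pipeline_config(seed = seed, outdir = file.path(outdir, "results"),
                         inputs = lapply(paths[1:8], identity))
  write_pipeline_config(cfg, paths$config)
  invisible(list(universe = uni, planted = planted, k27 = k27,
                 tf_reps = tf_reps, libs = libs, expression = expr,
                 strain = strain, causal = causal, decoys = decoys,
                 paths = paths, config = cfg))
}

stage_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — TF peak reproducibility, distal
#' filtering, window quantification, NB differential test, enhancer
#' classification, super-enhancer calling, gene association and
#' enrichment, expression (DEGs, signature), motif-mutation association —
#' writing each stage's TSV/BED outputs plus a consolidated summary to the
#' configured output directory. The configuration is echoed verbatim into
#' the output directory.
#'
#' @param config a `PipelineConfig` whose `inputs` list names the files
#'   written by [simulate_bundle()] (fields `atac_peaks`, `genes`,
#'   `tf_reps`, `tags`, `expression`, `positive`, `negative`, `pwms`).
#' @return list with `summary` (named numbers), paths of outputs, and the
#'   stage objects, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  inp <- config$inputs
  need <- c("atac_peaks", "genes", "tf_reps", "tags", "expression",
            "positive", "negative", "pwms")
  miss <- setdiff(need, names(inp))
  if (length(miss))
    stop("run_pipeline: missing input(s): ", paste(miss, collapse = ", "))
  for (f in unlist(inp[need]))
    if (!file.exists(f)) stop("run_pipeline: input not readable: ", f)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(outdir, "config.yaml"))
  log <- character()

  peaks <- read_bed(inp$atac_peaks, name = "atac", genome = "synth1")
  genes <- read_gene_annotation(inp$genes)
  log <- stage_log(log, "load", sprintf("%d peaks, %d genes (seed %d)",
                                        nrow(peaks), nrow(genes), config$seed))

  tf_reps <- lapply(unlist(inp$tf_reps), read_bed, genome = "synth1")
  tf <- reproducible_peaks(tf_reps, name = "tf")
  write_bed(tf, file.path(outdir, "tf_reproducible.bed"))
  log <- stage_log(log, "repro", sprintf("%d reproducible TF peaks from %d replicates",
                                         nrow(tf), length(tf_reps)))

  distal <- filter_distal(peaks, genes, config$distal_bp)
  log <- stage_log(log, "distal", sprintf("%d of %d peaks distal (> %d bp)",
                                          nrow(distal), nrow(peaks), config$distal_bp))

  libs <- lapply(unlist(inp$tags), function(f) {
    sid <- sub("\\.tsv$", "", sub("^h3k27ac_", "", basename(f)))
    read_tag_library(f, sample_id = sid, condition = sub("_rep.*$", "", sid))
  })
  k27 <- quantify(distal, libs, window = config$k27_window)
  log <- stage_log(log, "quantify", sprintf("%d features x %d samples (window %d bp)",
                                            nrow(k27$counts), ncol(k27$counts),
                                            config$k27_window))

  conds <- unique(k27$samples$condition)
  diff <- nb_wald_test(k27, conds[1], conds[2])
  diff <- call_differential_peaks(diff, config$fc, config$alpha)
  write_diff_results(diff, file.path(outdir, "h3k27ac_diff.tsv"))
  n_up <- sum(diff$verdict == "up"); n_down <- sum(diff$verdict == "down")
  log <- stage_log(log, "diff", sprintf("%d up, %d down (%s vs %s)",
                                        n_up, n_down, conds[2], conds[1]))

  active <- select_active_enhancers(distal, k27, config$activity_floor)
  records <- classify_enhancers(active,
                                diff[diff$feature_id %in% active$peak_id, ],
                                tf, genes)
  write_enhancer_records(records,
                         bed_path = file.path(outdir, "enhancer_classes.bed"),
                         tsv_path = file.path(outdir, "enhancer_classes.tsv"))
  cls_counts <- table(records$enh_class)
  log <- stage_log(log, "classify", paste(names(cls_counts), cls_counts,
                                          sep = "=", collapse = ", "))

  se_peaks <- active
  se_peaks$score <- rowMeans(normalized_counts(k27))[match(active$peak_id,
                                                           rownames(k27$counts))]
  se <- call_super_enhancers(se_peaks, stitch_bp = config$stitch_bp)
  utils::write.table(as.data.frame(se), file.path(outdir, "super_enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- stage_log(log, "superenh", sprintf("%d stitched regions, %d super",
                                            nrow(se), sum(se$is_super)))

  expr <- read_expression_table(inp$expression)
  degs <- call_degs(expr, "focal", "focal_ko", fc = config$fc,
                    alpha = config$alpha, floor = config$expr_floor)
  write_diff_results(degs, file.path(outdir, "degs.tsv"))
  up_genes <- degs$feature_id[degs$verdict == "up"]
  down_genes <- degs$feature_id[degs$verdict == "down"]
  subtype_groups <- setdiff(unique(expr$samples$group), c("focal", "focal_ko"))
  signature <- define_signature(expr, "focal", other_groups = subtype_groups,
                                fold = config$signature_fold)
  write_gene_set(signature, file.path(outdir, "signature_genes.txt"))
  sig_overlap <- gene_set_overlap(signature, down_genes,
                                  universe = nrow(expr$counts))
  log <- stage_log(log, "expression",
                   sprintf("%d up, %d down DEGs; %d signature genes (overlap with down: %d, p=%.3g)",
                           length(up_genes), length(down_genes),
                           length(signature), sig_overlap$overlap, sig_overlap$p))

  report <- class_gene_report(records, up_genes, down_genes,
                              universe = nrow(expr$counts))
  utils::write.table(report, file.path(outdir, "class_gene_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pwms <- read_jaspar(inp$pwms)
  pos <- read_fasta(inp$positive); neg <- read_fasta(inp$negative)
  pairs <- variant_pair_set(data.frame(locus_id = names(pos),
                                       positive_seq = unname(pos),
                                       negative_seq = unname(neg[names(pos)]),
                                       stringsAsFactors = FALSE))
  assoc <- motif_mutation_association(pairs, pwms, expression = expr,
                                      focal_group = "focal",
                                      tpm_filter = config$tpm_filter)
  motifs <- cluster_motifs(assoc, r_threshold = config$cluster_r)
  write_motif_results(motifs, file.path(outdir, "motif_association.tsv"))
  top_motif <- motifs$motif[which.max(abs(motifs$signed_logp))]
  log <- stage_log(log, "motifs", sprintf("%d motifs tested; strongest: %s",
                                          nrow(motifs), top_motif))

  up_ov <- overlap_summary(max(n_up, 1L),
                           sum(records$enh_class == "direct_repressed"))
  down_ov <- overlap_summary(max(n_down, 1L),
                             sum(records$enh_class == "direct_activated"))
  summary <- c(
    n_peaks = nrow(peaks), n_tf_peaks = nrow(tf), n_distal = nrow(distal),
    n_active = nrow(active), n_k27_up = n_up, n_k27_down = n_down,
    n_direct_activated = unname(cls_counts["direct_activated"]),
    n_direct_repressed = unname(cls_counts["direct_repressed"]),
    n_indirect_activated = unname(cls_counts["indirect_activated"]),
    n_indirect_repressed = unname(cls_counts["indirect_repressed"]),
    pct_up_tf_bound = up_ov$percent_rounded,
    pct_down_tf_bound = down_ov$percent_rounded,
    n_super = sum(se$is_super),
    n_deg_up = length(up_genes), n_deg_down = length(down_genes),
    n_signature = length(signature),
    signature_down_overlap = sig_overlap$overlap)
  sdf <- data.frame(metric = names(summary), value = unname(summary))
  utils::write.table(sdf, file.path(outdir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(log, file.path(outdir, "pipeline.log"))
  invisible(list(summary = summary, outdir = outdir, records = records,
                 diff = diff, tf = tf, super_enhancers = se, degs = degs,
                 signature = signature, motifs = motifs, report = report,
                 log = log))
}
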