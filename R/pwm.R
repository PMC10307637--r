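DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Stores per-position base probabilities with a background model; scores
#' are log2 odds (bits), so a total score of 4 means the window is 2^4 =
#' 16-fold more likely under the motif than under background.
#'
#' @param probs 4 x L numeric matrix (rows A, C, G, T); columns must each
#'   sum to 1 within 1e-6. A count matrix is accepted and normalized.
#' @param name motif name.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount probability mass added per cell before taking logs
#'   (default 0.001), preventing -Inf scores.
#' @return object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.001) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("pwm: probs must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 4) stop("pwm: motif length must be >= 4")
  cs <- colSums(probs)
  if (any(cs <= 0)) stop("pwm: empty column")
  probs <- sweep(probs, 2, cs, `/`)
  if (abs(sum(background) - 1) > 1e-6) stop("pwm: background must sum to 1")
  rownames(probs) <- DNA_BASES
  structure(list(name = name, probs = probs,
                 background = stats::setNames(background, DNA_BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s', length %d, consensus %s\n", x$name, ncol(x$probs),
              paste(DNA_BASES[apply(x$probs, 2, which.max)], collapse = "")))
  invisible(x)
}

pwm_length <- function(p) ncol(p$probs)

# 5 x L log2-odds matrix; 5th row (ambiguous base N) contributes 0 bits.
pwm_logodds <- function(p) {
  pr <- (p$probs + p$pseudocount) / (1 + 4 * p$pseudocount)
  lo <- log2(pr / p$background)
  rbind(lo, N = 0)
}

#' Reverse complement of a PWM
#' @param p a `pwm`.
#' @return the reverse-complemented `pwm`.
#' @export
pwm_revcomp <- function(p) {
  pr <- p$probs[4:1, ncol(p$probs):1, drop = FALSE]
  rownames(pr) <- DNA_BASES
  pwm(pr, name = p$name, background = unname(p$background[4:1]),
      pseudocount = p$pseudocount)
}

#' Consensus sequence of a PWM
#' @param p a `pwm`.
#' @return character string.
#' @export
pwm_consensus <- function(p)
  paste(DNA_BASES[apply(p$probs, 2, which.max)], collapse = "")

seq_codes <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  x[is.na(x)] <- 5L  # N and friends score as background (0 bits)
  x
}

#' Score one window under a PWM
#'
#' Sum over positions of `log2(prob(base) / background(base))`, with the
#' PWM's pseudocount applied; ambiguous bases (N) contribute 0 bits.
#'
#' @param p a `pwm`.
#' @param window character string of exactly the motif length.
#' @return score in bits.
#' @export
pwm_score <- function(p, window) {
  L <- pwm_length(p)
  code <- seq_codes(window)
  if (length(code) != L)
    stop("pwm_score: window length ", length(code), " != motif length ", L)
  lo <- pwm_logodds(p)
  sum(lo[cbind(code, seq_len(L))])
}

scan_one_strand <- function(lo, code, L) {
  W <- length(code) - L + 1L
  if (W < 1) return(numeric(0))
  s <- numeric(W)
  for (i in seq_len(L))
    s <- s + lo[code[i:(i + W - 1L)], i]
  s
}

#' Scan a sequence for motif matches above a score threshold
#'
#' Reports every window, on both strands, whose log2-odds score is
#' strictly greater than `threshold` (default 4 bits, i.e. a 16-fold
#' likelihood ratio over background). Overlapping matches are all kept.
#'
#' @param p a `pwm`.
#' @param seq character string over A/C/G/T (N allowed).
#' @param threshold score threshold in bits.
#' @return data frame with `pwm`, `start` (0-based), `end` (half-open),
#'   `strand`, `score`; empty when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(p, seq, threshold = 4) {
  L <- pwm_length(p)
  code <- seq_codes(seq)
  fwd <- scan_one_strand(pwm_logodds(p), code, L)
  rev <- scan_one_strand(pwm_logodds(pwm_revcomp(p)), code, L)
  hit_f <- which(fwd > threshold)
  hit_r <- which(rev > threshold)
  out <- data.frame(
    pwm = rep(p$name, length(hit_f) + length(hit_r)),
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + L,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Best PWM score over all windows and both strands
#'
#' @param p a `pwm`.
#' @param seq character string; sequences shorter than the motif score
#'   `-Inf`.
#' @return maximum score in bits.
#' @export
best_pwm_score <- function(p, seq) {
  L <- pwm_length(p)
  code <- seq_codes(seq)
  s <- c(scan_one_strand(pwm_logodds(p), code, L),
         scan_one_strand(pwm_logodds(pwm_revcomp(p)), code, L))
  if (!length(s)) return(-Inf)
  max(s)
}

#' Read a JASPAR-format PWM file
#'
#' Plain-text JASPAR format: a `>identifier name` header followed by four
#' rows `A [ counts... ]` etc. Counts are column-normalized to
#' probabilities.
#'
#' @param path file path.
#' @param background,pseudocount passed to [pwm()].
#' @return list of `pwm` objects, named by motif name.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.001) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("read_jaspar: no '>' headers in ", path)
  out <- lapply(heads, function(h) {
    nm <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    nm <- nm[length(nm)]  # prefer the motif name over the accession
    rows <- lines[h + 1:4]
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[?", "", r)
      r <- gsub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1)
      stop("read_jaspar: ragged matrix under ", lines[h])
    pwm(do.call(rbind, vals), name = nm, background = background,
        pseudocount = pseudocount)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' @rdname read_jaspar
#' @param pwms list of `pwm` objects.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name, " ", p$name), con)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(p$probs[b, ], digits = 6),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param seq character string.
#' @return character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction of a sequence
#' @param seq character string.
#' @return fraction of G/C among unambiguous bases.
#' @export
gc_content <- function(seq) {
  code <- seq_codes(seq)
  known <- code != 5L
  if (!any(known)) return(NA_real_)
  mean(code[known] %in% c(2L, 3L))
}
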