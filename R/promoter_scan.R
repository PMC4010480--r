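#' Read JASPAR-style position frequency matrices
#'
#' Parses the flat JASPAR format: a `>` header per motif (id and optional
#' name) followed by four rows of counts. Both the bracketed dialect
#' (`A [ 4 19 0 ]`) and four bare numeric rows (assumed A, C, G, T order) are
#' accepted.
#'
#' @param file Path to a PFM flat file (may hold several motifs).
#' @return Named list of 4 x L count matrices with rownames `A`, `C`, `G`, `T`.
#' @export
read_jaspar_pfm <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' motif headers found")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L) stop("motif must have exactly 4 count rows")
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- gsub("\\s+", "_", name)
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1L) stop("ragged count rows in motif ", name)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[name]] <- m
  }
  out
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Each cell becomes
#' `log2((count + pseudocount * bg) / (colsum + pseudocount) / bg)`, i.e. the
#' smoothed position-specific base probability against the background. The
#' minimum and maximum attainable scores (column-wise minima/maxima summed)
#' are stored for relative profile scoring.
#'
#' @param pfm 4 x L count matrix with rownames `A`, `C`, `G`, `T`.
#' @param pseudocount Total pseudocount split by background (default 0.8, a
#'   common JASPAR convention).
#' @param background Base composition, length-4, summing to 1.
#' @param name Motif label carried through reports.
#' @return A `pwm_model`: list with `name`, `pwm` (4 x L log-odds), `s_min`,
#'   `s_max`, and the source `pfm`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       name = "motif") {
  stopifnot(is.matrix(pfm), nrow(pfm) == 4L, pseudocount > 0,
            length(background) == 4L, abs(sum(background) - 1) < 1e-8)
  if (ncol(pfm) == 0L) stop("empty position frequency matrix")
  if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
  pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
  colsum <- colSums(pfm)
  prob <- sweep(pfm + pseudocount * background,
                2, colsum + pseudocount, "/")
  pwm <- log2(prob / background)
  structure(list(name = name, pwm = pwm,
                 s_min = sum(apply(pwm, 2, min)),
                 s_max = sum(apply(pwm, 2, max)),
                 pfm = pfm),
            class = "pwm_model")
}

# A,C,G,T -> 1:4; anything else (N) -> NA
seq_to_idx <- function(sequence) {
  idx <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  idx
}

# raw window scores on one strand; windows containing N score NA
window_scores <- function(idx, pwm) {
  L <- ncol(pwm)
  nw <- length(idx) - L + 1L
  s <- numeric(nw)
  for (j in seq_len(L)) {
    s <- s + pwm[, j][idx[j:(j + nw - 1L)]]
  }
  s
}

#' Best two-strand relative profile score of a PWM on a sequence
#'
#' Slides the motif over every offset of the sequence and its reverse
#' complement, takes the maximum raw log-odds sum, and rescales it to
#' `(s - s_min) / (s_max - s_min)` in `[0, 1]` — the relative profile score
#' used for JASPAR-style threshold scans. Windows containing `N` are skipped;
#' a degenerate motif with `s_max == s_min` scores 1 by convention.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N` (case-insensitive).
#' @param pwm A `pwm_model` from [pfm_to_pwm()].
#' @return Relative score in `[0, 1]`, or `NA` if no window is free of `N`.
#' @export
best_hit_relative_score <- function(sequence, pwm) {
  stopifnot(inherits(pwm, "pwm_model"))
  L <- ncol(pwm$pwm)
  idx <- seq_to_idx(sequence)
  if (length(idx) < L) stop("sequence shorter than the motif")
  rc <- rev(5L - idx)  # A<->T, C<->G, reversed
  s <- c(window_scores(idx, pwm$pwm), window_scores(rc, pwm$pwm))
  s <- s[!is.na(s)]
  if (!length(s)) {
    warning("no window free of N; returning NA")
    return(NA_real_)
  }
  if (pwm$s_max == pwm$s_min) return(1)
  (max(s) - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

#' Promoters whose best motif hit reaches a relative-score threshold
#'
#' @param promoters Named character vector of promoter sequences.
#' @param pwm A `pwm_model`.
#' @param threshold Relative profile score cutoff in `(0, 1]`; the comparison
#'   is inclusive ("at least"). Default 0.99.
#' @return Character vector of promoter ids passing the threshold.
#' @export
scan_threshold <- function(promoters, pwm, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(promoters)) return(character(0))
  if (is.null(names(promoters))) names(promoters) <- seq_along(promoters)
  sc <- vapply(promoters, best_hit_relative_score, numeric(1), pwm = pwm)
  names(sc)[!is.na(sc) & sc >= threshold]
}

#' Motif enrichment z-test of an input promoter set against background
#'
#' pscan-style statistic: per-promoter best-hit relative scores are computed
#' for the input set and a background promoter population, and the input mean
#' is compared to the background with
#' `z = (mean_input - mean_background) / (sd_background / sqrt(m))`,
#' `m = |input|`, yielding a one-sided upper-tail normal p-value. This is a
#' one-sample z approximation of the published pscan statistic.
#'
#' @param input Named character vector of input promoter sequences (the gene
#'   set of interest).
#' @param background Named character vector of background promoters (>= 30
#'   recommended).
#' @param pwm A `pwm_model`.
#' @return One-row `data.frame`: `tf`, `mean_input`, `mean_background`, `z`,
#'   `p_value`.
#' @export
pscan_ztest <- function(input, background, pwm) {
  stopifnot(length(input) > 0, length(background) > 1)
  si <- vapply(input, best_hit_relative_score, numeric(1), pwm = pwm)
  sb <- vapply(background, best_hit_relative_score, numeric(1), pwm = pwm)
  si <- si[!is.na(si)]; sb <- sb[!is.na(sb)]
  sd_bg <- stats::sd(sb)
  if (!is.finite(sd_bg) || sd_bg == 0) {
    stop("degenerate background: zero score variance")
  }
  z <- (mean(si) - mean(sb)) / (sd_bg / sqrt(length(si)))
  data.frame(tf = pwm$name, mean_input = mean(si), mean_background = mean(sb),
             z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Common transcription-factor regulators across promoter groups
#'
#' Two modes. `"all_members"` (miRNA clusters): a TF is a common regulator of
#' a group when *every* member promoter carries a hit at `threshold` relative
#' profile score ([scan_threshold()]). `"pscan"` (mRNA sets): a TF is common
#' when its [pscan_ztest()] p-value is below `alpha` in *every* group. In both
#' modes the cross-group summary reports TFs shared by at least two groups
#' (`shared`) and by all groups (`common_all`).
#'
#' @param groups Named list of named character vectors of promoter sequences.
#' @param pwms List of `pwm_model` objects.
#' @param mode `"all_members"` or `"pscan"`.
#' @param threshold Relative-score cutoff for `"all_members"` (default 0.99).
#' @param background Background promoter set, required for `"pscan"`.
#' @param alpha Per-group significance cutoff for `"pscan"` (default 0.1).
#' @return List with `per_group` (named list of TF label vectors), `shared`,
#'   `common_all`.
#' @export
common_regulators <- function(groups, pwms, mode = c("all_members", "pscan"),
                              threshold = 0.99, background = NULL,
                              alpha = 0.1) {
  mode <- match.arg(mode)
  stopifnot(is.list(groups), length(groups) > 0, is.list(pwms))
  tf_names <- vapply(pwms, function(p) p$name, character(1))
  per_group <- lapply(groups, function(set) {
    hit <- vapply(pwms, function(pw) {
      if (mode == "all_members") {
        length(scan_threshold(set, pw, threshold)) == length(set)
      } else {
        if (is.null(background)) stop("pscan mode needs a background set")
        pscan_ztest(set, background, pw)$p_value < alpha
      }
    }, logical(1))
    tf_names[hit]
  })
  all_tfs <- unlist(per_group, use.names = FALSE)
  counts <- table(all_tfs)
  list(per_group = per_group,
       shared = sort(names(counts)[counts >= 2L]),
       common_all = sort(names(counts)[counts == length(groups)]))
}

#' Read promoter sequences from a FASTA file
#'
#' @param file Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences; names are the first
#'   whitespace-separated token of each header.
#' @export
read_promoter_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  out
}

#' Write promoter sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA sequences.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_promoter_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), file)
  invisible(file)
}
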