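#' Construct an expression study
#'
#' Bundles a normalized log2 expression matrix (probes x samples) with its
#' case/control sample grouping for one cancer-vs-normal comparison.
#'
#' @param cancer_id Label for the study (e.g. `"breast"`).
#' @param matrix Numeric matrix of log2 intensities; rownames are probe ids,
#'   colnames sample ids.
#' @param group Character vector, one of `"case"`/`"control"` per column.
#' @return An `expression_study` object (a validated list).
#' @export
expression_study <- function(cancer_id, matrix, group) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix))) stop("expression matrix needs probe rownames")
  if (anyDuplicated(rownames(matrix))) stop("duplicate probe ids in matrix")
  if (length(group) != ncol(matrix)) stop("one group label per sample required")
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  if (sum(group == "case") < 2L || sum(group == "control") < 2L) {
    stop("at least 2 samples per group required")
  }
  if (!all(is.finite(matrix))) stop("non-finite expression values")
  structure(list(cancer_id = cancer_id, matrix = matrix, group = group),
            class = "expression_study")
}

#' Per-probe log2 fold change (case minus control)
#'
#' @param study An [expression_study()].
#' @return Named numeric vector: mean(case) - mean(control) per probe, on the
#'   log2 scale.
#' @export
log2_fold_change <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  rowMeans(m[, study$group == "case", drop = FALSE]) -
    rowMeans(m[, study$group == "control", drop = FALSE])
}

#' Per-probe Welch t-test p-values
#'
#' Two-sided unequal-variance t-test per probe, vectorized over rows, with
#' Welch-Satterthwaite degrees of freedom. Probes with zero variance in both
#' groups and equal means get p = 1 (no evidence); zero variance with unequal
#' means gets p = 0.
#'
#' @param study An [expression_study()].
#' @return Named numeric vector of p-values in `[0, 1]`.
#' @export
welch_t <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  case <- m[, study$group == "case", drop = FALSE]
  ctrl <- m[, study$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & m1 == m2] <- 1
  p[se2 == 0 & m1 != m2] <- 0
  p
}

#' Call per-probe direction from fold change and significance
#'
#' A probe is `over` when its log2 fold change is at least `log2(fold_threshold)`
#' and p < alpha, `down` when at most `-log2(fold_threshold)` and p < alpha,
#' else `unchanged`. Boundaries are inclusive ("at least k-fold"). Standard
#' thresholds: 2.0 for mRNA, 1.5 for miRNA, 1.2 for the cross-cancer tracing
#' mode.
#'
#' @param fold Named numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values, aligned with `fold`.
#' @param fold_threshold Linear fold-change threshold (> 1).
#' @param alpha Significance level in (0, 1).
#' @return Named character vector over `{"over", "down", "unchanged"}`.
#' @export
call_directions <- function(fold, p, fold_threshold = 2, alpha = 0.05) {
  stopifnot(length(fold) == length(p), fold_threshold > 1,
            alpha > 0, alpha < 1)
  cut <- log2(fold_threshold)
  dir <- rep("unchanged", length(fold))
  dir[p < alpha & fold >= cut] <- "over"
  dir[p < alpha & fold <= -cut] <- "down"
  names(dir) <- names(fold)
  dir
}

#' Top-n probes by absolute fold change
#'
#' Among probes significant at `alpha` with the requested sign, returns up to
#' `n` probe ids with the largest |log2 fold change|. Ties at the cut are
#' broken by lexicographic probe id, so the selection is deterministic.
#'
#' @param fold Named numeric vector of log2 fold changes (names = probe ids).
#' @param p Aligned p-values.
#' @param n Maximum number of probes to return.
#' @param direction `"over"` or `"down"`.
#' @param alpha Significance filter; set to 1 to disable the p filter.
#' @return Character vector of probe ids (length <= n).
#' @export
top_n_by_fold <- function(fold, p, n, direction = c("over", "down"),
                          alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(n >= 1, length(fold) == length(p), !is.null(names(fold)))
  keep <- if (direction == "over") fold > 0 & p < alpha else fold < 0 & p < alpha
  ids <- names(fold)[keep]
  if (length(ids) == 0L) return(character(0))
  o <- order(-abs(fold[keep]), ids)
  ids[o][seq_len(min(n, length(ids)))]
}

#' Differential expression table for one study
#'
#' Convenience wrapper combining [log2_fold_change()], [welch_t()] and
#' [call_directions()].
#'
#' @inheritParams call_directions
#' @param study An [expression_study()].
#' @return `data.frame` with `probe_id`, `log2fc`, `p`, `direction`.
#' @export
de_table <- function(study, fold_threshold = 2, alpha = 0.05) {
  fold <- log2_fold_change(study)
  p <- welch_t(study)
  data.frame(probe_id = names(fold), log2fc = unname(fold), p = unname(p),
             direction = unname(call_directions(fold, p, fold_threshold, alpha)),
             stringsAsFactors = FALSE)
}
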