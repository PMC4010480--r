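#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value for the table `rbind(c(a, b), c(c, d))`, computed by summing
#' the hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7 to absorb floating-point noise, as in
#' [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative counts (vectors of equal length are accepted
#'   and processed elementwise).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d))
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (any(a + b + c + d == 0)) stop("all-zero 2x2 table")
  p_one <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    supp <- max(0, k - n):min(k, m)
    pr <- stats::dhyper(supp, m, n, k)
    sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
  }
  pmin(1, mapply(p_one, a, b, c, d))
}

#' Digital differential display screen of EST pools
#'
#' Compares per-cluster EST fractions between a normal pool (A) and a cancer
#' pool (B). For each cluster the fold difference between pool fractions and a
#' Fisher's exact test on the 2x2 table
#' `(count_A, size_A - count_A; count_B, size_B - count_B)` are computed; a
#' cluster passes when the test is significant at `alpha` and the fold
#' difference strictly exceeds `ratio_threshold`.
#'
#' Fold modes: `"b_over_a"` is the plain cancer/normal ratio
#' `fraction_B / fraction_A` (infinite when `fraction_A = 0` and
#' `fraction_B > 0`); `"symmetric"` (default) uses
#' `max(fraction_B / fraction_A, fraction_A / fraction_B)` so that strong
#' depletion in cancer is screened as well, with the direction recorded. No
#' pseudocounts are applied; a cluster absent from both pools has undefined
#' fold and never passes.
#'
#' @param counts `data.frame` with columns `cluster_id`, `count_A`, `count_B`.
#' @param size_A,size_B Total ESTs in pools A and B (> 0).
#' @param ratio_threshold Fold cutoff, strict inequality (default 10; >= 1 —
#'   setting it to 1 reduces the screen to the exact test alone, useful for
#'   calibration studies).
#' @param alpha Significance level for the exact test (default 0.05).
#' @param ratio_mode `"symmetric"` or `"b_over_a"`.
#' @return `data.frame` with `cluster_id`, `fraction_A`, `fraction_B`,
#'   `fold_difference`, `p_value`, `direction` (`over`/`down`/`none`),
#'   `passes`.
#' @export
ddd_screen <- function(counts, size_A, size_B, ratio_threshold = 10,
                       alpha = 0.05, ratio_mode = c("symmetric", "b_over_a")) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(is.data.frame(counts),
            all(c("cluster_id", "count_A", "count_B") %in% names(counts)),
            size_A > 0, size_B > 0, ratio_threshold >= 1,
            all(counts$count_A <= size_A), all(counts$count_B <= size_B),
            all(counts$count_A >= 0), all(counts$count_B >= 0))
  fa <- counts$count_A / size_A
  fb <- counts$count_B / size_B
  ba <- ifelse(fa == 0, ifelse(fb > 0, Inf, NaN), fb / fa)
  ab <- ifelse(fb == 0, ifelse(fa > 0, Inf, NaN), fa / fb)
  fold <- if (ratio_mode == "b_over_a") ba else pmax(ba, ab)
  p <- fisher_exact_2x2(counts$count_A, size_A - counts$count_A,
                        counts$count_B, size_B - counts$count_B)
  direction <- ifelse(fb > fa, "over", ifelse(fb < fa, "down", "none"))
  passes <- !is.nan(fold) & fold > ratio_threshold & p < alpha
  data.frame(cluster_id = counts$cluster_id, fraction_A = fa, fraction_B = fb,
             fold_difference = fold, p_value = p, direction = direction,
             passes = passes, stringsAsFactors = FALSE)
}
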