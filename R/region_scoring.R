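#' Per-band altered-probeset frequencies across cancers
#'
#' Accumulates, for every cytogenetic band, the number of over-expressed and
#' down-expressed probesets summed over all studies (FOR and FDR), together
#' with the number of probesets annotated to the band on the chip (FTP). FTP
#' is counted once from the chip annotation, not per cancer; the percentage
#' denominator multiplies it by the number of cancers instead. Probes without
#' a band (`"unmapped"`) are excluded from counting.
#'
#' @param calls Named list (one element per cancer) of `data.frame`s with
#'   columns `probe_id` and `direction` (`over`/`down`/`unchanged`).
#' @param annotation Probe annotation `data.frame` with `probe_id`,
#'   `chromosome`, `band` columns (see [annotate_probes()]); this is the chip
#'   annotation supplying the FTP denominator.
#' @param map Optional `cytoband_map` used to attach each band's genomic start
#'   (needed for deterministic tie-breaks downstream).
#' @return `data.frame` with one row per mapped band: `chromosome`, `band`,
#'   `start`, `FTP`, `FOR`, `FDR`; attribute `per_cancer` holds the
#'   band x cancer count matrices (`over`, `down`).
#' @export
region_frequencies <- function(calls, annotation, map = NULL) {
  stopifnot(is.list(calls), length(calls) > 0, is.data.frame(annotation),
            all(c("probe_id", "chromosome", "band") %in% names(annotation)))
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    names(calls) <- paste0("cancer", seq_along(calls))
  }
  for (cn in names(calls)) {
    extra <- setdiff(calls[[cn]]$probe_id, annotation$probe_id)
    if (length(extra)) {
      stop("calls for ", cn, " contain probes absent from the chip annotation",
           " (chip mismatch), e.g. ", extra[1L])
    }
  }
  mapped <- annotation[annotation$band != "unmapped", , drop = FALSE]
  bands <- unique(mapped[, c("chromosome", "band")])
  bands <- bands[order(chromosome_order(bands$chromosome), bands$band), ,
                 drop = FALSE]
  ftp <- table(factor(mapped$band, levels = bands$band))
  band_of <- stats::setNames(mapped$band, mapped$probe_id)

  per_over <- matrix(0L, nrow(bands), length(calls),
                     dimnames = list(bands$band, names(calls)))
  per_down <- per_over
  for (cn in names(calls)) {
    dc <- calls[[cn]]
    b <- band_of[dc$probe_id]
    keep <- !is.na(b)
    tab_over <- table(factor(b[keep & dc$direction == "over"], levels = bands$band))
    tab_down <- table(factor(b[keep & dc$direction == "down"], levels = bands$band))
    per_over[, cn] <- as.integer(tab_over)
    per_down[, cn] <- as.integer(tab_down)
  }
  start <- rep(NA_real_, nrow(bands))
  if (!is.null(map)) start <- map$start[match(bands$band, map$band)]
  out <- data.frame(chromosome = bands$chromosome, band = bands$band,
                    start = start, FTP = as.integer(ftp),
                    FOR = as.integer(rowSums(per_over)),
                    FDR = as.integer(rowSums(per_down)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "per_cancer") <- list(over = per_over, down = per_down)
  out
}

#' Aggregate band frequencies to chromosomes
#'
#' Sums a band-level frequency table to chromosome level: FOC/FDC are the
#' altered counts summed over cancers, FCTP the total probesets on the chip
#' per chromosome (mapped probes only, so chromosome totals equal the sum of
#' their bands' totals).
#'
#' @param freq Output of [region_frequencies()].
#' @return `data.frame` with `chromosome`, `FCTP`, `FOC`, `FDC`.
#' @export
chromosome_frequencies <- function(freq) {
  stopifnot(all(c("chromosome", "FTP", "FOR", "FDR") %in% names(freq)))
  agg <- stats::aggregate(freq[, c("FTP", "FOR", "FDR")],
                          by = list(chromosome = freq$chromosome), FUN = sum)
  agg <- agg[order(chromosome_order(agg$chromosome)), , drop = FALSE]
  out <- data.frame(chromosome = agg$chromosome, FCTP = agg$FTP,
                    FOC = agg$FOR, FDC = agg$FDR, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Participation percentages per band or chromosome
#'
#' The region participation percentage is
#' `100 * FOR / (n_cancers * FTP)` for over-expression and
#' `100 * FDR / (n_cancers * FTP)` for down-expression (chromosome analogue:
#' FOC/FDC over FCTP). Regions whose chip denominator is zero are omitted
#' rather than scored 0, so they can never enter a top-k list. The
#' `denominator` flag switches to dividing by FTP alone for sensitivity
#' analysis.
#'
#' @param freq Output of [region_frequencies()] or [chromosome_frequencies()].
#' @param n_cancers Number of cancers pooled into the counts.
#' @param denominator `"n_ftp"` (default: n * total probes) or `"ftp"`.
#' @return The input rows (denominator > 0 only) with `percent_over` and
#'   `percent_down` columns appended.
#' @export
participation_percent <- function(freq, n_cancers,
                                  denominator = c("n_ftp", "ftp")) {
  denominator <- match.arg(denominator)
  stopifnot(n_cancers >= 1)
  is_chrom <- "FCTP" %in% names(freq)
  tot <- if (is_chrom) freq$FCTP else freq$FTP
  over <- if (is_chrom) freq$FOC else freq$FOR
  down <- if (is_chrom) freq$FDC else freq$FDR
  keep <- tot > 0
  freq <- freq[keep, , drop = FALSE]
  den <- if (denominator == "n_ftp") n_cancers * tot[keep] else tot[keep]
  freq$percent_over <- 100 * over[keep] / den
  freq$percent_down <- 100 * down[keep] / den
  rownames(freq) <- NULL
  freq
}

#' Select potential cancer-susceptibility regions (PCSRs)
#'
#' For each chromosome and each direction, picks the `k` bands with the
#' highest participation percentage. Ties are broken by genomic order
#' (chromosome, then band start, then band label), which makes the selection
#' deterministic; chromosomes with fewer than `k` scored bands return all of
#' them.
#'
#' @param scores Band-level output of [participation_percent()] (columns
#'   `chromosome`, `band`, `start`, `percent_over`, `percent_down`).
#' @param k Number of regions per chromosome and direction (default 5).
#' @return `data.frame` with `chromosome`, `direction`, `rank`, `band`,
#'   `percent`, ordered by chromosome, direction, rank.
#' @export
select_pcsrs <- function(scores, k = 5) {
  stopifnot(all(c("chromosome", "band", "percent_over", "percent_down")
                %in% names(scores)), k >= 1)
  start <- if ("start" %in% names(scores)) scores$start else rep(NA_real_, nrow(scores))
  start[is.na(start)] <- Inf
  pick <- function(dir) {
    pc <- if (dir == "over") scores$percent_over else scores$percent_down
    res <- lapply(unique(scores$chromosome), function(chr) {
      idx <- which(scores$chromosome == chr)
      o <- idx[order(-pc[idx], start[idx], scores$band[idx])]
      o <- o[seq_len(min(k, length(o)))]
      data.frame(chromosome = chr, direction = dir,
                 rank = seq_along(o), band = scores$band[o],
                 percent = pc[o], stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- rbind(pick("over"), pick("down"))
  out <- out[order(chromosome_order(out$chromosome),
                   out$direction, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chi-square test of chromosome participation
#'
#' Goodness-of-fit test of the per-chromosome altered counts against an
#' expectation proportional to each chromosome's share of chip probesets
#' (FCTP), with `#chromosomes - 1` degrees of freedom.
#'
#' @param chrom_freq Output of [chromosome_frequencies()].
#' @param direction `"over"` (uses FOC) or `"down"` (uses FDC).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chromosome_chi_square <- function(chrom_freq, direction = c("over", "down")) {
  direction <- match.arg(direction)
  stopifnot(nrow(chrom_freq) >= 2)
  obs <- if (direction == "over") chrom_freq$FOC else chrom_freq$FDC
  if (sum(obs) <= 0) stop("no altered probesets observed")
  if (any(chrom_freq$FCTP == 0)) {
    stop("chromosome(s) with zero chip probesets give expected counts of 0; ",
         "merge or exclude them before testing: ",
         paste(chrom_freq$chromosome[chrom_freq$FCTP == 0], collapse = ", "))
  }
  ht <- suppressWarnings(
    stats::chisq.test(obs, p = chrom_freq$FCTP / sum(chrom_freq$FCTP)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
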