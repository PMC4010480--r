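#' Pipeline run configuration
#'
#' All analysis thresholds with their standard defaults: 2-fold symmetric
#' change for mRNA probes and 1.5-fold for miRNA probes at alpha 0.05, a
#' 1.2-fold tracing threshold for the cross-cancer common-RNA step, top-200
#' ranking as the alternative region threshold, commonality in at least 6
#' cancers, 5 regions per chromosome, a strict 10-fold DDD ratio, a 0.1
#' promoter-enrichment cutoff and a 0.99 relative profile score.
#'
#' @param fold_mrna,fold_mirna,fold_trace Linear fold-change thresholds.
#' @param alpha Differential-call significance level.
#' @param top_n Size of the highest-fold-change alternative ranking.
#' @param top_n_p_filter Whether the top-n ranking is restricted to probes
#'   significant at `alpha` (default TRUE); `top_n` applies per direction.
#' @param min_cancers Cross-cancer commonality threshold.
#' @param k Regions selected per chromosome and direction.
#' @param ddd_ratio,ddd_alpha,ratio_mode DDD screen settings (see
#'   [ddd_screen()]).
#' @param pscan_alpha Promoter enrichment selection cutoff.
#' @param rel_score Relative profile score threshold for motif scans.
#' @param denominator Participation denominator flag (see
#'   [participation_percent()]).
#' @return A `run_config` list.
#' @export
run_config <- function(fold_mrna = 2, fold_mirna = 1.5, fold_trace = 1.2,
                       alpha = 0.05, top_n = 200, top_n_p_filter = TRUE,
                       min_cancers = 6, k = 5,
                       ddd_ratio = 10, ddd_alpha = 0.05,
                       ratio_mode = "symmetric",
                       pscan_alpha = 0.1, rel_score = 0.99,
                       denominator = "n_ftp") {
  structure(list(fold_mrna = fold_mrna, fold_mirna = fold_mirna,
                 fold_trace = fold_trace, alpha = alpha, top_n = top_n,
                 top_n_p_filter = top_n_p_filter, min_cancers = min_cancers,
                 k = k, ddd_ratio = ddd_ratio, ddd_alpha = ddd_alpha,
                 ratio_mode = ratio_mode, pscan_alpha = pscan_alpha,
                 rel_score = rel_score, denominator = denominator),
            class = "run_config")
}

write_report <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a synthetic input directory
#'
#' Materializes one draw of the synthetic generators as the on-disk formats
#' the pipeline reads: a UCSC-style cytoband file, a probe annotation TSV,
#' per-cancer expression matrices with a sample sheet, EST pool counts with a
#' sizes sidecar, promoter FASTA files and a PFM file holding the planted
#' motif. A `truth_regions.tsv` file records the planted bands for later
#' evaluation; the pipeline itself never reads it.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the ground-truth list
#'   (`genome`, `expression`, `est`, `promoters` truth components).
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  expr <- generate_expression(config, genome)
  est <- generate_est(config)
  prom <- generate_promoters(config)

  map <- genome$map
  writeLines(paste("chr", map$chromosome, "\t", map$start, "\t", map$end,
                   "\t", sub("^[^pq]*", "", map$band), "\t", map$stain,
                   sep = ""), file.path(dir, "cytoband.txt"))
  write_report(genome$probes[, c("probe_id", "gene_symbol", "rna_class",
                                 "chromosome", "position")],
               file.path(dir, "annotation.tsv"))
  samples <- do.call(rbind, lapply(expr$studies, function(st)
    data.frame(sample_id = colnames(st$matrix), group = st$group,
               cancer_id = st$cancer_id, stringsAsFactors = FALSE)))
  write_report(samples, file.path(dir, "samples.tsv"))
  for (st in expr$studies) {
    df <- data.frame(probe_id = rownames(st$matrix), st$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_report(df, file.path(dir, paste0("expr_", st$cancer_id, ".tsv")))
  }
  write_report(est$counts, file.path(dir, "est_counts.tsv"))
  write_report(data.frame(size_A = est$size_A, size_B = est$size_B),
               file.path(dir, "est_sizes.tsv"))
  write_promoter_fasta(prom$input, file.path(dir, "promoters_input.fa"))
  write_promoter_fasta(prom$background, file.path(dir, "promoters_background.fa"))
  motif <- toupper(config$promoters$motif)
  L <- nchar(motif)
  # heterogeneous off-consensus counts so columns differ in information
  # content (a flat 97/1/1/1 profile would make relative scores collapse to
  # the fraction of matching bases)
  off <- matrix(c(2, 5, 9, 5, 9, 2, 9, 2, 5), 3)[, rep(1:3, length.out = L),
                                                 drop = FALSE]
  pfm <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- match(strsplit(motif, "")[[1]], rownames(pfm))
  for (j in seq_len(L)) {
    pfm[-cons[j], j] <- off[, j]
    pfm[cons[j], j] <- 100 - sum(off[, j])
  }
  writeLines(c(">planted_motif",
               vapply(rownames(pfm), function(b)
                 paste0(b, " [ ", paste(pfm[b, ], collapse = " "), " ]"),
                 character(1))),
             file.path(dir, "motifs.pfm"))
  write_report(expr$truth$planted, file.path(dir, "truth_regions.tsv"))
  invisible(list(genome = genome, expression = expr$truth, est = est$truth,
                 promoters = prom$truth))
}

read_studies <- function(dir) {
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  studies <- list()
  for (cn in unique(samples$cancer_id)) {
    df <- utils::read.delim(file.path(dir, paste0("expr_", cn, ".tsv")),
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$probe_id
    sub <- samples[samples$cancer_id == cn, ]
    m <- m[, sub$sample_id, drop = FALSE]
    studies[[cn]] <- expression_study(cn, m, sub$group)
  }
  studies
}

#' Run the full PCSR analysis on an input directory
#'
#' Executes every stage on the files written by [simulate_inputs()] (or
#' equally formatted real inputs): per-cancer differential calls, band and
#' chromosome participation with top-k region selection under both the
#' fold-change and top-n thresholds, the chromosome chi-square test, the DDD
#' EST screen, cross-cancer common-RNA integration with class assignment and
#' risk-region flags, same-band miRNA cluster detection, and promoter motif
#' enrichment. All stages are deterministic: rerunning the same inputs and
#' configuration reproduces every report byte for byte.
#'
#' @param input_dir Directory of inputs (`cytoband.txt`, `annotation.tsv`,
#'   `samples.tsv`, `expr_<cancer>.tsv`; optionally `est_counts.tsv` +
#'   `est_sizes.tsv`, `promoters_input.fa` + `promoters_background.fa` +
#'   `motifs.pfm`).
#' @param out_dir Report directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a named list of the report `data.frame`s.
#' @export
run_pipeline <- function(input_dir, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  reports <- list()

  map <- stage("annotation", parse_cytoband_file(file.path(input_dir, "cytoband.txt")))
  ann <- stage("annotation", {
    a <- read_probe_annotation(file.path(input_dir, "annotation.tsv"))
    annotate_probes(a, map)
  })
  studies <- stage("expression", read_studies(input_dir))
  n_cancers <- length(studies)

  de <- stage("diffexpr", {
    lapply(studies, function(st) {
      fold <- log2_fold_change(st)
      p <- welch_t(st)
      thr <- ifelse(ann$rna_class[match(names(fold), ann$probe_id)] == "miRNA",
                    config$fold_mirna, config$fold_mrna)
      dir <- rep("unchanged", length(fold))
      for (th in unique(thr)) {
        i <- thr == th
        dir[i] <- call_directions(fold[i], p[i], th, config$alpha)
      }
      data.frame(probe_id = names(fold), log2fc = unname(fold),
                 p = unname(p), direction = dir, stringsAsFactors = FALSE)
    })
  })
  for (cn in names(de)) {
    write_report(de[[cn]], file.path(out_dir, paste0("de_", cn, ".tsv")))
  }

  reports$regions <- stage("region_scoring", {
    calls <- lapply(de, function(d) d[, c("probe_id", "direction")])
    freq <- region_frequencies(calls, ann, map)
    scores <- participation_percent(freq, n_cancers, config$denominator)
    pcsr <- select_pcsrs(scores, config$k)
    write_report(scores[, c("chromosome", "band", "FTP", "FOR", "FDR",
                            "percent_over", "percent_down")],
                 file.path(out_dir, "region_participation.tsv"))
    write_report(pcsr, file.path(out_dir, "pcsr_fold.tsv"))

    chrom <- chromosome_frequencies(freq)
    cscores <- participation_percent(chrom, n_cancers, config$denominator)
    write_report(cscores, file.path(out_dir, "chromosome_participation.tsv"))
    chi <- do.call(rbind, lapply(c("over", "down"), function(d) {
      obs <- if (d == "over") chrom$FOC else chrom$FDC
      if (sum(obs) == 0) {
        # nothing altered in this direction: report an empty test, not a crash
        return(data.frame(direction = d, statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, stringsAsFactors = FALSE))
      }
      h <- chromosome_chi_square(chrom, d)
      data.frame(direction = d, statistic = h$statistic, df = h$df,
                 p_value = h$p_value, stringsAsFactors = FALSE)
    }))
    write_report(chi, file.path(out_dir, "chi_square.tsv"))
    list(scores = scores, pcsr = pcsr, chromosomes = cscores, chi = chi)
  })

  reports$top_n <- stage("region_scoring_top_n", {
    calls <- lapply(de, function(d) {
      fold <- stats::setNames(d$log2fc, d$probe_id)
      p <- stats::setNames(d$p, d$probe_id)
      alpha <- if (config$top_n_p_filter) config$alpha else 1
      up <- top_n_by_fold(fold, p, config$top_n, "over", alpha)
      dn <- top_n_by_fold(fold, p, config$top_n, "down", alpha)
      data.frame(probe_id = c(up, dn),
                 direction = rep(c("over", "down"), c(length(up), length(dn))),
                 stringsAsFactors = FALSE)
    })
    freq <- region_frequencies(calls, ann, map)
    scores <- participation_percent(freq, n_cancers, config$denominator)
    pcsr <- select_pcsrs(scores, config$k)
    write_report(pcsr, file.path(out_dir, "pcsr_top_n.tsv"))
    list(scores = scores, pcsr = pcsr)
  })

  reports$common <- stage("integration", {
    trace <- lapply(names(de), function(cn) {
      d <- de[[cn]]
      dir <- call_directions(stats::setNames(d$log2fc, d$probe_id),
                             stats::setNames(d$p, d$probe_id),
                             config$fold_trace, config$alpha)
      alt <- dir != "unchanged"
      if (!any(alt)) return(NULL)
      data.frame(gene = ann$gene_symbol[match(d$probe_id[alt], ann$probe_id)],
                 cancer = cn, direction = unname(dir[alt]),
                 source = "microarray", stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, trace)
    if (is.null(calls) || nrow(calls) == 0L) {
      common <- data.frame(gene = character(0), n_cancers_altered = integer(0),
                           location = character(0), class = character(0),
                           on_pcsr = logical(0), stringsAsFactors = FALSE)
    } else {
      common <- collect_common(calls, config$min_cancers, n_cancers)
      common$location <- ann$band[match(common$gene, ann$gene_symbol)]
      cls <- assign_classes(calls[calls$gene %in% common$gene, , drop = FALSE])
      common$class <- cls$class[match(common$gene, cls$gene)]
      common <- flag_pcsr(common, reports$regions$pcsr)
    }
    write_report(common, file.path(out_dir, "common_rna.tsv"))
    mirna_genes <- ann[ann$rna_class == "miRNA", , drop = FALSE]
    mrec <- data.frame(mirna = common$gene, location = common$location,
                       stringsAsFactors = FALSE)
    mrec <- mrec[common$gene %in% mirna_genes$gene_symbol, , drop = FALSE]
    clusters <- detect_mirna_clusters(mrec)
    clusters_out <- flag_pcsr(
      data.frame(band = clusters$band, n_members = clusters$n_members,
                 members = clusters$members, location = clusters$band,
                 stringsAsFactors = FALSE),
      reports$regions$pcsr)
    write_report(clusters_out[, c("band", "n_members", "members", "on_pcsr")],
                 file.path(out_dir, "mirna_clusters.tsv"))
    list(common = common, clusters = clusters_out)
  })

  if (file.exists(file.path(input_dir, "est_counts.tsv"))) {
    reports$ddd <- stage("ddd", {
      counts <- utils::read.delim(file.path(input_dir, "est_counts.tsv"),
                                  stringsAsFactors = FALSE)
      sizes <- utils::read.delim(file.path(input_dir, "est_sizes.tsv"))
      res <- ddd_screen(counts, sizes$size_A, sizes$size_B,
                        config$ddd_ratio, config$ddd_alpha, config$ratio_mode)
      write_report(res, file.path(out_dir, "ddd.tsv"))
      res
    })
  }

  if (file.exists(file.path(input_dir, "promoters_input.fa"))) {
    reports$tf <- stage("promoter_scan", {
      input <- read_promoter_fasta(file.path(input_dir, "promoters_input.fa"))
      bg <- read_promoter_fasta(file.path(input_dir, "promoters_background.fa"))
      pfms <- read_jaspar_pfm(file.path(input_dir, "motifs.pfm"))
      enr <- do.call(rbind, lapply(names(pfms), function(nm) {
        pw <- pfm_to_pwm(pfms[[nm]], name = nm)
        pscan_ztest(input, bg, pw)
      }))
      enr$selected <- enr$p_value < config$pscan_alpha
      write_report(enr, file.path(out_dir, "tf_enrichment.tsv"))
      enr
    })
  }

  manifest <- data.frame(
    key = c("package", "version",
            paste0("config.", names(unclass(config))),
            paste0("md5.", basename(input_files <- Filter(
              function(f) !dir.exists(f),
              sort(list.files(input_dir, full.names = TRUE)))))),
    value = c("pcsrscan", as.character(utils::packageVersion("pcsrscan")),
              vapply(unclass(config), function(v) paste(format(v), collapse = ","),
                     character(1)),
              unname(tools::md5sum(input_files))),
    stringsAsFactors = FALSE)
  write_report(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(reports)
}
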