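#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators. The defaults define
#' the reference desk-scale study: a small genome of 5 chromosomes x 8 bands
#' x 40 probes, an 11-cancer panel with 5 case and 5 control samples each,
#' log2-normal noise of 0.25, and three planted risk regions (log2 effect 1.5
#' on 30% of the band's probes, affecting 8 of the 11 cancers). EST pools
#' default to 200 clusters of 1e5 ESTs per pool — the depth of aggregated
#' UniGene pools — with 10 clusters inflated 50-fold in the cancer pool.
#'
#' @param seed Integer seed; every generator is a pure function of the config
#'   (same config, same output).
#' @param n_chromosomes,bands_per_chromosome,probes_per_band Genome layout;
#'   probe counts per band are fixed at `probes_per_band`.
#' @param n_cancers,samples_per_group Study panel dimensions.
#' @param noise_sd Log2-scale standard deviation of expression noise.
#' @param baseline Mean log2 intensity of unaffected probes.
#' @param n_planted Number of planted risk bands.
#' @param planted_effect Log2 shift applied to altered probes in cases.
#' @param planted_fraction Fraction of a planted band's probes that are
#'   altered.
#' @param planted_cancers Number of cancers affected by each planted band.
#' @param planted_directions Directions recycled over planted bands.
#' @param mirna_fraction Fraction of probes annotated as miRNA.
#' @param est List: `n_clusters`, `size_A`, `size_B`, `n_planted`,
#'   `planted_fold`.
#' @param promoters List: `n_input`, `n_background`, `length`,
#'   `planted_fraction`, `motif` (consensus inserted into input promoters).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       bands_per_chromosome = 8L,
                       probes_per_band = 40L,
                       n_cancers = 11L,
                       samples_per_group = 5L,
                       noise_sd = 0.25,
                       baseline = 8,
                       n_planted = 3L,
                       planted_effect = 1.5,
                       planted_fraction = 0.3,
                       planted_cancers = 8L,
                       planted_directions = c("over", "over", "down"),
                       mirna_fraction = 0,
                       est = list(n_clusters = 200L, size_A = 1e5,
                                  size_B = 1e5, n_planted = 10L,
                                  planted_fold = 50),
                       promoters = list(n_input = 10L, n_background = 200L,
                                        length = 500L, planted_fraction = 1,
                                        motif = "TGACGTCA")) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              bands_per_chromosome = bands_per_chromosome,
              probes_per_band = probes_per_band, n_cancers = n_cancers,
              samples_per_group = samples_per_group, noise_sd = noise_sd,
              baseline = baseline, n_planted = n_planted,
              planted_effect = planted_effect,
              planted_fraction = planted_fraction,
              planted_cancers = planted_cancers,
              planted_directions = planted_directions,
              mirna_fraction = mirna_fraction, est = est,
              promoters = promoters)
  stopifnot(cfg$planted_fraction >= 0, cfg$planted_fraction <= 1,
            cfg$planted_effect >= 0, cfg$noise_sd > 0,
            cfg$planted_cancers <= cfg$n_cancers,
            cfg$mirna_fraction >= 0, cfg$mirna_fraction <= 1,
            cfg$samples_per_group >= 2)
  class(cfg) <- "sim_config"
  cfg
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic genome (cytoband map + probe annotation)
#'
#' Builds contiguous, non-overlapping 1-Mb bands per chromosome (first half p
#' arm, second half q arm) and places `probes_per_band` probes uniformly
#' within each band. Band membership is recorded directly, giving ground
#' truth against which [locate_band()] can be checked.
#'
#' @param config A [sim_config()].
#' @return List with `map` (a `cytoband_map`) and `probes` (annotation
#'   `data.frame` with `probe_id`, `gene_symbol`, `rna_class`, `chromosome`,
#'   `position`, `band`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, {
    bw <- 1e6
    B <- config$bands_per_chromosome
    rows <- list()
    for (c_i in seq_len(config$n_chromosomes)) {
      chr <- as.character(c_i)
      arm <- ifelse(seq_len(B) <= B / 2, "p", "q")
      # arm-local numbering: p11..p1k then q11..q1k
      num <- stats::ave(seq_len(B), arm, FUN = seq_along)
      rows[[c_i]] <- data.frame(
        chromosome = chr, start = (seq_len(B) - 1) * bw, end = seq_len(B) * bw,
        band = paste0(chr, arm, "1", num), stain = "gneg",
        stringsAsFactors = FALSE)
    }
    map <- validate_cytoband_map(do.call(rbind, rows))
    n_probes <- nrow(map) * config$probes_per_band
    band_idx <- rep(seq_len(nrow(map)), each = config$probes_per_band)
    position <- floor(stats::runif(n_probes, map$start[band_idx],
                                   map$end[band_idx]))
    rna_class <- ifelse(stats::runif(n_probes) < config$mirna_fraction,
                        "miRNA", "mRNA")
    probes <- data.frame(
      probe_id = sprintf("PS%05d", seq_len(n_probes)),
      gene_symbol = sprintf("G%05d", seq_len(n_probes)),
      rna_class = rna_class,
      chromosome = map$chromosome[band_idx],
      position = position,
      band = map$band[band_idx],
      stringsAsFactors = FALSE)
    list(map = map, probes = probes)
  })
}

#' Generate per-cancer expression studies with planted risk regions
#'
#' Control samples are drawn i.i.d. `Normal(baseline, noise_sd)` per probe on
#' the log2 scale (mimicking RMA-normalized intensities). For each planted
#' band, a fixed random subset of its probes (`planted_fraction`) is shifted
#' by `planted_effect` (sign by direction) in the case samples of a fixed
#' random subset of cancers (`planted_cancers` of `n_cancers`), emulating
#' risk regions shared by most but not all cancers. The same probes are
#' altered in every affected cancer.
#'
#' @param config A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @return List with `studies` (named list of [expression_study()]) and
#'   `truth`: `planted` (`data.frame`: `band`, `chromosome`, `direction`,
#'   `effect`, `fraction`), `cancers` (list of affected cancer ids per band),
#'   `probes` (list of altered probe ids per band).
#' @export
generate_expression <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed + 1L, {
    probes <- genome$probes
    all_bands <- unique(probes$band)
    stopifnot(config$n_planted <= length(all_bands))
    planted_bands <- sample(all_bands, config$n_planted)
    dirs <- rep_len(config$planted_directions, config$n_planted)
    cancer_ids <- sprintf("cancer%02d", seq_len(config$n_cancers))
    affected <- lapply(seq_len(config$n_planted), function(i)
      sort(sample(cancer_ids, config$planted_cancers)))
    alt_probes <- lapply(planted_bands, function(b) {
      ids <- probes$probe_id[probes$band == b]
      sort(sample(ids, round(config$planted_fraction * length(ids))))
    })
    spg <- config$samples_per_group
    np <- nrow(probes)
    shift <- stats::setNames(numeric(np), probes$probe_id)
    studies <- list()
    for (cn in cancer_ids) {
      m <- matrix(stats::rnorm(np * 2 * spg, config$baseline, config$noise_sd),
                  nrow = np,
                  dimnames = list(probes$probe_id,
                                  c(paste0(cn, "_ctrl", seq_len(spg)),
                                    paste0(cn, "_case", seq_len(spg)))))
      delta <- shift
      for (i in seq_len(config$n_planted)) {
        if (cn %in% affected[[i]]) {
          delta[alt_probes[[i]]] <- delta[alt_probes[[i]]] +
            ifelse(dirs[i] == "over", 1, -1) * config$planted_effect
        }
      }
      m[, spg + seq_len(spg)] <- m[, spg + seq_len(spg)] + delta
      studies[[cn]] <- expression_study(cn, m,
                                        rep(c("control", "case"), each = spg))
    }
    truth <- list(
      planted = data.frame(
        band = planted_bands,
        chromosome = probes$chromosome[match(planted_bands, probes$band)],
        direction = dirs, effect = config$planted_effect,
        fraction = config$planted_fraction, stringsAsFactors = FALSE),
      cancers = stats::setNames(affected, planted_bands),
      probes = stats::setNames(alt_probes, planted_bands))
    list(studies = studies, truth = truth)
  })
}

#' Generate EST pool counts with planted overrepresentation
#'
#' Base cluster frequencies are drawn from a gamma profile and renormalized;
#' pool A counts are multinomial at those frequencies, while pool B counts use
#' frequencies in which the planted clusters are inflated `planted_fold`-fold
#' before renormalization (`planted_fold = 1` is the exchangeable null).
#'
#' @param config A [sim_config()] (`config$est` is used).
#' @return List with `counts` (`data.frame`: `cluster_id`, `count_A`,
#'   `count_B`), `size_A`, `size_B` and `truth` (planted cluster ids).
#' @export
generate_est <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  e <- config$est
  with_rng(config$seed + 2L, {
    K <- e$n_clusters
    base <- stats::rgamma(K, shape = 5, rate = 1)
    pA <- base / sum(base)
    planted <- if (e$n_planted > 0) sort(sample(K, e$n_planted)) else integer(0)
    w <- pA
    w[planted] <- w[planted] * e$planted_fold
    pB <- w / sum(w)
    ids <- sprintf("Cl%04d", seq_len(K))
    counts <- data.frame(
      cluster_id = ids,
      count_A = as.vector(stats::rmultinom(1, e$size_A, pA)),
      count_B = as.vector(stats::rmultinom(1, e$size_B, pB)),
      stringsAsFactors = FALSE)
    list(counts = counts, size_A = e$size_A, size_B = e$size_B,
         truth = ids[planted])
  })
}

#' Generate promoter sets with a planted motif
#'
#' Sequences are i.i.d. uniform DNA. The consensus of `config$promoters$motif`
#' is inserted (overwriting the sequence) at a random offset into a fraction
#' `planted_fraction` of the input promoters; the background stays clean.
#'
#' @param config A [sim_config()] (`config$promoters` is used).
#' @return List with `input`, `background` (named character vectors) and
#'   `truth` (`data.frame`: `id`, `offset` 1-based of each insertion).
#' @export
generate_promoters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$promoters
  with_rng(config$seed + 3L, {
    rand_seq <- function(n, len) {
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
    }
    input <- stats::setNames(rand_seq(p$n_input, p$length),
                             sprintf("input%03d", seq_len(p$n_input)))
    background <- stats::setNames(rand_seq(p$n_background, p$length),
                                  sprintf("bg%03d", seq_len(p$n_background)))
    motif <- toupper(p$motif)
    L <- nchar(motif)
    stopifnot(L <= p$length)
    n_pl <- round(p$planted_fraction * p$n_input)
    pl <- if (n_pl > 0) sort(sample(p$n_input, n_pl)) else integer(0)
    offs <- integer(0)
    if (length(pl)) {
      offs <- sample(p$length - L + 1L, length(pl), replace = TRUE)
      for (j in seq_along(pl)) {
        s <- input[[pl[j]]]
        substr(s, offs[j], offs[j] + L - 1L) <- motif
        input[[pl[j]]] <- s
      }
    }
    list(input = input, background = background,
         truth = data.frame(id = names(input)[pl], offset = offs,
                            stringsAsFactors = FALSE))
  })
}
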