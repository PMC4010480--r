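# Shared builders and independent oracles used across the suite.

toy_cytoband_lines <- function() {
  c("chr1\t0\t100\tp1\tgneg",
    "chr1\t100\t300\tq1\tgpos50",
    "chr2\t0\t150\tp1\tgneg",
    "chr2\t150\t400\tq1\tgneg")
}

toy_map <- function(lines = toy_cytoband_lines()) {
  parse_cytoband_file(textConnection(lines))
}

# brute-force band lookup: linear scan over all intervals
brute_locate <- function(chromosome, position, map) {
  vapply(seq_along(chromosome), function(i) {
    hit <- which(map$chromosome == chromosome[i] &
                 map$start <= position[i] & position[i] < map$end)
    if (length(hit) == 1L) map$band[hit] else "unmapped"
  }, character(1))
}

# random cytoband map with n_band non-overlapping intervals per chromosome
random_map <- function(n_chrom = 3, n_band = 4) {
  rows <- lapply(seq_len(n_chrom), function(ci) {
    cuts <- sort(sample(1:500, n_band + 1))
    data.frame(chromosome = as.character(ci),
               start = cuts[-(n_band + 1)], end = cuts[-1],
               band = paste0(ci, "b", seq_len(n_band)),
               stain = "gneg", stringsAsFactors = FALSE)
  })
  validate_cytoband_map(do.call(rbind, rows))
}

make_study <- function(seed = 1, n_probes = 20, n_per_group = 4,
                       cancer_id = "toy") {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * 2 * n_per_group, 8, 0.5), nrow = n_probes,
              dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                              paste0("s", seq_len(2 * n_per_group))))
  expression_study(cancer_id, m, rep(c("control", "case"), each = n_per_group))
}

# exact two-sided Fisher p via explicit binomial-coefficient enumeration over
# the full support (independent of dhyper)
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  supp <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, supp) * choose(r2, c1 - supp) / choose(n, c1)
  sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
}

# brute-force two-strand sliding-window best relative score
brute_best_hit <- function(sequence, pwm) {
  score_strand <- function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- ncol(pwm$pwm)
    best <- -Inf
    for (o in seq_len(length(ch) - L + 1)) {
      win <- ch[o:(o + L - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      best <- max(best, sum(vapply(seq_len(L),
        function(j) pwm$pwm[win[j], j], numeric(1))))
    }
    best
  }
  revcomp <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  s <- max(score_strand(sequence), score_strand(revcomp(sequence)))
  if (pwm$s_max == pwm$s_min) return(1)
  (s - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

random_pfm <- function(len = 6) {
  matrix(sample(0:20, 4 * len, replace = TRUE), nrow = 4,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# combined mRNA catalogue fixtures (both class tables), loaded once
load_mrna_fixture <- function() {
  t1 <- read_common_rna_table(pcsr_example_file("common_mrna_classI_II.tsv"))
  t2 <- read_common_rna_table(pcsr_example_file("common_mrna_classIII.tsv"))
  list(genes = rbind(t1$genes, t2$genes), calls = rbind(t1$calls, t2$calls))
}

load_mirna_fixture <- function() {
  read_mirna_table(pcsr_example_file("common_mirna.tsv"))
}

gene_record <- function(calls, gene) {
  calls[calls$gene == gene, , drop = FALSE]
}
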