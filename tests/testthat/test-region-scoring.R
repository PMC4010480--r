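ann_from_map <- function(map, probes_per_band = 4) {
  idx <- rep(seq_len(nrow(map)), each = probes_per_band)
  n <- length(idx)
  data.frame(probe_id = sprintf("P%03d", seq_len(n)),
             gene_symbol = sprintf("G%03d", seq_len(n)),
             rna_class = "mRNA",
             chromosome = map$chromosome[idx],
             position = floor((map$start[idx] + map$end[idx]) / 2),
             band = map$band[idx], stringsAsFactors = FALSE)
}

test_that("region frequencies count altered probes per band", {
  map <- toy_map()
  ann <- ann_from_map(map)
  none <- list(c1 = data.frame(probe_id = ann$probe_id, direction = "unchanged"))
  freq <- region_frequencies(none, ann, map)
  expect_true(all(freq$FOR == 0) && all(freq$FDR == 0))
  expect_equal(freq$FTP, rep(4L, 4))

  # one band with 4 probes of which 3 over
  one <- list(c1 = data.frame(
    probe_id = ann$probe_id[ann$band == "1p1"],
    direction = c("over", "over", "over", "unchanged")))
  freq <- region_frequencies(one, ann, map)
  expect_equal(freq$FOR[freq$band == "1p1"], 3L)
  expect_equal(freq$FTP[freq$band == "1p1"], 4L)
})

test_that("region frequencies equal an independent group-by tally", {
  set.seed(31)
  map <- random_map(3, 4)
  ann <- ann_from_map(map, 6)
  calls <- lapply(1:3, function(i)
    data.frame(probe_id = ann$probe_id,
               direction = sample(c("over", "down", "unchanged"),
                                  nrow(ann), replace = TRUE),
               stringsAsFactors = FALSE))
  names(calls) <- paste0("c", 1:3)
  freq <- region_frequencies(calls, ann, map)
  for (b in freq$band) {
    ids <- ann$probe_id[ann$band == b]
    exp_over <- sum(vapply(calls, function(d)
      sum(d$direction == "over" & d$probe_id %in% ids), 1L))
    exp_down <- sum(vapply(calls, function(d)
      sum(d$direction == "down" & d$probe_id %in% ids), 1L))
    expect_equal(freq$FOR[freq$band == b], exp_over)
    expect_equal(freq$FDR[freq$band == b], exp_down)
  }
  # conservation: per-cancer band contributions sum to that cancer's calls
  per <- attr(freq, "per_cancer")
  for (cn in names(calls)) {
    expect_equal(sum(per$over[, cn]), sum(calls[[cn]]$direction == "over"))
    expect_equal(sum(per$down[, cn]), sum(calls[[cn]]$direction == "down"))
  }
})

test_that("probes outside the chip annotation raise a chip mismatch", {
  map <- toy_map()
  ann <- ann_from_map(map)
  bad <- list(c1 = data.frame(probe_id = "NOT_ON_CHIP", direction = "over"))
  expect_error(region_frequencies(bad, ann, map), "chip mismatch")
})

test_that("participation percentage follows 100*F/(n*FTP) and omits FTP=0", {
  freq <- data.frame(chromosome = c("1", "1"), band = c("1p1", "1q1"),
                     start = c(0, 100), FTP = c(10L, 0L),
                     FOR = c(6L, 0L), FDR = c(30L, 0L))
  sc <- participation_percent(freq, n_cancers = 3)
  expect_equal(nrow(sc), 1L)   # FTP = 0 band omitted
  expect_equal(sc$percent_over, 100 * 6 / (3 * 10))   # 20%
  expect_equal(sc$percent_down, 100)                  # every probe, every cancer
  # denominator flag: divide by FTP alone
  sc2 <- participation_percent(freq, 3, denominator = "ftp")
  expect_equal(sc2$percent_over, 60)
})

test_that("adding an over call never decreases percent_over", {
  map <- toy_map()
  ann <- ann_from_map(map)
  set.seed(8)
  base <- data.frame(probe_id = ann$probe_id,
                     direction = sample(c("over", "unchanged"), nrow(ann),
                                        replace = TRUE),
                     stringsAsFactors = FALSE)
  more <- base
  i <- which(more$direction == "unchanged")[1]
  more$direction[i] <- "over"
  p1 <- participation_percent(region_frequencies(list(a = base), ann, map), 1)
  p2 <- participation_percent(region_frequencies(list(a = more), ann, map), 1)
  expect_true(all(p2$percent_over >= p1$percent_over))
})

test_that("PCSR selection keeps the k best per chromosome with genomic ties", {
  sc <- data.frame(chromosome = "1",
                   band = paste0("1b", 1:8),
                   start = (0:7) * 100,
                   percent_over = c(9, 8, 7, 6, 5, 5, 4, 3),
                   percent_down = 0)
  top <- select_pcsrs(sc, k = 5)
  over <- top[top$direction == "over", ]
  # two-way tie at rank 5: the genomically earlier band (1b5) wins
  oracle <- sc$band[order(-sc$percent_over, sc$start)][1:5]
  expect_equal(over$band, oracle)
  expect_equal(over$rank, 1:5)

  few <- select_pcsrs(sc[1:3, ], k = 5)
  expect_equal(nrow(few[few$direction == "over", ]), 3L)
})

test_that("chromosome aggregation and chi-square match hand calculations", {
  map <- toy_map()
  ann <- ann_from_map(map)
  calls <- list(c1 = data.frame(probe_id = ann$probe_id[1:6],
                                direction = rep("over", 6)))
  freq <- region_frequencies(calls, ann, map)
  chrom <- chromosome_frequencies(freq)
  expect_equal(chrom$FCTP, c(8L, 8L))
  expect_equal(sum(chrom$FOC), 6L)

  # observed exactly proportional to FCTP
  cf <- data.frame(chromosome = c("1", "2"), FCTP = c(50L, 50L),
                   FOC = c(20L, 20L), FDC = c(0L, 0L))
  res <- chromosome_chi_square(cf, "over")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  cf2 <- data.frame(chromosome = c("1", "2"), FCTP = c(50L, 50L),
                    FOC = c(10L, 0L), FDC = c(1L, 1L))
  res2 <- chromosome_chi_square(cf2, "over")
  expect_equal(res2$statistic, 10)   # (5^2)/5 + (5^2)/5
  expect_equal(res2$df, 1)

  cf3 <- data.frame(chromosome = c("1", "2"), FCTP = c(50L, 0L),
                    FOC = c(10L, 0L), FDC = c(0L, 0L))
  expect_error(chromosome_chi_square(cf3, "over"), "merge or exclude")
})
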