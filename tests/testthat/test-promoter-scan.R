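test_that("JASPAR flat PFM files are parsed in both dialects", {
  f <- tempfile()
  writeLines(c(">MA0001 TOY",
               "A [ 4 19 0 ]",
               "C [ 16 0 20 ]",
               "G [ 0 1 0 ]",
               "T [ 0 0 0 ]",
               ">BARE",
               "1 2", "3 4", "5 6", "7 8"), f)
  pfms <- read_jaspar_pfm(f)
  expect_named(pfms, c("MA0001_TOY", "BARE"))
  expect_equal(pfms$MA0001_TOY["C", ], c(16, 0, 20))
  expect_equal(pfms$BARE["T", ], c(7, 8))
})

test_that("pfm_to_pwm applies the smoothed log-odds formula", {
  uni <- matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pw <- pfm_to_pwm(uni)
  expect_true(all(abs(pw$pwm) < 1e-12))
  expect_equal(pw$s_min, 0)
  expect_equal(pw$s_max, 0)

  single <- matrix(c(10, 0, 0, 0), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pw <- pfm_to_pwm(single, pseudocount = 1)
  # hand arithmetic: log2(((count + 1*0.25) / (10 + 1)) / 0.25)
  expect_equal(unname(pw$pwm[, 1]),
               log2((c(10, 0, 0, 0) + 0.25) / 11 / 0.25))
  expect_equal(pw$s_max, log2(10.25 / 11 / 0.25))
  expect_equal(pw$s_min, log2(0.25 / 11 / 0.25))

  # the column-wise best-scoring base is the most frequent one
  set.seed(5)
  pfm <- random_pfm(8)
  pw <- pfm_to_pwm(pfm)
  for (j in 1:8) {
    expect_equal(which.max(pw$pwm[, j]), which.max(pfm[, j]))
  }
  expect_error(pfm_to_pwm(matrix(numeric(0), 4, 0)), "empty")
})

test_that("best-hit relative score spans [0, 1] at consensus/anti-consensus", {
  pfm <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm["A", ] <- 10                       # consensus AAAA
  pw <- pfm_to_pwm(pfm)
  expect_equal(best_hit_relative_score("AAAA", pw), 1)
  # CCCC scores the minimum on the forward strand and its complement GGGG
  # ties the same minimum, so the best over both strands is exactly 0
  expect_equal(best_hit_relative_score("CCCC", pw), 0)
  expect_error(best_hit_relative_score("AA", pw), "shorter")

  uni <- pfm_to_pwm(matrix(2, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(best_hit_relative_score("ACGTAG", uni), 1)  # degenerate motif
})

test_that("best-hit equals the brute-force two-strand scan", {
  set.seed(13)
  for (i in 1:25) {
    pw <- pfm_to_pwm(random_pfm(6))
    seq <- random_dna(60)
    expect_equal(best_hit_relative_score(seq, pw), brute_best_hit(seq, pw))
  }
})

test_that("score is invariant under reverse complement and skips N windows", {
  set.seed(19)
  pw <- pfm_to_pwm(random_pfm(5))
  seq <- random_dna(80)
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(seq, "")[[1]])), collapse = "")
  expect_equal(best_hit_relative_score(seq, pw),
               best_hit_relative_score(rc, pw))

  withN <- paste0(substr(seq, 1, 40), "N", substr(seq, 42, 80))
  expect_true(is.finite(best_hit_relative_score(withN, pw)))
  expect_warning(best_hit_relative_score("NNNNNNNN", pw), "no window")
})

test_that("threshold scans are inclusive and anti-monotone in the threshold", {
  pfm <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm["G", ] <- 12
  pw <- pfm_to_pwm(pfm)
  proms <- c(hit = paste0("AAAA", "GGGGGG", "TTTT"), miss = "ACACACACACACAC")
  expect_equal(scan_threshold(proms, pw, 0.99), "hit")
  expect_equal(scan_threshold(proms, pw,
               best_hit_relative_score(proms["miss"], pw)),  # inclusive
               c("hit", "miss"))
  expect_equal(scan_threshold(character(0), pw), character(0))

  set.seed(3)
  proms <- setNames(replicate(30, random_dna(50)), paste0("p", 1:30))
  prev <- scan_threshold(proms, pw, 0.5)
  for (th in c(0.7, 0.9, 0.99)) {
    cur <- scan_threshold(proms, pw, th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("pscan z-test behaves at the fixed points and finds planted motifs", {
  set.seed(29)
  pw <- pfm_to_pwm(random_pfm(6))
  bg <- setNames(replicate(60, random_dna(100)), paste0("b", 1:60))
  same <- pscan_ztest(bg, bg, pw)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 0.5)

  cfg <- sim_config(seed = 101, promoters = list(n_input = 8,
          n_background = 80, length = 300, planted_fraction = 1,
          motif = "TTGACGTCAT"))
  prom <- generate_promoters(cfg)
  consensus <- pfm_to_pwm(local({
    m <- matrix(1, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(strsplit("TTGACGTCAT", "")[[1]], rownames(m)), 1:10)] <- 20
    m
  }), name = "planted")
  res <- pscan_ztest(prom$input, prom$background, consensus)
  expect_lt(res$p_value, 0.1)

  flat <- setNames(rep("ACGTACGTAC", 10), paste0("f", 1:10))
  expect_error(pscan_ztest(flat, flat, pw), "degenerate")
})

test_that("common regulators require hits in every cluster member", {
  m <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(strsplit("TGACGTCA", "")[[1]], rownames(m)), 1:8)] <- 40
  tf1 <- pfm_to_pwm(m, name = "TF1")
  m2 <- m[c(4, 3, 2, 1), ]; rownames(m2) <- c("A", "C", "G", "T")
  tf2 <- pfm_to_pwm(m2, name = "TF2")

  with_site <- function(n) setNames(vapply(seq_len(n), function(i)
    paste0(random_dna(20), "TGACGTCA", random_dna(20)), ""), paste0("s", 1:n))
  set.seed(7)
  cl1 <- with_site(3)
  cl2 <- with_site(2)
  cl3 <- c(with_site(1), none = random_dna(48))  # TF1 hits 1 of 2 members

  res <- common_regulators(list(a = cl1, b = cl2, c = cl3),
                           list(tf1, tf2), mode = "all_members")
  expect_true("TF1" %in% res$per_group$a && "TF1" %in% res$per_group$b)
  expect_false("TF1" %in% res$per_group$c)
  expect_true("TF1" %in% res$shared)
  expect_false("TF1" %in% res$common_all)
})
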