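toy_pwm <- function() {
  # width 2: pos1 favours C, pos2 favours A (prob 0.5, others 1/6)
  pwm <- build_pwm(c("CA"), pseudocount = 0)
  pwm$prob <- matrix(c(1 / 6, 0.5, 1 / 6, 1 / 6,
                       0.5, 1 / 6, 1 / 6, 1 / 6),
                     nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm$width <- 2L
  pwm
}

test_that("PWM estimation applies the pseudocount formula", {
  p0 <- build_pwm(c("AA", "AA"), pseudocount = 0)
  expect_equal(unname(p0$prob["A", ]), c(1, 1))
  p1 <- build_pwm("AC", pseudocount = 0.5)
  expect_equal(unname(p1$prob["A", 1]), 1.5 / 3)
  expect_equal(unname(p1$prob["G", 1]), 0.5 / 3)
  expect_equal(unname(p1$prob["C", 2]), 0.5)
  p2 <- build_pwm(c("AC", "AG"), pseudocount = 0)
  expect_equal(unname(p2$prob["C", 2]), 0.5)
  expect_equal(unname(p2$prob["G", 2]), 0.5)
  expect_true(all(abs(colSums(p1$prob) - 1) < 1e-9))
  expect_error(build_pwm(c("AC", "A")), "equal length")
  expect_error(build_pwm("ACN"), "only A, C, G, T")
})

test_that("PWMs round-trip through TSV and MEME-style text", {
  pwm <- example_motif_pwm()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, tsv)
  expect_equal(read_pwm(tsv)$prob, pwm$prob, tolerance = 1e-9,
               ignore_attr = TRUE)
  meme <- withr::local_tempfile(fileext = ".txt")
  write_pwm_meme(pwm, meme)
  expect_equal(read_pwm_meme(meme)$prob, pwm$prob, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("site sequences are windows around peak centers, clipped at ends", {
  genome <- c(chrT = paste(rep("ACGT", 300), collapse = ""))
  peaks <- tibble::tibble(chrom = "chrT", peak_start = 480, peak_end = 520)
  got <- extract_site_sequences(genome, peaks, flank = 200)
  expect_equal(unname(nchar(got$seq)), 400)
  expect_equal(c(got$start, got$end), c(300, 700))
  expect_equal(got$seq, unname(toupper(substr(genome, 301, 700))))

  near <- tibble::tibble(chrom = "chrT", peak_start = 90, peak_end = 110)
  expect_warning(clip <- extract_site_sequences(genome, near, flank = 200),
                 "clipped")
  expect_equal(c(clip$start, clip$end), c(0, 300))

  # a planted marker string is recovered exactly
  marked <- genome
  substr(marked, 491, 510) <- "GGGGGGGGGGCCCCCCCCCC"
  got2 <- extract_site_sequences(marked, peaks, flank = 200)
  expect_match(got2$seq, "GGGGGGGGGGCCCCCCCCCC")
})

test_that("best-window scoring handles strands, ties and short sequences", {
  pwm <- toy_pwm()
  hit <- score_best_window("CA", pwm)
  expect_equal(hit$score, 2)
  expect_equal(hit$strand, "+")
  expect_equal(hit$offset, 0L)

  hit_rc <- score_best_window("TG", pwm)
  expect_equal(hit_rc$score, 2)
  expect_equal(hit_rc$strand, "-")

  expect_error(score_best_window("C", pwm), "at least PWM width")
  # N bases contribute the background odds (score 0), not -Inf
  hit_n <- score_best_window("NN", pwm)
  expect_equal(hit_n$score, 0)
})

test_that("best-window scan equals the exhaustive offset x strand oracle", {
  set.seed(31)
  pwm <- example_motif_pwm()
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(20:80, 1), TRUE),
                 collapse = "")
    got <- score_best_window(seq, pwm)
    want <- oracle_best_window(seq, pwm)
    expect_equal(got$score, want$score)
    expect_equal(got$strand, want$strand)
    expect_equal(got$offset, as.integer(want$offset))
    # reverse complement preserves the best score
    rc <- score_best_window(reverse_complement(seq), pwm)
    expect_equal(rc$score, got$score)
  }
})

test_that("core counting includes both strands with overlaps allowed", {
  expect_equal(count_core("GCCATGCCAT"), 2L)
  expect_equal(count_core("ATGGC"), 1L)
  expect_equal(count_core("AAAAA"), 0L)
  expect_equal(count_core("ATGGC", both_strands = FALSE), 0L)
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    expect_equal(count_core(s), count_core(reverse_complement(s)))
  }
})

test_that("strength bins split equal-count with remainder to the strongest", {
  sites <- tibble::tibble(strength = c(10, 20, 30, 40), score = c(1, 2, 3, 4))
  bs <- bin_and_summarize(sites, n_bins = 2, values = "score")
  expect_equal(bs$mean, c(3.5, 1.5))
  expect_equal(bs$n, c(2L, 2L))

  five <- tibble::tibble(strength = 5:1, score = 5:1)
  b5 <- bin_and_summarize(five, n_bins = 2, values = "score")
  expect_equal(b5$n, c(3L, 2L))  # remainder joins the strongest bin

  const <- tibble::tibble(strength = 1:8, score = rep(2, 8))
  bc <- bin_and_summarize(const, n_bins = 4, values = "score")
  expect_true(all(bc$mean == 2))
  expect_true(all(bc$ci_hi - bc$ci_lo == 0))

  set.seed(2)
  rnd <- tibble::tibble(strength = runif(40), score = rnorm(40))
  br <- bin_and_summarize(rnd, n_bins = 4, values = "score")
  expect_true(all(br$ci_lo <= br$mean & br$mean <= br$ci_hi))
  expect_error(bin_and_summarize(rnd[1:3, ], n_bins = 4, values = "score"),
               "fewer sites")
})

test_that("rank-sum trend test: exact enumeration and approximation agree", {
  exact <- rank_trend_test(c(1, 2), c(3, 4))
  expect_equal(exact$p.value, 2 / 6)
  expect_equal(rank_trend_test(c(5, 5, 5), c(5, 5, 5))$p.value, 1)

  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, mean = runif(1, 0, 1.5))
    p_exact <- rank_trend_test(a, b, exact_limit = 12)$p.value
    p_approx <- rank_trend_test(a, b, exact_limit = 0)$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
    # cross-check the exact branch against the standard implementation
    expect_equal(p_exact, wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Spearman correlation is the Pearson correlation of mid-ranks", {
  expect_equal(spearman_correlation(1:3, c(1, 4, 9)), 1)
  expect_equal(spearman_correlation(1:3, 3:1), -1)
  expect_equal(spearman_correlation(1:4, c(2, 1, 4, 3)), 0.6)
  expect_error(spearman_correlation(1:3, rep(2, 3)), "variance")
  set.seed(4)
  x <- rnorm(25); y <- x + rnorm(25)
  expect_equal(spearman_correlation(x, y),
               cor(x, y, method = "spearman"))
})
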