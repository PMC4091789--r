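test_that("exact signed-rank p-values match the sign-flip enumeration", {
  # 8 concordant negative differences, one-sided "less": 1/256
  r8 <- 1:8 * 1.0
  t1 <- wilcoxon_signed_rank(r8, r8 - (1:8) / 10, alternative = "less")
  expect_equal(t1$p.value, 1 / 256)
  expect_equal(t1$statistic, 0)
  expect_equal(t1$n, 8L)

  # 7 negative, the single positive difference smallest in magnitude: 2/256
  d <- c(0.05, -1, -2, -3, -4, -5, -6, -7)
  t2 <- wilcoxon_signed_rank(d, alternative = "less")
  expect_equal(t2$p.value, 2 / 256)
  expect_equal(t2$statistic, 1)

  # a single negative difference: p = 0.5
  expect_equal(wilcoxon_signed_rank(-3, alternative = "less")$p.value, 0.5)

  # all differences zero: degenerate, flagged
  t0 <- wilcoxon_signed_rank(rep(0, 5), alternative = "less")
  expect_equal(t0$p.value, 1)
  expect_identical(t0$n, 0L)
})

test_that("exact branch equals brute-force 2^n enumeration, with ties", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # rounding induces tied magnitudes
    d <- d[d != 0]
    if (length(d) < 2) next
    for (alt in c("less", "greater", "two.sided")) {
      got <- wilcoxon_signed_rank(d, alternative = alt)$p.value
      expect_equal(got, oracle_signed_rank_p(d, alt))
    }
  }
})

test_that("signed-rank matches wilcox.test on tie-free data and obeys the tail identity", {
  set.seed(26)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9, -0.5)
    got <- wilcoxon_signed_rank(x, y, alternative = "less")
    want <- wilcox.test(y, x, paired = TRUE, alternative = "less",
                        exact = TRUE)
    expect_equal(got$p.value, want$p.value)
    # p(less) + p(greater) = 1 + P(W+ = observed)
    d <- (y - x)[(y - x) != 0]
    p_l <- wilcoxon_signed_rank(d, alternative = "less")$p.value
    p_g <- wilcoxon_signed_rank(d, alternative = "greater")$p.value
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    W_all <- as.vector(signs %*% rank(abs(d)))
    W <- wilcoxon_signed_rank(d)$statistic
    expect_equal(p_l + p_g, 1 + mean(abs(W_all - W) < 1e-9))
  }
  # large-n approximation stays close to the exact enumeration
  set.seed(27)
  d <- rnorm(18, -0.4)
  p_exact <- wilcoxon_signed_rank(d, alternative = "less")$p.value
  p_approx <- wilcoxon_signed_rank(d, alternative = "less",
                                   exact_limit = 5)$p.value
  expect_lt(abs(p_exact - p_approx), 0.01)
})

test_that("adjusted average signal subtracts the genomic background", {
  # constant profile: signal 0 at every center
  p <- make_profile(rep(2.5, 60), spacing = 36)
  p$smoothed <- p$ratio
  peaks <- tibble::tibble(pre_id = "preA", chrom = "chr2L", center = 1000)
  expect_equal(adjusted_average_signal(p, peaks)$signal, 0)

  # window probes at 3.0, genomic average 1.2 -> 1.8
  vals <- rep(1, 60)
  p2 <- make_profile(vals, spacing = 36)
  p2$smoothed <- vals
  in_win <- abs(p2$midpoint - 1000) < 250
  p2$smoothed[in_win] <- 3
  bg <- mean(p2$smoothed)
  got <- adjusted_average_signal(p2, peaks)$signal
  expect_equal(got, 3 - bg)

  # shift invariance: adding a constant leaves the signal unchanged
  p3 <- dplyr::mutate(p2, smoothed = smoothed + 7.7)
  expect_equal(adjusted_average_signal(p3, peaks)$signal, got)

  # probe desert: error naming the PRE
  far <- tibble::tibble(pre_id = "lonely", chrom = "chr2L", center = 1e6)
  expect_error(adjusted_average_signal(p2, far), "lonely")
})

test_that("compare_states pairs signals per PRE and tests active < repressed", {
  # planted 50% reduction at 8 PREs: all differences negative, p = 1/256
  n <- 600
  centers <- seq(2000, by = 2500, length.out = 8)
  base <- rep(1, n)
  prof <- function(amplitudes) {
    v <- base
    mids <- (seq_len(n) - 1) * 36 + 12.5
    for (i in seq_along(centers)) {
      v <- v + amplitudes[i] * pmax(0, 1 - abs(mids - centers[i]) / 500)
    }
    p <- make_profile(v, spacing = 36)
    p$smoothed <- v
    p
  }
  amp <- c(5, 6, 7, 8, 9, 10, 11, 12)
  cmp <- compare_states(prof(amp), prof(amp * 0.5),
                        tibble::tibble(pre_id = paste0("pre", 1:8),
                                       chrom = "chr2L", center = centers))
  expect_true(all(cmp$signals$difference < 0))
  expect_equal(cmp$test$p.value, 1 / 256)

  # identical profiles: all differences zero, degenerate p = 1
  same <- compare_states(prof(amp), prof(amp),
                         tibble::tibble(pre_id = paste0("pre", 1:8),
                                        chrom = "chr2L", center = centers))
  expect_equal(same$test$p.value, 1)
  expect_identical(same$test$n, 0L)

  # reduction at 7 of 8 with the discordant difference smallest: p = 2/256
  amp_a <- amp * 0.5
  amp_a[1] <- amp[1] * 1.001  # tiny positive difference at the weakest PRE
  cmp7 <- compare_states(prof(amp), prof(amp_a),
                         tibble::tibble(pre_id = paste0("pre", 1:8),
                                        chrom = "chr2L", center = centers))
  expect_equal(sum(cmp7$signals$difference < 0), 7)
  expect_equal(cmp7$test$p.value, 2 / 256)

  # a PRE with no probes in one state is excluded with a warning
  missing_peak <- tibble::tibble(pre_id = c(paste0("pre", 1:8), "ghost"),
                                 chrom = "chr2L",
                                 center = c(centers, 5e6))
  expect_warning(
    cmp_miss <- compare_states(prof(amp), prof(amp * 0.5), missing_peak),
    "ghost"
  )
  expect_equal(nrow(cmp_miss$signals), 8)

  g <- glance(cmp)
  expect_equal(g$n_negative, 8)
  expect_equal(tidy(cmp), cmp$signals)
})
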