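test_that("background adjustment uses mean + k*SD with sample SD", {
  p <- make_adjusted(rep(2, 10))
  a <- adjust_profile(p, sd_multiplier = 3)
  expect_equal(background_cutoff(a), 2)
  expect_equal(a$adjusted, rep(0, 10))

  vals <- c(1, 1, 1, 1, 6)
  a2 <- adjust_profile(make_adjusted(vals), sd_multiplier = 3)
  expect_equal(background_cutoff(a2), 2 + 3 * sqrt(5), tolerance = 1e-12)
  expect_equal(a2$adjusted, rep(0, 5))

  # one probe exactly delta above the cutoff
  vals3 <- c(rep(1, 9), 1)
  p3 <- make_adjusted(vals3)
  cutoff <- mean(vals3) + 3 * sd(vals3)
  delta <- 0.25
  p3$smoothed[5] <- NA  # recompute below with the planted value
  vals4 <- vals3
  base <- adjust_profile(make_adjusted(vals4), 3)
  expect_equal(background_cutoff(base), cutoff)
  planted <- vals4
  planted[5] <- cutoff + delta
  # cutoff shifts once the value is planted; verify the definition directly
  a4 <- adjust_profile(make_adjusted(planted), 3)
  expect_equal(a4$adjusted[5],
               max(0, planted[5] - background_cutoff(a4)))
  expect_error(adjust_profile(make_adjusted(c(NA_real_, NA_real_))), "defined")
})

test_that("gap and span rules match the worked 25-mer examples", {
  # positive probes at 0,100,200 only: span [0,225) = 225 bp < 360 -> nothing
  mk <- function(pos_starts, all_starts) {
    tibble::tibble(
      chrom = "chr2L", start = all_starts, length = 25,
      midpoint = all_starts + 12.5,
      smoothed = ifelse(all_starts %in% pos_starts, 5, 0.5),
      adjusted = ifelse(all_starts %in% pos_starts, 4, 0)
    )
  }
  short <- mk(c(0, 100, 200), seq(0, 400, by = 100))
  expect_identical(nrow(call_bound_regions(short)), 0L)

  # positive probes at 800..1200: span [800,1225) = 425 bp -> one region
  ok <- mk(seq(800, 1200, by = 100), seq(0, 1600, by = 100))
  regions <- call_bound_regions(ok)
  expect_identical(nrow(regions), 1L)
  expect_equal(c(regions$start, regions$end), c(800, 1225))
  expect_equal(regions$n_features, 5L)

  # two positive probes 600 bp apart split into two clusters (both too short)
  split2 <- mk(c(0, 600), seq(0, 600, by = 100))
  expect_identical(nrow(call_bound_regions(split2)), 0L)
  # all-zero adjusted profile -> no regions
  none <- mk(numeric(0), seq(0, 400, by = 100))
  expect_identical(nrow(call_bound_regions(none)), 0L)
})

test_that("the 6-feature peak maximizes the window mean, leftmost on ties", {
  probes <- tibble::tibble(
    chrom = "chr2L", start = seq(0, 800, by = 100), length = 25,
    smoothed = c(1, 2, 9, 9, 9, 9, 9, 9, 2)
  )
  pk <- define_peak(probes, k = 6)
  expect_equal(pk$strength, 9)
  expect_equal(c(pk$peak_start, pk$peak_end), c(200, 725))

  six <- probes[1:6, ]
  pk6 <- define_peak(six, k = 6)
  expect_equal(pk6$strength, mean(six$smoothed))
  expect_equal(c(pk6$peak_start, pk6$peak_end), c(0, 525))

  tied <- tibble::tibble(chrom = "chr2L", start = seq(0, 600, by = 100),
                         length = 25, smoothed = rep(4, 7))
  pkt <- define_peak(tied, k = 6)
  expect_equal(pkt$peak_start, 0)  # leftmost of the two tied windows
})

test_that("strength ranking is descending and stable on ties", {
  r <- tibble::tibble(chrom = "chr2L", start = c(0, 500, 1000),
                      end = c(400, 900, 1400), strength = c(2, 5, 3))
  expect_equal(rank_by_strength(r)$strength, c(5, 3, 2))
  tied <- dplyr::mutate(r, strength = 1)
  expect_equal(rank_by_strength(tied)$start, c(0, 500, 1000))
  set.seed(7)
  many <- tibble::tibble(chrom = "chrX", start = seq(0, by = 1000, length.out = 100),
                         end = start + 500, strength = sample(50, 100, TRUE))
  got <- rank_by_strength(many)$strength
  expect_equal(got, sort(many$strength, decreasing = TRUE))
})

test_that("caller equals the brute-force oracle on random profiles", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(10:80, 1)
    spacing <- sample(c(50, 100, 300, 450), 1)
    smoothed <- runif(n, 0.2, 6)
    cutoff <- runif(1, 1, 4)
    p <- make_adjusted(smoothed, adjusted = pmax(smoothed - cutoff, 0),
                       spacing = spacing)
    got <- call_bound_regions(p)
    want <- oracle_call_regions(p, 500, 360, 6)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_equal(as.data.frame(dplyr::select(got, -region_id)),
                   as.data.frame(want[names(dplyr::select(got, -region_id))]))
    }
  }
})

test_that("raising the SD multiplier shrinks what the caller returns", {
  # A higher cutoff can split one long region in two, so the region *count*
  # is not monotone; the above-cutoff probe count and the total called
  # coverage are, and every region called at a stricter cutoff lies inside
  # a region called at the looser one.
  set.seed(5)
  smoothed <- runif(200, 0.5, 3) + rep(c(0, 4, 0, 6, 0), each = 40)
  p <- make_profile(smoothed, spacing = 100)
  p$smoothed <- smoothed
  ks <- c(0.5, 1, 2, 3, 4)
  calls <- lapply(ks, function(k) {
    adj <- adjust_profile(p, k)
    list(n_pos = sum(adj$adjusted > 0, na.rm = TRUE),
         regions = call_bound_regions(adj))
  })
  n_pos <- vapply(calls, function(x) x$n_pos, numeric(1))
  coverage <- vapply(calls, function(x) sum(x$regions$end - x$regions$start),
                     numeric(1))
  expect_true(all(diff(n_pos) <= 0))
  expect_true(all(diff(coverage) <= 0))
  for (i in seq_along(ks)[-1]) {
    strict <- calls[[i]]$regions
    loose <- calls[[i - 1]]$regions
    for (j in seq_len(nrow(strict))) {
      expect_true(any(loose$start <= strict$start[j] &
                        loose$end >= strict$end[j]))
    }
  }
})

test_that("every returned peak mean beats all other k-windows in its region", {
  set.seed(21)
  smoothed <- runif(120, 0.5, 8)
  p <- make_adjusted(smoothed, adjusted = pmax(smoothed - 2, 0), spacing = 90)
  regions <- call_bound_regions(p)
  expect_gt(nrow(regions), 0)
  for (i in seq_len(nrow(regions))) {
    idx <- which(p$start >= regions$start[i] & p$start < regions$end[i] &
                   p$adjusted > 0)
    m <- length(idx)
    k <- min(6, m)
    all_means <- vapply(seq_len(m - k + 1),
                        function(j) mean(p$smoothed[idx[j:(j + k - 1)]]),
                        numeric(1))
    expect_equal(regions$strength[i], max(all_means))
  }
})
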