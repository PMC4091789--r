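# Small in-code fixtures shared across tests.

# A probe track with evenly spaced probes on one chromosome and constant
# intensities unless overridden.
make_track <- function(n = 30, spacing = 36, length = 25, chrom = "chr2L",
                       chip = 2, input = 1) {
  tibble::tibble(
    chrom = chrom,
    start = (seq_len(n) - 1) * spacing,
    length = length,
    chip_1 = rep_len(chip, n),
    chip_2 = rep_len(chip, n),
    input_1 = rep_len(input, n),
    input_2 = rep_len(input, n)
  )
}

# Ratio profile straight from per-probe values (unit input).
make_profile <- function(values, spacing = 36, length = 25, chrom = "chr2L") {
  n <- length(values)
  tibble::tibble(
    chrom = chrom,
    start = (seq_len(n) - 1) * spacing,
    length = length,
    midpoint = (seq_len(n) - 1) * spacing + length / 2,
    ratio = values
  )
}

# Attach smoothed/adjusted columns directly (bypassing the smoother) for
# caller-focused tests.
make_adjusted <- function(smoothed, adjusted = pmax(smoothed - 1, 0),
                          spacing = 100, length = 25, chrom = "chr2L") {
  p <- make_profile(smoothed, spacing = spacing, length = length, chrom = chrom)
  p$smoothed <- smoothed
  p$adjusted <- adjusted
  p
}

intervals <- function(starts, ends, chrom = "chr2L", ...) {
  tibble::tibble(chrom = chrom, start = starts, end = ends, ...)
}

# Brute-force oracle for the smoother: per-probe window scan.
oracle_smooth <- function(profile, window_bp, min_features, trim_fraction) {
  half <- window_bp / 2
  vapply(seq_len(nrow(profile)), function(i) {
    sel <- profile$chrom == profile$chrom[i] &
      abs(profile$midpoint - profile$midpoint[i]) <= half + 1e-9 &
      is.finite(profile$ratio)
    v <- profile$ratio[sel]
    if (length(v) < min_features) return(NA_real_)
    v <- sort(v)
    k <- floor(trim_fraction * length(v))
    mean(v[(k + 1):(length(v) - k)])
  }, numeric(1))
}

# Brute-force oracle for the region caller: enumerate maximal qualifying
# runs of positive probes, apply the span filter, exhaustive peak search.
oracle_call_regions <- function(profile, max_gap_bp, min_region_bp, k) {
  out <- list()
  for (chr in unique(profile$chrom)) {
    p <- profile[profile$chrom == chr, ]
    p <- p[order(p$midpoint), ]
    pos <- which(!is.na(p$adjusted) & p$adjusted > 0)
    if (length(pos) == 0) next
    runs <- split(pos, cumsum(c(0, diff(p$midpoint[pos]) > max_gap_bp)))
    for (idx in runs) {
      span_start <- p$start[idx[1]]
      span_end <- p$start[idx[length(idx)]] + p$length[idx[length(idx)]]
      if (span_end - span_start < min_region_bp) next
      m <- length(idx)
      if (m <= k) {
        best_mean <- mean(p$smoothed[idx])
        win <- c(1, m)
      } else {
        means <- vapply(seq_len(m - k + 1),
                        function(i) mean(p$smoothed[idx[i:(i + k - 1)]]),
                        numeric(1))
        i <- which.max(means)
        best_mean <- means[i]
        win <- c(i, i + k - 1)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chr, start = span_start, end = span_end,
        n_features = m,
        peak_start = p$start[idx[win[1]]],
        peak_end = p$start[idx[win[2]]] + p$length[idx[win[2]]],
        strength = best_mean
      )
    }
  }
  if (length(out) == 0) return(NULL)
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# Exhaustive PWM scan oracle over every offset and strand.
oracle_best_window <- function(seq, pwm) {
  L <- pwm$width
  lo <- log2(pwm$prob / pwm$background)
  score_at <- function(s, off) {
    win <- strsplit(substr(s, off, off + L - 1), "")[[1]]
    sum(vapply(seq_len(L), function(j) {
      b <- match(win[j], c("A", "C", "G", "T"))
      if (is.na(b)) 0 else lo[b, j]
    }, numeric(1)))
  }
  rc <- reverse_complement(seq)
  n <- nchar(seq)
  best <- -Inf; best_strand <- "+"; best_off <- 0L
  for (off in seq_len(n - L + 1)) {
    s <- score_at(seq, off)
    if (s > best + 1e-12) { best <- s; best_strand <- "+"; best_off <- off - 1L }
  }
  for (off in seq_len(n - L + 1)) {
    s <- score_at(rc, off)
    if (s > best + 1e-12) {
      best <- s; best_strand <- "-"
      best_off <- n - L - (off - 1L)  # forward coordinates of the rc window
    }
  }
  list(score = best, strand = best_strand, offset = best_off)
}

# Exact signed-rank p by direct enumeration of all 2^n sign vectors.
oracle_signed_rank_p <- function(d, alternative) {
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  switch(alternative,
         less = mean(W_all <= W + 1e-9),
         greater = mean(W_all >= W - 1e-9),
         two.sided = min(1, 2 * min(mean(W_all <= W + 1e-9),
                                    mean(W_all >= W - 1e-9))))
}
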