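#' Background-adjust a smoothed profile
#'
#' The background cutoff is the mean plus `sd_multiplier` standard
#' deviations (sample SD) of all defined values of the profile, computed
#' genome-wide. The adjusted value of each probe is its value minus the
#' cutoff, with negative results set to zero; undefined probes stay
#' undefined.
#'
#' @param profile tibble from [smooth_profile()] (or any probe tibble with
#'   the value column).
#' @param sd_multiplier SD multiplier in the cutoff (default 3).
#' @param value name of the value column (default `"smoothed"`).
#' @return the input tibble with an `adjusted` column; the cutoff is stored
#'   in the `"background_cutoff"` attribute (see [background_cutoff()]).
#' @export
adjust_profile <- function(profile, sd_multiplier = 3, value = "smoothed") {
  if (!value %in% names(profile)) {
    abort(sprintf("profile has no '%s' column", value))
  }
  if (sd_multiplier < 0) abort("`sd_multiplier` must be >= 0")
  v <- profile[[value]]
  def <- is.finite(v)
  if (sum(def) < 2) abort("need at least 2 defined profile values")
  cutoff <- mean(v[def]) + sd_multiplier * stats::sd(v[def])
  adj <- pmax(v - cutoff, 0)
  adj[!def] <- NA_real_
  profile$adjusted <- adj
  attr(profile, "background_cutoff") <- cutoff
  profile
}

#' @rdname adjust_profile
#' @export
background_cutoff <- function(profile) {
  attr(profile, "background_cutoff")
}

#' Call bound regions from an adjusted profile
#'
#' Bound regions are maximal clusters of array features whose adjusted
#' value exceeds zero and in which the distance from each feature to its
#' nearest above-zero neighbour (midpoint to midpoint) does not exceed
#' `max_gap_bp`. Clusters whose genomic span (first-probe start to
#' last-probe end) falls short of `min_region_bp` — the estimated ChIP
#' resolution — are discarded. Within each region the window of
#' `peak_features` consecutive features with the highest average profile
#' value defines the binding peak, and that average is the region's binding
#' strength.
#'
#' @param profile tibble from [adjust_profile()]; needs `adjusted` plus the
#'   strength value column.
#' @param max_gap_bp maximum neighbour gap in bp (default 500).
#' @param min_region_bp minimum region span in bp (default 360).
#' @param peak_features features per peak window (default 6); regions with
#'   fewer supporting features use the whole region as peak.
#' @param value column the peak average is computed over (default
#'   `"smoothed"`).
#' @return tibble of class `"bound_regions"` with one row per region:
#'   `region_id`, `chrom`, `start`, `end`, `n_features`, `peak_start`,
#'   `peak_end`, `strength`; sorted by genomic position, non-overlapping.
#' @export
call_bound_regions <- function(profile, max_gap_bp = 500, min_region_bp = 360,
                               peak_features = 6, value = "smoothed") {
  need <- c("chrom", "start", "length", "midpoint", "adjusted", value)
  if (!all(need %in% names(profile))) {
    abort(sprintf("`profile` needs columns: %s", paste(need, collapse = ", ")))
  }
  rows <- list()
  for (chr in unique(profile$chrom)) {
    p <- profile[profile$chrom == chr, ]
    p <- p[order(p$midpoint), ]
    pos <- which(!is.na(p$adjusted) & p$adjusted > 0)
    if (length(pos) == 0) next
    gap_break <- c(FALSE, diff(p$midpoint[pos]) > max_gap_bp)
    run_id <- cumsum(gap_break)
    for (r in unique(run_id)) {
      idx <- pos[run_id == r]
      span_start <- p$start[idx[1]]
      span_end <- p$start[idx[length(idx)]] + p$length[idx[length(idx)]]
      if (span_end - span_start < min_region_bp) next
      pk <- peak_window(p$start[idx], p$length[idx], p[[value]][idx],
                        k = peak_features)
      rows[[length(rows) + 1]] <- tibble(
        chrom = chr, start = span_start, end = span_end,
        n_features = length(idx),
        peak_start = pk$peak_start, peak_end = pk$peak_end,
        strength = pk$strength
      )
    }
  }
  out <- if (length(rows) == 0) {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           n_features = integer(), peak_start = numeric(),
           peak_end = numeric(), strength = numeric())
  } else {
    arrange(bind_rows(rows), .data$chrom, .data$start)
  }
  out <- mutate(out,
                region_id = sprintf("%s:%d-%d", .data$chrom,
                                    as.integer(.data$start),
                                    as.integer(.data$end)),
                .before = 1)
  class(out) <- c("bound_regions", class(out))
  out
}

peak_window <- function(starts, lengths, values, k) {
  m <- length(values)
  if (m <= k) {
    return(list(peak_start = starts[1],
                peak_end = starts[m] + lengths[m],
                strength = mean(values)))
  }
  cs <- cumsum(c(0, values))
  means <- (cs[(k + 1):(m + 1)] - cs[1:(m - k + 1)]) / k
  i <- which.max(means)  # leftmost on ties
  list(peak_start = starts[i],
       peak_end = starts[i + k - 1] + lengths[i + k - 1],
       strength = means[i])
}

#' Peak window of a single region
#'
#' Exhaustively evaluates every window of `k` consecutive supporting
#' features and returns the one with the maximal average value (leftmost on
#' ties); for regions with fewer than `k` features the peak is the whole
#' region.
#'
#' @param probes tibble of a region's supporting probes with `start`,
#'   `length` and the value column, in genomic order.
#' @param k features per peak window (default 6).
#' @param value value column name (default `"smoothed"`).
#' @return one-row tibble with `peak_start`, `peak_end`, `strength`.
#' @export
define_peak <- function(probes, k = 6, value = "smoothed") {
  if (nrow(probes) == 0) abort("region has no probes")
  if (!value %in% names(probes)) {
    abort(sprintf("`probes` has no '%s' column", value))
  }
  pk <- peak_window(probes$start, probes$length, probes[[value]], k = k)
  as_tibble(pk)
}

#' Rank bound regions by binding strength
#'
#' Orders regions descending by strength; ties keep genomic order (stable
#' sort), so the ranking is deterministic.
#'
#' @param regions a [call_bound_regions()] tibble (any tibble with
#'   `strength`, `chrom`, `start`).
#' @return the same tibble, reordered, with a `rank` column.
#' @export
rank_by_strength <- function(regions) {
  if (!"strength" %in% names(regions)) abort("`regions` has no 'strength' column")
  out <- arrange(regions, desc(.data$strength), .data$chrom, .data$start)
  out$rank <- seq_len(nrow(out))
  out
}
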