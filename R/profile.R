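#' Compute the per-probe ChIP/Input ratio profile
#'
#' The ratio at each probe is the mean of the ChIP replicate intensities
#' divided by the mean of the Input replicate intensities (ratio of means,
#' not mean of ratios). Probes whose mean Input intensity is zero have an
#' undefined ratio (`NA`), which downstream stages skip rather than impute.
#'
#' @param track probe table from [read_probe_table()] or [simulate_track()].
#' @return tibble with `chrom`, `start`, `length`, `midpoint`
#'   (`start + length/2`, the probe position used by all windowing) and
#'   `ratio`.
#' @export
compute_ratio_profile <- function(track) {
  track <- validate_probe_track(track, source = "track")
  chip_cols <- grep("^chip_", names(track), value = TRUE)
  input_cols <- grep("^input_", names(track), value = TRUE)
  chip_mean <- rowMeans(as.matrix(track[chip_cols]))
  input_mean <- rowMeans(as.matrix(track[input_cols]))
  ratio <- chip_mean / input_mean
  ratio[input_mean == 0] <- NA_real_
  tibble(
    chrom = track$chrom,
    start = track$start,
    length = track$length,
    midpoint = track$start + track$length / 2,
    ratio = ratio
  )
}

#' Smooth a ratio profile with a sliding trimmed mean
#'
#' For each probe, all probes on the same chromosome whose midpoints lie
#' within `window_bp / 2` of its midpoint (window closed on both ends) are
#' collected; if fewer than `min_features` of them carry a defined ratio the
#' smoothed value is undefined (`NA`), otherwise it is the trimmed mean of
#' their ratios (the `floor(trim_fraction * n)` smallest and largest values
#' dropped before averaging).
#'
#' @param profile tibble from [compute_ratio_profile()].
#' @param window_bp window width in bp (default 675).
#' @param min_features minimum probes per window (default 10).
#' @param trim_fraction fraction trimmed per tail, in `[0, 0.5)` (default 0.1).
#' @return the input tibble with a `smoothed` column added.
#' @export
smooth_profile <- function(profile, window_bp = 675, min_features = 10,
                           trim_fraction = 0.1) {
  if (window_bp <= 0) abort("`window_bp` must be > 0")
  if (min_features < 1) abort("`min_features` must be >= 1")
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("`trim_fraction` must lie in [0, 0.5)")
  }
  need <- c("chrom", "midpoint", "ratio")
  if (!all(need %in% names(profile))) {
    abort("`profile` needs columns chrom, midpoint, ratio; see compute_ratio_profile()")
  }
  half <- window_bp / 2
  tol <- 1e-9 * max(1, window_bp)
  smoothed <- rep(NA_real_, nrow(profile))
  for (chr in unique(profile$chrom)) {
    sel <- which(profile$chrom == chr)
    mids <- profile$midpoint[sel]
    if (is.unsorted(mids)) {
      ord <- order(mids)
      sel <- sel[ord]
      mids <- mids[ord]
    }
    ok <- is.finite(profile$ratio[sel])
    dm <- mids[ok]
    dv <- profile$ratio[sel][ok]
    if (length(dm) == 0) next
    lo <- findInterval(mids - half - tol, dm) + 1L
    hi <- findInterval(mids + half + tol, dm)
    n_in <- hi - lo + 1L
    for (i in seq_along(sel)) {
      if (n_in[i] < min_features) next
      smoothed[sel[i]] <- mean(dv[lo[i]:hi[i]], trim = trim_fraction)
    }
  }
  profile$smoothed <- smoothed
  attr(profile, "smooth_params") <- list(
    window_bp = window_bp, min_features = min_features,
    trim_fraction = trim_fraction
  )
  profile
}
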