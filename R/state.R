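#' Adjusted average binding signal around peaks
#'
#' For each PRE the mean of all defined smoothed ChIP/Input values within a
#' window (default 500 bp) centered on its PHO peak is computed, and the
#' genomic average of the same profile (the background signal, mean of all
#' defined smoothed values) is subtracted. Because the background cancels,
#' adding a constant to the whole profile leaves the signal unchanged.
#'
#' @param profile tibble from [smooth_profile()].
#' @param peaks tibble with `chrom` and either `center` or
#'   `peak_start`/`peak_end` (center = floor of the midpoint); an optional
#'   `pre_id`/`region_id`/`name` column names the PREs.
#' @param window_bp window width in bp (default 500).
#' @return tibble with `pre_id`, `chrom`, `center`, `signal`. A window
#'   containing no defined probe is an error naming the PRE.
#' @export
adjusted_average_signal <- function(profile, peaks, window_bp = 500) {
  if (window_bp <= 0) abort("`window_bp` must be > 0")
  if (!all(c("chrom", "midpoint", "smoothed") %in% names(profile))) {
    abort("`profile` needs chrom, midpoint, smoothed; see smooth_profile()")
  }
  center <- if ("center" %in% names(peaks)) peaks$center else
    floor((peaks$peak_start + peaks$peak_end) / 2)
  ids <- if ("pre_id" %in% names(peaks)) peaks$pre_id else
    if ("region_id" %in% names(peaks)) peaks$region_id else
      if ("name" %in% names(peaks)) peaks$name else
        sprintf("pre_%02d", seq_len(nrow(peaks)))
  def <- is.finite(profile$smoothed)
  if (!any(def)) abort("profile has no defined smoothed values")
  background <- mean(profile$smoothed[def])
  half <- window_bp / 2
  signal <- vapply(seq_len(nrow(peaks)), function(i) {
    sel <- profile$chrom == peaks$chrom[i] &
      profile$midpoint >= center[i] - half &
      profile$midpoint < center[i] + half &
      def
    if (!any(sel)) {
      abort(sprintf("no defined probes within %d bp of PRE '%s' (%s:%d)",
                    as.integer(window_bp), ids[i], peaks$chrom[i],
                    as.integer(center[i])))
    }
    mean(profile$smoothed[sel]) - background
  }, numeric(1))
  tibble(pre_id = ids, chrom = peaks$chrom, center = center, signal = signal)
}

#' Compare per-PRE binding between two chromatin states
#'
#' Computes the adjusted average binding signal at the same PRE peaks in
#' two smoothed profiles — one from cells where the PREs are repressed, one
#' where they are active — and tests the paired difference with the exact
#' Wilcoxon signed-rank test ([wilcoxon_signed_rank()]). The default
#' one-sided alternative `"less"` asks whether binding in the active state
#' is lower.
#'
#' PREs whose window contains no defined probe in one of the states are
#' excluded with a warning rather than failing the whole comparison.
#'
#' @param profile_repressed,profile_active smoothed profiles
#'   ([smooth_profile()]) for the two states.
#' @param pre_peaks PRE peak tibble (see [adjusted_average_signal()]).
#' @param window_bp signal window width in bp (default 500).
#' @param alternative passed to [wilcoxon_signed_rank()] (default `"less"`).
#' @return object of class `"state_comparison"`: a list with `signals`
#'   (tibble `pre_id`, `signal_repressed`, `signal_active`, `difference`)
#'   and `test` (the `"signed_rank_test"`). `tidy()` returns the signals,
#'   `glance()` the test row.
#' @export
compare_states <- function(profile_repressed, profile_active, pre_peaks,
                           window_bp = 500, alternative = "less") {
  sig_one <- function(profile, i) {
    tryCatch(
      adjusted_average_signal(profile, pre_peaks[i, ], window_bp)$signal,
      error = function(e) NA_real_
    )
  }
  n <- nrow(pre_peaks)
  sig_r <- vapply(seq_len(n), function(i) sig_one(profile_repressed, i),
                  numeric(1))
  sig_a <- vapply(seq_len(n), function(i) sig_one(profile_active, i),
                  numeric(1))
  ids <- adjusted_ids(pre_peaks)
  keep <- is.finite(sig_r) & is.finite(sig_a)
  if (!all(keep)) {
    warn(sprintf("excluding PRE(s) with no defined signal in one state: %s",
                 paste(ids[!keep], collapse = ", ")))
  }
  if (!any(keep)) abort("no PRE has a defined signal in both states")
  signals <- tibble(
    pre_id = ids[keep],
    signal_repressed = sig_r[keep],
    signal_active = sig_a[keep],
    difference = sig_a[keep] - sig_r[keep]
  )
  test <- wilcoxon_signed_rank(signals$signal_repressed,
                               signals$signal_active,
                               alternative = alternative)
  structure(list(signals = signals, test = test), class = "state_comparison")
}

adjusted_ids <- function(peaks) {
  if ("pre_id" %in% names(peaks)) peaks$pre_id else
    if ("region_id" %in% names(peaks)) peaks$region_id else
      if ("name" %in% names(peaks)) peaks$name else
        sprintf("pre_%02d", seq_len(nrow(peaks)))
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("Two-state binding comparison over %d PREs\n", nrow(x$signals)))
  cat(sprintf("  %d of %d differences negative (active < repressed)\n",
              sum(x$signals$difference < 0), nrow(x$signals)))
  print(x$test)
  invisible(x)
}

#' @method tidy state_comparison
#' @export
tidy.state_comparison <- function(x, ...) x$signals

#' @method glance state_comparison
#' @export
glance.state_comparison <- function(x, ...) {
  bind_cols(
    tibble(n_pres = nrow(x$signals),
           n_negative = sum(x$signals$difference < 0)),
    tidy(x$test)
  )
}
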