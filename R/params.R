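#' Pipeline parameter record
#'
#' Collects every numeric constant used by the profile, region-calling,
#' motif and state-comparison stages in one validated list, so a whole run
#' is reproducible from a single record (and from the YAML config consumed
#' by [run_pipeline()]).
#'
#' Defaults are the values used throughout the analysis this package
#' implements:
#'
#' * `smooth_window_bp = 675`, `min_features_per_window = 10`: the sliding
#'   trimmed-mean smoother; windows holding fewer than 10 probes are
#'   undefined.
#' * `sd_multiplier = 3`: the background cutoff is mean + 3·SD of the
#'   smoothed ratio profile.
#' * `max_gap_bp = 500`, `min_region_bp = 360`: clustering of
#'   above-background probes into bound regions (360 bp is the estimated
#'   ChIP resolution).
#' * `peak_features = 6`: a binding peak is the 6 consecutive features with
#'   the highest average ratio; its mean is the binding strength.
#' * `motif_window_bp = 14`, `motif_flank_bp = 200`, `core_motif = "GCCAT"`:
#'   PWM scan width, half-width of the sequence window around each peak,
#'   and the conserved core pentamer.
#' * `state_window_bp = 500`: window centered on the PHO peak over which the
#'   adjusted average binding signal is computed.
#' * `tss_halfwidth_fly_bp = 300` / `tss_halfwidth_human_bp = 700`: TSS
#'   window half-widths (600 bp / 1400 bp windows).
#' * `rpkm_threshold = 300`, `rma_threshold = 6`: expression-activity
#'   thresholds (RPKM at or above 300; RMA strictly above 6).
#' * `trim_fraction = 0.1`, `pwm_pseudocount = 0.5`: conventional defaults,
#'   exposed because they are not forced by the procedure itself.
#'
#' @param smooth_window_bp width in bp of the sliding smoothing window.
#' @param min_features_per_window minimum probes per window for a defined
#'   smoothed value.
#' @param trim_fraction fraction trimmed from each tail of the window before
#'   averaging; must lie in `[0, 0.5)`.
#' @param sd_multiplier multiplier of the profile SD in the background cutoff.
#' @param max_gap_bp maximum midpoint-to-midpoint distance between
#'   neighbouring above-background probes within one region.
#' @param min_region_bp minimum genomic span of a bound region.
#' @param peak_features number of consecutive features defining a peak.
#' @param motif_window_bp PWM scan window width in bp.
#' @param motif_flank_bp half-width of the sequence window around a peak
#'   center used as motif-search input.
#' @param state_window_bp width of the window around a PHO peak for the
#'   adjusted average binding signal.
#' @param tss_halfwidth_fly_bp,tss_halfwidth_human_bp TSS window half-widths.
#' @param rpkm_threshold,rma_threshold expression-activity thresholds.
#' @param core_motif conserved core pentamer counted on both strands.
#' @param pwm_pseudocount pseudocount added per base when estimating a PWM.
#'
#' @return A list of class `"pipeline_params"`.
#' @examples
#' p <- pipeline_params()
#' p$smooth_window_bp
#' @export
pipeline_params <- function(smooth_window_bp = 675,
                            min_features_per_window = 10,
                            trim_fraction = 0.1,
                            sd_multiplier = 3,
                            max_gap_bp = 500,
                            min_region_bp = 360,
                            peak_features = 6,
                            motif_window_bp = 14,
                            motif_flank_bp = 200,
                            state_window_bp = 500,
                            tss_halfwidth_fly_bp = 300,
                            tss_halfwidth_human_bp = 700,
                            rpkm_threshold = 300,
                            rma_threshold = 6,
                            core_motif = "GCCAT",
                            pwm_pseudocount = 0.5) {
  p <- list(
    smooth_window_bp = smooth_window_bp,
    min_features_per_window = min_features_per_window,
    trim_fraction = trim_fraction,
    sd_multiplier = sd_multiplier,
    max_gap_bp = max_gap_bp,
    min_region_bp = min_region_bp,
    peak_features = peak_features,
    motif_window_bp = motif_window_bp,
    motif_flank_bp = motif_flank_bp,
    state_window_bp = state_window_bp,
    tss_halfwidth_fly_bp = tss_halfwidth_fly_bp,
    tss_halfwidth_human_bp = tss_halfwidth_human_bp,
    rpkm_threshold = rpkm_threshold,
    rma_threshold = rma_threshold,
    core_motif = core_motif,
    pwm_pseudocount = pwm_pseudocount
  )
  lengths_pos <- c(
    "smooth_window_bp", "min_features_per_window", "max_gap_bp",
    "min_region_bp", "peak_features", "motif_window_bp", "motif_flank_bp",
    "state_window_bp", "tss_halfwidth_fly_bp", "tss_halfwidth_human_bp"
  )
  for (nm in lengths_pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number", nm))
    }
  }
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("`trim_fraction` must lie in [0, 0.5)")
  }
  if (!is.numeric(sd_multiplier) || sd_multiplier < 0) {
    abort("`sd_multiplier` must be >= 0")
  }
  if (!is.character(core_motif) || nchar(core_motif) == 0L ||
      grepl("[^ACGT]", core_motif)) {
    abort("`core_motif` must be a non-empty ACGT string")
  }
  if (!is.numeric(pwm_pseudocount) || pwm_pseudocount < 0) {
    abort("`pwm_pseudocount` must be >= 0")
  }
  structure(p, class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
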