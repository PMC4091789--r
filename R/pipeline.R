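#' Run the full analysis pipeline from a YAML config
#'
#' Executes the stages in dependency order — simulate (or read a probe
#' table), ratio profile, smoothing, background adjustment, region calling,
#' and optionally overlap curves, motif scoring of called peaks, and the
#' two-state comparison — writing each stage's output under `out_dir` and
#' returning a manifest. Given the same config and seed the deterministic
#' outputs are bit-identical across reruns.
#'
#' Config keys (YAML or an equivalent list):
#' \preformatted{
#' seed: 1
#' out_dir: out
#' params: {smooth_window_bp: 675, ...}      # optional overrides
#' simulate: {genome_length: 200000, n_pre_sites: 8, n_tss_sites: 8}
#' # or, instead of simulate:
#' input: {probe_table: probes.tsv, genome: genome.fa}
#' references: {pres: pres.bed, tss: tss.bed} # optional overlap stage
#' motif: {enabled: true, pwm: pwm.tsv}       # optional; default PWM if absent
#' compare: {reduction: 0.5}                  # optional two-state stage
#'                                            # (simulated inputs only)
#' }
#'
#' All referenced input files are checked before any stage runs; a missing
#' file fails the whole run up front.
#'
#' @param config path to a YAML file or a config list.
#' @param out_dir output directory, overriding the config entry.
#' @param quiet suppress progress messages (default `FALSE`).
#' @return the run manifest (list with resolved parameters, seed, input
#'   digests, per-stage output paths and package version), invisibly;
#'   also written to `out_dir/manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a list")
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...))
  }
  seed <- config$seed %||% abort("config needs a `seed`")
  out_dir <- out_dir %||% config$out_dir %||% abort("config needs an `out_dir`")
  params <- do.call(pipeline_params, config$params %||% list())

  # pre-flight: every referenced input must exist before compute starts
  inputs <- character()
  if (is.null(config$simulate)) {
    if (is.null(config$input$probe_table)) {
      abort("config needs either a `simulate` block or `input$probe_table`")
    }
    inputs <- c(inputs, probe_table = config$input$probe_table)
    if (!is.null(config$input$genome)) inputs <- c(inputs, genome = config$input$genome)
    if (!is.null(config$compare)) {
      abort("the two-state compare stage requires a `simulate` block")
    }
  }
  for (ref in names(config$references %||% list())) {
    inputs <- c(inputs, stats::setNames(config$references[[ref]], ref))
  }
  if (!is.null(config$motif$pwm)) inputs <- c(inputs, pwm = config$motif$pwm)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    abort(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  }
  if (isTRUE(config$motif$enabled %||% !is.null(config$motif)) &&
      is.null(config$simulate) && is.null(config$input$genome)) {
    abort("the motif stage needs a genome (config$input$genome)")
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  pwm <- if (!is.null(config$motif$pwm)) read_pwm(config$motif$pwm) else
    example_motif_pwm(params$pwm_pseudocount)

  genome <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    say("simulate: generating genome and planted sites")
    sim_args <- config$simulate
    sim_args$seed <- seed
    cfg <- do.call(simulation_config, sim_args)
    exp <- simulate_chip_experiment(cfg, pwm = pwm)
    genome <- exp$genome; truth <- exp$truth; track <- exp$track
    paths$genome <- file.path(out_dir, "genome.fa")
    write_genome_fasta(genome, paths$genome)
    paths$truth <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth, paths$truth)
    paths$probe_table <- file.path(out_dir, "probes.tsv")
    readr::write_tsv(track, paths$probe_table)
  } else {
    say("input: reading probe table")
    track <- read_probe_table(config$input$probe_table)
    if (!is.null(config$input$genome)) genome <- config$input$genome
  }

  say("profile: ratio + trimmed-mean smoothing")
  profile <- compute_ratio_profile(track)
  profile <- smooth_profile(profile, params$smooth_window_bp,
                            params$min_features_per_window,
                            params$trim_fraction)
  paths$smoothed <- file.path(out_dir, "smoothed.bedGraph")
  write_track(profile, paths$smoothed, "bedGraph")

  say("call: background adjustment + bound regions")
  profile <- adjust_profile(profile, params$sd_multiplier)
  regions <- call_bound_regions(profile, params$max_gap_bp,
                                params$min_region_bp, params$peak_features)
  paths$regions <- file.path(out_dir, "bound_regions.bed")
  write_regions_bed(regions, paths$regions, "span")
  paths$peaks <- file.path(out_dir, "binding_peaks.bed")
  write_regions_bed(regions, paths$peaks, "peak")

  for (ref in names(config$references %||% list())) {
    say("overlap: curve against '%s'", ref)
    reference <- read_intervals(config$references[[ref]])
    curve <- overlap_curve(regions, reference, reference_label = ref)
    paths[[paste0("overlap_", ref)]] <-
      file.path(out_dir, sprintf("overlap_%s.tsv", ref))
    readr::write_tsv(as_tibble(curve), paths[[paste0("overlap_", ref)]])
  }

  if (isTRUE(config$motif$enabled %||% !is.null(config$motif)) &&
      !is.null(genome) && nrow(regions) > 0) {
    say("motif: scoring %d called sites", nrow(regions))
    seqs <- extract_site_sequences(genome, regions, params$motif_flank_bp)
    scores <- score_best_window(seqs, pwm)
    scores$core_count <- count_core(seqs, params$core_motif)
    scores$strength <- regions$strength
    paths$site_scores <- file.path(out_dir, "site_scores.tsv")
    readr::write_tsv(scores, paths$site_scores)
  }

  if (!is.null(config$compare) && !is.null(truth) && nrow(truth) > 0) {
    say("compare: two-state simulation and signed-rank test")
    red <- config$compare$reduction %||% 0.5
    factors <- rep(red, length.out = nrow(truth))
    states <- simulate_two_states(genome, truth, factors,
                                  do.call(simulation_config,
                                          c(config$simulate, list(seed = seed))))
    smooth_state <- function(tr) {
      smooth_profile(compute_ratio_profile(tr), params$smooth_window_bp,
                     params$min_features_per_window, params$trim_fraction)
    }
    peaks <- tibble(pre_id = truth$site_id, chrom = truth$chrom,
                    center = truth$center)
    cmp <- compare_states(smooth_state(states$repressed),
                          smooth_state(states$active),
                          peaks, params$state_window_bp)
    paths$state_signals <- file.path(out_dir, "state_signals.tsv")
    readr::write_tsv(tidy(cmp), paths$state_signals)
    paths$state_test <- file.path(out_dir, "state_test.tsv")
    readr::write_tsv(glance(cmp), paths$state_test)
  }

  manifest <- list(
    tool = "tilechip",
    version = as.character(packageVersion("tilechip")),
    seed = seed,
    params = unclass(params),
    inputs = as.list(if (length(inputs) > 0) tools::md5sum(inputs) else character()),
    outputs = map(paths, ~ unname(tools::md5sum(.x))),
    output_paths = paths
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("done: %d output file(s) under %s", length(paths), out_dir)
  invisible(manifest)
}
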