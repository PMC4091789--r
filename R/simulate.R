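#' Simulation configuration
#'
#' Bundles the parameters of the synthetic ChIP-chip generator. The
#' defaults emulate the structure of the array data the pipeline targets:
#' ~25-mer probes every 36 bp (the Affymetrix Drosophila tiling design
#' scale), two ChIP plus two Input replicates, localized enrichment over
#' planted sites spread by a fragment-size kernel (half-width 500 bp, the
#' estimated ChIP resolution), multiplicative lognormal noise, and two
#' classes of planted sites: motif-driven "TSS-proximal" sites whose
#' amplitude tracks the quality of their embedded motif instance, and
#' "PRE" sites carrying 1-3 GCCAT cores with amplitude drawn independently
#' of sequence.
#'
#' @param genome_length genome length in bp.
#' @param gc GC fraction of the background sequence (default 0.41, the
#'   Drosophila genome-wide value).
#' @param probe_spacing probe start-to-start spacing in bp (default 36).
#' @param probe_length probe length in bp (default 25).
#' @param n_chip,n_input replicate counts per channel (default 2 each).
#' @param kernel `"triangular"` (default) or `"gaussian"` enrichment kernel.
#' @param kernel_width kernel half-width `w` in bp (default 500);
#'   `K(0) = 1`, `K(x) = 0` for `x >= 1` with `x = distance / w`.
#' @param noise_sigma lognormal noise sigma (default 0.1).
#' @param baseline_meanlog meanlog of the Input baseline (default log(500)).
#' @param n_pre_sites,n_tss_sites planted sites per class (default 10 each).
#' @param pre_amplitude list `(meanlog, sdlog)` of the lognormal PRE
#'   amplitude distribution (default `meanlog = log(8)`, `sdlog = 0.6`).
#' @param tss_amplitude list `(a0, beta, sdlog)`: TSS amplitude is
#'   `a0 * 2^(beta * (score - E[score])) * lognormal(0, sdlog)` (defaults
#'   `a0 = 8`, `beta = 0.3`, `sdlog = 0.1`).
#' @param min_separation minimum distance between planted centers (default
#'   `2 * kernel_width + 400`, keeping sites resolvable by the caller).
#' @param seed mandatory random seed; all generator randomness flows
#'   through it.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(genome_length = 2e6,
                              gc = 0.41,
                              probe_spacing = 36,
                              probe_length = 25,
                              n_chip = 2,
                              n_input = 2,
                              kernel = c("triangular", "gaussian"),
                              kernel_width = 500,
                              noise_sigma = 0.1,
                              baseline_meanlog = log(500),
                              n_pre_sites = 10,
                              n_tss_sites = 10,
                              pre_amplitude = list(meanlog = log(8), sdlog = 0.6),
                              tss_amplitude = list(a0 = 8, beta = 0.3, sdlog = 0.1),
                              min_separation = NULL,
                              seed) {
  kernel <- match.arg(kernel)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("`seed` is mandatory (reproducibility contract)")
  }
  for (nm in c("genome_length", "probe_spacing", "probe_length", "n_chip",
               "n_input", "kernel_width")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) abort(sprintf("`%s` must be > 0", nm))
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  if (gc < 0 || gc > 1) abort("`gc` must lie in [0, 1]")
  min_separation <- min_separation %||% (2 * kernel_width + 400)
  structure(
    list(genome_length = genome_length, gc = gc,
         probe_spacing = probe_spacing, probe_length = probe_length,
         n_chip = n_chip, n_input = n_input, kernel = kernel,
         kernel_width = kernel_width, noise_sigma = noise_sigma,
         baseline_meanlog = baseline_meanlog,
         n_pre_sites = n_pre_sites, n_tss_sites = n_tss_sites,
         pre_amplitude = pre_amplitude, tss_amplitude = tss_amplitude,
         min_separation = min_separation, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. at the stated GC fraction; the same seed always
#' yields the same sequence.
#'
#' @param length_bp genome length.
#' @param gc GC fraction.
#' @param seed random seed.
#' @param chrom_name chromosome name (default `"chrS"`).
#' @return a named character vector of length 1 (the chromosome sequence).
#' @export
simulate_genome <- function(length_bp, gc = 0.41, seed, chrom_name = "chrS") {
  if (length_bp <= 0) abort("`length_bp` must be > 0")
  seq <- withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length_bp, replace = TRUE, prob = p), collapse = "")
  })
  stats::setNames(seq, chrom_name)
}

sample_pwm_instance <- function(pwm) {
  bases <- vapply(seq_len(pwm$width), function(j) {
    sample(DNA_BASES, 1, prob = pwm$prob[, j])
  }, character(1))
  paste(bases, collapse = "")
}

pwm_forward_score <- function(seq, pwm) {
  code <- encode_dna(seq)
  sum(pwm_log_odds(pwm)[cbind(code, seq_along(code))])
}

pwm_expected_score <- function(pwm) {
  sum(pwm$prob * pwm_log_odds(pwm))
}

replace_substring <- function(seq, at, piece) {
  # at is 0-based start of the replacement; substr() with an explicit end —
  # substring()'s default `last` silently truncates strings beyond 1e6 chars
  paste0(substr(seq, 1, at), piece,
         substr(seq, at + nchar(piece) + 1, nchar(seq)))
}

#' Plant binding sites into a genome
#'
#' Embeds two classes of sites at rejection-sampled, non-overlapping
#' positions: TSS-class sites carry a sequence sampled from the PWM, and
#' their amplitude is log-linearly coupled to that instance's score
#' (`a = a0 * 2^(beta * (score - E[score])) * lognormal(0, sdlog)`);
#' PRE-class sites carry 1-3 perfect GCCAT cores at random offsets within
#' 100 bp of the center, and their amplitude is drawn independently of the
#' sequence. This encodes the empirical contrast the pipeline must be able
#' to recover: motif quality predicts strength at TSS-proximal sites but
#' not at PREs.
#'
#' @param genome named character vector (single chromosome) from
#'   [simulate_genome()].
#' @param pwm the motif model, e.g. [example_motif_pwm()].
#' @param config a [simulation_config()].
#' @param seed random seed (default `config$seed + 1`).
#' @return list with `genome` (edited sequence) and `truth`, a tibble with
#'   `site_id`, `class` (`"PRE"`/`"TSS"`), `chrom`, `center`, `amplitude`,
#'   `n_cores_planted`, `pwm_score` and `core_count` (both measured on the
#'   +/-200 bp window after editing).
#' @export
plant_sites <- function(genome, pwm, config, seed = config$seed + 1L) {
  n_pre <- config$n_pre_sites
  n_tss <- config$n_tss_sites
  n_sites <- n_pre + n_tss
  flank <- 200
  margin <- config$kernel_width + flank + pwm$width
  len <- nchar(genome)
  if (n_sites > 0 &&
      (len - 2 * margin) < n_sites * config$min_separation) {
    abort("genome too small for the requested number of planted sites")
  }
  chrom <- names(genome)
  seq <- unname(genome)
  if (n_sites == 0) {
    truth <- tibble(site_id = character(), class = character(),
                    chrom = character(), center = numeric(),
                    amplitude = numeric(), n_cores_planted = integer(),
                    pwm_score = numeric(), core_count = integer())
    return(list(genome = genome, truth = truth))
  }
  out <- withr::with_seed(seed, {
    centers <- numeric(0)
    for (tries in seq_len(100000)) {
      cand <- floor(runif(1, margin, len - margin))
      if (all(abs(cand - centers) >= config$min_separation)) {
        centers <- c(centers, cand)
      }
      if (length(centers) == n_sites) break
    }
    if (length(centers) < n_sites) {
      abort("could not place non-overlapping sites; enlarge the genome")
    }
    classes <- rep(c("PRE", "TSS"), c(n_pre, n_tss))
    amp <- numeric(n_sites)
    n_cores <- integer(n_sites)
    e_score <- pwm_expected_score(pwm)
    for (i in seq_len(n_sites)) {
      if (classes[i] == "PRE") {
        k <- sample(1:3, 1)
        n_cores[i] <- k
        offs <- sample(seq(-100, 95, by = 6), k)  # non-overlapping 5-mers
        for (o in offs) {
          seq <- replace_substring(seq, centers[i] + o, "GCCAT")
        }
        amp[i] <- rlnorm(1, config$pre_amplitude$meanlog,
                         config$pre_amplitude$sdlog)
      } else {
        inst <- sample_pwm_instance(pwm)
        at <- centers[i] - floor(pwm$width / 2)
        seq <- replace_substring(seq, at, inst)
        s <- pwm_forward_score(inst, pwm)
        ta <- config$tss_amplitude
        amp[i] <- ta$a0 * 2^(ta$beta * (s - e_score)) *
          rlnorm(1, 0, ta$sdlog)
      }
    }
    list(seq = seq, centers = centers, classes = classes, amp = amp,
         n_cores = n_cores)
  })
  genome <- stats::setNames(out$seq, chrom)
  windows <- tibble(chrom = chrom,
                    start = out$centers - flank,
                    end = out$centers + flank,
                    site_id = sprintf("%s_%03d", tolower(out$classes),
                                      seq_len(n_sites)))
  site_seqs <- toupper(substring(genome, windows$start + 1, windows$end))
  truth <- tibble(
    site_id = windows$site_id,
    class = out$classes,
    chrom = chrom,
    center = out$centers,
    amplitude = out$amp,
    n_cores_planted = out$n_cores,
    pwm_score = score_best_window(site_seqs, pwm)$score,
    core_count = count_core(site_seqs)
  )
  truth <- arrange(truth, .data$center)
  list(genome = genome, truth = truth)
}

kernel_weight <- function(dist, width, kernel = "triangular") {
  x <- abs(dist) / width
  if (kernel == "triangular") pmax(0, 1 - x) else exp(-x^2 / 2) * (x < 3)
}

#' Simulate a replicate probe intensity track
#'
#' Probes are laid at fixed spacing. Each Input replicate value is
#' `lognormal(baseline_meanlog, sigma)`; each ChIP replicate value is an
#' independent baseline draw times the enrichment
#' `1 + sum_s a_s * K(|midpoint - center_s| / w)` times multiplicative
#' `lognormal(0, sigma)` noise, with `K` the fragment-size kernel. At
#' `sigma = 0` a probe at a site center has ratio exactly `1 + a`.
#'
#' @param genome named character vector (used for its length and name).
#' @param truth truth tibble from [plant_sites()] (may be empty).
#' @param config a [simulation_config()].
#' @param seed random seed (default `config$seed + 2`).
#' @param amplitude_multiplier optional per-site multiplier in `(0, 1]`
#'   (state simulations).
#' @return probe table tibble (`chrom`, `start`, `length`, `chip_*`,
#'   `input_*`) accepted by [compute_ratio_profile()].
#' @export
simulate_track <- function(genome, truth, config, seed = config$seed + 2L,
                           amplitude_multiplier = NULL) {
  len <- nchar(genome)
  chrom <- names(genome)
  plen <- config$probe_length
  n_probes <- floor((len - plen) / config$probe_spacing) + 1
  starts <- (seq_len(n_probes) - 1) * config$probe_spacing
  mids <- starts + plen / 2
  amp <- truth$amplitude
  if (!is.null(amplitude_multiplier)) {
    if (length(amplitude_multiplier) != nrow(truth)) {
      abort("need one amplitude multiplier per planted site")
    }
    if (any(amplitude_multiplier <= 0 | amplitude_multiplier > 1)) {
      abort("amplitude multipliers must lie in (0, 1]")
    }
    amp <- amp * amplitude_multiplier
  }
  enrich <- rep(1, n_probes)
  w <- config$kernel_width
  reach <- if (config$kernel == "triangular") w else 3 * w
  for (i in seq_len(nrow(truth))) {
    affected <- which(abs(mids - truth$center[i]) < reach)
    if (length(affected) > 0) {
      enrich[affected] <- enrich[affected] +
        amp[i] * kernel_weight(mids[affected] - truth$center[i], w,
                               config$kernel)
    }
  }
  sigma <- config$noise_sigma
  mu0 <- config$baseline_meanlog
  n_pairs <- max(config$n_chip, config$n_input)
  tbl <- withr::with_seed(seed, {
    out <- tibble(chrom = chrom, start = starts, length = plen)
    # "matching chromatin inputs": each ChIP replicate multiplies its
    # matching input baseline, so at sigma = 0 the ratio is exactly the
    # enrichment
    for (r in seq_len(n_pairs)) {
      base <- rlnorm(n_probes, mu0, sigma)
      if (r <= config$n_input) out[[paste0("input_", r)]] <- base
      if (r <= config$n_chip) {
        out[[paste0("chip_", r)]] <- base * enrich * rlnorm(n_probes, 0, sigma)
      }
    }
    cols <- c("chrom", "start", "length",
              paste0("chip_", seq_len(config$n_chip)),
              paste0("input_", seq_len(config$n_input)))
    out[cols]
  })
  tbl
}

#' Simulate matched tracks for two chromatin states
#'
#' State R ("repressed") uses the planted amplitudes as they are; state A
#' ("active") multiplies each planted site's amplitude by its reduction
#' factor in `(0, 1]`. Everything else is identical in distribution, with
#' independent noise per state.
#'
#' @param genome,truth,config as in [simulate_track()].
#' @param reduction_factors numeric vector, one factor per planted site.
#' @param seed base seed (default `config$seed + 10`); state R uses `seed`,
#'   state A `seed + 1`.
#' @return list with probe tables `repressed` and `active`.
#' @export
simulate_two_states <- function(genome, truth, reduction_factors, config,
                                seed = config$seed + 10L) {
  if (length(reduction_factors) != nrow(truth)) {
    abort("need one reduction factor per planted site")
  }
  if (any(reduction_factors <= 0 | reduction_factors > 1)) {
    abort("reduction factors must lie in (0, 1]")
  }
  list(
    repressed = simulate_track(genome, truth, config, seed = seed),
    active = simulate_track(genome, truth, config, seed = seed + 1L,
                            amplitude_multiplier = reduction_factors)
  )
}

#' One-call synthetic ChIP-chip experiment
#'
#' Convenience wrapper: genome, planted sites, and one replicate track,
#' all deterministically derived from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param pwm motif model (default [example_motif_pwm()]).
#' @return list with `genome`, `truth`, `track`, `pwm`, `config`.
#' @export
simulate_chip_experiment <- function(config, pwm = example_motif_pwm()) {
  genome <- simulate_genome(config$genome_length, config$gc,
                            seed = config$seed)
  planted <- plant_sites(genome, pwm, config)
  track <- simulate_track(planted$genome, planted$truth, config)
  list(genome = planted$genome, truth = planted$truth, track = track,
       pwm = pwm, config = config)
}

#' Synthetic extended-motif PWM
#'
#' A stand-in position weight matrix for the 14 bp extended PHO/PHOL/YY1
#' recognition motif, estimated from a synthetic alignment of 20
#' occurrences that conserve the GCCAT core (positions 6-10) and a
#' downstream thymidine while varying the flanks. It is constructed, not
#' derived from experimental site sequences, and exists so simulations and
#' examples run self-contained.
#'
#' @param pseudocount passed to [build_pwm()] (default 0.5).
#' @return a `"pwm"` object of width 14.
#' @export
example_motif_pwm <- function(pseudocount = 0.5) {
  flank5 <- c("CGAGT", "AGAGT", "CGTGT", "CAAGT", "CGAGC", "TGAGT", "CGACT",
              "CGAGT", "GGAGT", "CGAGT", "CCAGT", "CGATT", "CGAGT", "ACAGT",
              "CGGGT", "CGAGT", "TTAGT", "CGAGT", "CGCGT", "CGAGT")
  flank4 <- c("CTTG", "CTTC", "TTTG", "CTTA", "CTTG", "GTTG", "CTTT", "CATG",
              "CTTG", "CTGG", "TTTA", "CTTG", "ATTG", "CTTG", "CTTG", "GTTC",
              "CTTG", "CTCG", "CTTG", "CTTT")
  build_pwm(paste0(flank5, "GCCAT", flank4), pseudocount = pseudocount)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
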