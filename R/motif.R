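DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param seqs character vector of IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Estimate a position weight matrix from aligned motif occurrences
#'
#' Per-position base probabilities are `(count + pseudocount) /
#' (n + 4 * pseudocount)`. Motif discovery itself is out of scope: the
#' occurrences are supplied already aligned (e.g. exported from a motif
#' finder run on the strongest TSS-proximal sites).
#'
#' @param occurrences character vector of equal-length ACGT strings (case
#'   insensitive; ambiguity codes rejected).
#' @param pseudocount added per base per position (default 0.5).
#' @param background length-4 base probability vector in ACGT order
#'   (default uniform).
#' @return object of class `"pwm"`: a list with the 4 x L probability
#'   matrix `prob` (rows A, C, G, T), `background`, `pseudocount`, `width`.
#' @examples
#' build_pwm(c("GCCAT", "GCCAT", "GACAT"), pseudocount = 0.5)
#' @export
build_pwm <- function(occurrences, pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(occurrences) < 1) abort("need at least one occurrence")
  occurrences <- toupper(occurrences)
  L <- unique(nchar(occurrences))
  if (length(L) != 1) abort("occurrences must all have equal length")
  if (L < 1) abort("occurrences must be non-empty")
  if (any(grepl("[^ACGT]", occurrences))) {
    abort("occurrences must contain only A, C, G, T")
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be 4 positive probabilities summing to 1")
  }
  names(background) <- DNA_BASES
  chars <- matrix(unlist(strsplit(occurrences, "")), nrow = length(occurrences),
                  byrow = TRUE)
  n <- length(occurrences)
  prob <- vapply(seq_len(L), function(j) {
    counts <- table(factor(chars[, j], levels = DNA_BASES))
    (as.numeric(counts) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4))
  prob <- matrix(prob, nrow = 4, dimnames = list(DNA_BASES, NULL))
  structure(
    list(prob = prob, background = background, pseudocount = pseudocount,
         width = L),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, pseudocount %g\n", x$width, x$pseudocount))
  print(round(x$prob, 3))
  invisible(x)
}

#' @describeIn build_pwm tidy a PWM into a long tibble
#'   (`position`, `base`, `prob`, `log_odds`).
#' @param x a `"pwm"` object.
#' @param ... unused.
#' @method tidy pwm
#' @export
tidy.pwm <- function(x, ...) {
  lo <- log2(x$prob / x$background)
  tibble(
    position = rep(seq_len(x$width), each = 4),
    base = rep(DNA_BASES, x$width),
    prob = as.vector(x$prob),
    log_odds = as.vector(lo)
  )
}

#' Write / read a PWM
#'
#' `write_pwm()` stores the probability matrix as TSV (`position`, `A`,
#' `C`, `G`, `T`); `write_pwm_meme()` / `read_pwm_meme()` use a minimal
#' MEME-style letter-probability block.
#'
#' @param pwm a `"pwm"` object.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return a `"pwm"`.
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(t(pwm$prob))
  names(df) <- DNA_BASES
  df <- cbind(position = seq_len(pwm$width), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(DNA_BASES %in% names(df))) abort("PWM TSV needs columns A, C, G, T")
  prob <- t(as.matrix(df[DNA_BASES]))
  rownames(prob) <- DNA_BASES
  rowsums <- colSums(prob)
  if (any(abs(rowsums - 1) > 1e-6)) abort("PWM positions must sum to 1")
  structure(
    list(prob = prob, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
         pseudocount = NA_real_, width = ncol(prob)),
    class = "pwm"
  )
}

#' @rdname write_pwm
#' @export
write_pwm_meme <- function(pwm, path) {
  lines <- c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    sprintf("Background letter frequencies"),
    sprintf("A %.5f C %.5f G %.5f T %.5f",
            pwm$background[1], pwm$background[2], pwm$background[3],
            pwm$background[4]),
    "", "MOTIF pwm",
    sprintf("letter-probability matrix: alength= 4 w= %d", pwm$width),
    apply(t(pwm$prob), 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                              r[1], r[2], r[3], r[4]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^letter-probability matrix", lines)
  if (length(hdr) == 0) abort("no letter-probability matrix block found")
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr[1]]))
  rows <- lines[(hdr[1] + 1):(hdr[1] + w)]
  prob <- t(vapply(strsplit(trimws(rows), "[ \t]+"),
                   function(x) as.numeric(x[1:4]), numeric(4)))
  prob <- t(prob)
  rownames(prob) <- DNA_BASES
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^A [0-9.]+ C", lines)
  if (length(bgl) > 0) {
    parts <- strsplit(trimws(lines[bgl[1]]), "[ \t]+")[[1]]
    bg <- stats::setNames(as.numeric(parts[c(2, 4, 6, 8)]), DNA_BASES)
  }
  structure(
    list(prob = prob, background = bg, pseudocount = NA_real_, width = w),
    class = "pwm"
  )
}

#' Extract site sequences around binding peaks
#'
#' Takes the genomic sequence `[center - flank, center + flank)` around the
#' center of each peak window (400 bp at the default 200 bp flank),
#' uppercased. Windows running off a chromosome end are clipped with a
#' warning.
#'
#' @param genome a named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param peaks tibble with `chrom` and either `peak_start`/`peak_end` or
#'   `start`/`end`; the window is centered on `floor((from + to) / 2)`.
#' @param flank half-width in bp (default 200).
#' @return tibble with `site_id`, `chrom`, `start`, `end`, `seq`.
#' @export
extract_site_sequences <- function(genome, peaks, flank = 200) {
  genome <- as_genome_strings(genome)
  if ("peak_start" %in% names(peaks)) {
    from <- peaks$peak_start; to <- peaks$peak_end
  } else {
    from <- peaks$start; to <- peaks$end
  }
  center <- floor((from + to) / 2)
  ids <- if ("region_id" %in% names(peaks)) peaks$region_id else
    if ("site_id" %in% names(peaks)) peaks$site_id else
      sprintf("site_%03d", seq_len(nrow(peaks)))
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr) > 0) {
    abort(sprintf("chromosome(s) absent from genome: %s",
                  paste(missing_chr, collapse = ", ")))
  }
  chrom_len <- nchar(genome)[peaks$chrom]
  s <- pmax(0, center - flank)
  e <- pmin(chrom_len, center + flank)
  if (any(s > center - flank | e < center + flank)) {
    warn("some site windows were clipped at chromosome boundaries")
  }
  tibble(
    site_id = ids,
    chrom = peaks$chrom,
    start = unname(s),
    end = unname(e),
    seq = unname(toupper(substring(genome[peaks$chrom], s + 1, e)))
  )
}

as_genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(stats::setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    names(gs) <- sub("\\s.*$", "", names(gs))
    return(stats::setNames(as.character(gs), names(gs)))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("a character genome must be named by chromosome")
    }
    return(genome)
  }
  abort("`genome` must be a named character vector, DNAStringSet, or FASTA path")
}

pwm_log_odds <- function(pwm) {
  log2(pwm$prob / pwm$background)
}

encode_dna <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], DNA_BASES)
  m[is.na(m)] <- 5L  # ambiguous bases score the background odds (0)
  m
}

scan_scores <- function(code, lo) {
  L <- ncol(lo)
  lo5 <- rbind(lo, 0)
  n_win <- length(code) - L + 1L
  scores <- numeric(n_win)
  idx <- seq_len(n_win)
  for (j in seq_len(L)) {
    scores <- scores + lo5[cbind(code[idx + j - 1L], j)]
  }
  scores
}

#' Best PWM window within each site sequence
#'
#' Slides a `pwm$width` bp window one nucleotide at a time over the
#' sequence and its complementary strand, scores each window as the summed
#' log2 odds of its bases against the background, and reports the single
#' best score per site. Ties prefer the forward strand, then the smallest
#' offset. Ambiguous bases (e.g. `N`) contribute the background odds
#' (score 0) rather than minus infinity.
#'
#' @param seqs character vector of site sequences (each at least
#'   `pwm$width` long) or a tibble from [extract_site_sequences()].
#' @param pwm a `"pwm"` object.
#' @return tibble with one row per sequence: `site_id` (when available),
#'   `score`, `offset` (0-based start of the best window on the forward
#'   sequence) and `strand` (`"+"`/`"-"`).
#' @export
score_best_window <- function(seqs, pwm) {
  ids <- NULL
  if (is.data.frame(seqs)) {
    ids <- if ("site_id" %in% names(seqs)) seqs$site_id else NULL
    seqs <- seqs$seq
  }
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < pwm$width)) {
    abort(sprintf("all sequences must be at least PWM width (%d) long", pwm$width))
  }
  lo_fwd <- pwm_log_odds(pwm)
  # complement rows (A<->T, C<->G) and reverse columns: scores of the motif
  # on the reverse strand, expressed in forward coordinates
  lo_rev <- lo_fwd[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  res <- map(seqs, function(s) {
    code <- encode_dna(s)
    fwd <- scan_scores(code, lo_fwd)
    rev_ <- scan_scores(code, lo_rev)
    best_f <- max(fwd); best_r <- max(rev_)
    if (best_f >= best_r - 1e-12) {
      list(score = best_f, offset = which.max(fwd) - 1L, strand = "+")
    } else {
      list(score = best_r, offset = which.max(rev_) - 1L, strand = "-")
    }
  })
  out <- tibble(
    score = map_dbl(res, "score"),
    offset = vapply(res, function(r) as.integer(r$offset), integer(1)),
    strand = map_chr(res, "strand")
  )
  if (!is.null(ids)) out <- mutate(out, site_id = ids, .before = 1)
  out
}

#' Count perfect core-motif matches within site sequences
#'
#' Counts every perfect match to the conserved core pentamer (default
#' `GCCAT`) within each sequence. By default occurrences on both strands
#' are counted (the pattern plus its reverse complement on the given
#' sequence), overlaps allowed.
#'
#' @param seqs character vector of sequences or a tibble with a `seq`
#'   column.
#' @param core core motif (ACGT only; default `"GCCAT"`).
#' @param both_strands count the reverse complement too (default `TRUE`).
#' @return integer vector of counts, one per sequence.
#' @examples
#' count_core(c("GCCATGCCAT", "ATGGC", "AAAAA"))
#' @export
count_core <- function(seqs, core = "GCCAT", both_strands = TRUE) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (nchar(core) == 0 || grepl("[^ACGT]", core)) {
    abort("`core` must be a non-empty ACGT string")
  }
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  n <- Biostrings::vcountPattern(core, ss)
  if (both_strands) {
    rc <- reverse_complement(core)
    if (!identical(rc, core)) n <- n + Biostrings::vcountPattern(rc, ss)
  }
  as.integer(n)
}

#' Summarize motif statistics across binding-strength bins
#'
#' Sites are ranked by binding strength and split into `n_bins` equal-count
#' bins (bin 1 = strongest; any remainder goes to the strongest bins). For
#' each bin and each value column the mean and a seeded percentile-bootstrap
#' 95% confidence interval are reported — the per-bin summary behind
#' score-versus-strength histograms.
#'
#' @param sites tibble with a strength column and the value columns.
#' @param n_bins number of bins (default 4; must be `<= nrow(sites)`).
#' @param values character vector of value columns to summarize (default
#'   those of `score`, `core_count` that are present).
#' @param strength name of the strength column (default `"strength"`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf_level confidence level (default 0.95).
#' @param boot_seed seed for the bootstrap (default 1).
#' @return tibble of class `"bin_summary"`: `bin`, `n`, `variable`, `mean`,
#'   `ci_lo`, `ci_hi`.
#' @export
bin_and_summarize <- function(sites, n_bins = 4, values = NULL,
                              strength = "strength", n_boot = 1000,
                              conf_level = 0.95, boot_seed = 1) {
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  if (nrow(sites) < n_bins) abort("fewer sites than bins")
  if (!strength %in% names(sites)) {
    abort(sprintf("`sites` has no '%s' column", strength))
  }
  values <- values %||% intersect(c("score", "core_count"), names(sites))
  if (length(values) == 0) abort("no value columns to summarize")
  ord <- order(-sites[[strength]])
  n <- nrow(sites)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= rem)
  bin <- rep(seq_len(n_bins), times = sizes)
  alpha <- (1 - conf_level) / 2
  rows <- withr::with_seed(boot_seed, {
    out <- list()
    for (b in seq_len(n_bins)) {
      idx <- ord[bin == b]
      for (v in values) {
        x <- sites[[v]][idx]
        boots <- vapply(seq_len(n_boot),
                        function(i) mean(sample(x, replace = TRUE)),
                        numeric(1))
        ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
        out[[length(out) + 1]] <- tibble(
          bin = b, n = length(x), variable = v,
          mean = mean(x), ci_lo = ci[1], ci_hi = ci[2]
        )
      }
    }
    out
  })
  out <- bind_rows(rows)
  class(out) <- c("bin_summary", class(out))
  out
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) trend test
#'
#' Used to test whether motif statistics differ between the strongest and
#' weakest strength bins. The p-value is exact — computed by enumerating all
#' assignments of the combined mid-ranks to the first group — when
#' `n_a + n_b <= exact_limit`, and uses the normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exact_limit combined-size limit for exact enumeration (default 12).
#' @return object of class `"rank_sum_test"`: `statistic` (rank sum of
#'   `a`), `n_a`, `n_b`, `p.value`, `method`.
#' @export
rank_trend_test <- function(a, b, exact_limit = 12) {
  if (length(a) < 1 || length(b) < 1) abort("both groups need >= 1 value")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_limit) {
    sets <- combn(n, na)
    W_all <- colSums(matrix(r[sets], nrow = na))
    p <- mean(abs(W_all - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sigma
      p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation (tie-corrected)"
  }
  structure(
    list(statistic = W, n_a = na, n_b = nb, p.value = p, method = method),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s)\n", x$method))
  cat(sprintf("  W = %g (n = %d vs %d), two-sided p = %.4g\n",
              x$statistic, x$n_a, x$n_b, x$p.value))
  invisible(x)
}

#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, n_a = x$n_a,
         n_b = x$n_b, method = x$method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the mid-ranks — the statistic used to compare
#' per-PRE binding strengths between factors (e.g. PHO versus PHOL).
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return the correlation coefficient; zero rank variance is an error.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired values")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("rank variance is zero; Spearman correlation undefined")
  }
  as.numeric(cor(rx, ry))
}
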