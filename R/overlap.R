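intervals_to_granges <- function(df, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s need columns chrom, start, end", what))
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end))
  )
}

#' Fraction of sites overlapping a reference set
#'
#' A site overlaps if its span intersects at least one reference interval by
#' at least `min_overlap` bp (default 1 bp).
#'
#' @param sites tibble of site intervals (`chrom`, `start`, `end`).
#' @param reference tibble of reference intervals.
#' @param min_overlap minimum intersection in bp (default 1).
#' @return the fraction of `sites` overlapping, in `[0, 1]`. An empty site
#'   set is an error (not 0), to catch upstream failures.
#' @export
overlap_fraction <- function(sites, reference, min_overlap = 1L) {
  if (nrow(sites) == 0) abort("empty site set: overlap fraction is undefined")
  if (nrow(reference) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(
    intervals_to_granges(sites, "sites"),
    intervals_to_granges(reference, "reference"),
    minoverlap = min_overlap
  )
  mean(hits > 0)
}

#' Overlap-versus-strength curve
#'
#' Recomputes the overlap fraction with a reference set as the weaker
#' binding sites are progressively removed: for each retained fraction `f`
#' on a decreasing grid (100%, 95%, ... by `step_fraction`), the top
#' `ceiling(f * N)` sites by binding strength are kept and their overlap
#' fraction recorded.
#'
#' @param sites tibble of called regions with a `strength` column (ranked
#'   internally via [rank_by_strength()]).
#' @param reference reference interval tibble.
#' @param step_fraction grid step in `(0, 1]` (default 0.05).
#' @param min_overlap minimum intersection in bp (default 1).
#' @param site_label,reference_label labels carried into plots.
#' @return tibble of class `"overlap_curve"` with `retained_fraction`
#'   (decreasing), `n_sites` and `overlap_fraction`.
#' @seealso [autoplot.overlap_curve()]
#' @export
overlap_curve <- function(sites, reference, step_fraction = 0.05,
                          min_overlap = 1L,
                          site_label = "sites", reference_label = "reference") {
  if (nrow(sites) == 0) abort("empty site set")
  if (step_fraction <= 0 || step_fraction > 1) {
    abort("`step_fraction` must lie in (0, 1]")
  }
  ranked <- rank_by_strength(sites)
  flags <- if (nrow(reference) == 0) {
    rep(FALSE, nrow(ranked))
  } else {
    GenomicRanges::countOverlaps(
      intervals_to_granges(ranked, "sites"),
      intervals_to_granges(reference, "reference"),
      minoverlap = min_overlap
    ) > 0
  }
  n <- nrow(ranked)
  grid <- round(seq(1, step_fraction, by = -step_fraction), 10)
  out <- tibble(
    retained_fraction = grid,
    n_sites = pmin(n, ceiling(grid * n)),
    overlap_fraction = map_dbl(pmin(n, ceiling(grid * n)),
                               ~ mean(flags[seq_len(.x)]))
  )
  attr(out, "site_label") <- site_label
  attr(out, "reference_label") <- reference_label
  class(out) <- c("overlap_curve", class(out))
  out
}

#' Genomic intersection of several site sets
#'
#' Returns the merged genomic intervals covered by at least one site from
#' every input set — e.g. the binding sites co-occupied by PHO, PHOL and
#' SFMBT, or YY1 sites detected by all three antibodies. Commutative and
#' associative over the input sets.
#'
#' @param ... two or more site tibbles (`chrom`, `start`, `end`), or a
#'   single list of them.
#' @return tibble of merged intervals covered by all sets (possibly empty).
#' @export
intersect_site_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (length(sets) < 2) abort("need at least 2 site sets")
  covs <- map(sets, function(s) {
    if (nrow(s) == 0) GenomicRanges::GRanges() else
      GenomicRanges::reduce(intervals_to_granges(s, "sites"))
  })
  acc <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, covs)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(acc)),
    start = GenomicRanges::start(acc) - 1L,
    end = GenomicRanges::end(acc)
  )
}

#' Fraction of target domains carrying a co-occupied site
#'
#' @param domains tibble of target domains (e.g. Polycomb/H3K27me3 domains);
#'   must be non-empty.
#' @param sites tibble of (co-occupied) site intervals.
#' @return fraction of domains intersecting at least one site.
#' @export
target_coverage <- function(domains, sites) {
  if (nrow(domains) == 0) abort("`domains` must be non-empty")
  if (nrow(sites) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(
    intervals_to_granges(domains, "domains"),
    intervals_to_granges(sites, "sites")
  )
  mean(hits > 0)
}
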