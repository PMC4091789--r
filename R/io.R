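#' Read a probe-level tiling-array intensity table
#'
#' The pipeline's entry format is the tab-delimited probe table a CEL
#' processor would emit: one row per array feature (~25-mer probe) with its
#' genomic position and the raw per-replicate ChIP and Input intensities.
#' Required columns are `chrom`, `start` (0-based), `length` (bp), at least
#' one `chip_*` column and at least one `input_*` column.
#'
#' @param path path to a tab-delimited file with a header line.
#' @return A tibble sorted by `(chrom, start)` with the probe coordinate
#'   columns followed by the `chip_*` and `input_*` replicate columns.
#'   Unsorted input is sorted with a warning; negative intensities,
#'   non-positive probe lengths and duplicated `(chrom, start)` keys are
#'   errors.
#' @seealso [compute_ratio_profile()], [simulate_track()]
#' @export
read_probe_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed probe table '%s': parse problem at line %d (%s)",
      path, probs$row[1] + 1L, probs$expected[1]
    ))
  }
  validate_probe_track(tbl, source = path)
}

validate_probe_track <- function(tbl, source = "probe table") {
  need <- c("chrom", "start", "length")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s lacks required column(s): %s",
                  source, paste(missing, collapse = ", ")))
  }
  chip_cols <- grep("^chip_", names(tbl), value = TRUE)
  input_cols <- grep("^input_", names(tbl), value = TRUE)
  if (length(chip_cols) == 0 || length(input_cols) == 0) {
    abort(sprintf("%s needs at least one chip_* and one input_* column", source))
  }
  num_cols <- c("start", "length", chip_cols, input_cols)
  for (nm in num_cols) {
    if (!is.numeric(tbl[[nm]])) {
      abort(sprintf("%s: column '%s' must be numeric", source, nm))
    }
  }
  if (any(tbl$start < 0)) abort(sprintf("%s: negative probe start", source))
  if (any(tbl$length <= 0)) abort(sprintf("%s: probe length must be > 0", source))
  inten <- as.matrix(tbl[c(chip_cols, input_cols)])
  if (anyNA(inten)) abort(sprintf("%s: missing intensity value", source))
  if (any(inten < 0)) {
    bad <- which(inten < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: negative intensity at data row %d", source, bad[["row"]]))
  }
  if (anyDuplicated(tbl[c("chrom", "start")])) {
    abort(sprintf("%s: duplicated (chrom, start) probe", source))
  }
  ord <- order(tbl$chrom, tbl$start)
  if (!identical(ord, seq_len(nrow(tbl)))) {
    warn(sprintf("%s: probes were not sorted; sorting by (chrom, start)", source))
    tbl <- tbl[ord, ]
  }
  as_tibble(tbl)
}

#' Read a BED interval file
#'
#' Reads BED3/BED6 reference interval sets (PREs, Polycomb/H3K27me3 domains,
#' TSS windows) via `rtracklayer` and returns 0-based half-open intervals.
#'
#' @param path path to a BED file.
#' @param format only `"bed"` is supported.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the file, `name`, `score`, `strand`; sorted by `(chrom, start)`.
#'   Empty intervals (`end <= start`) are an error; an empty file gives an
#'   empty tibble.
#' @export
read_intervals <- function(path, format = "bed") {
  format <- match.arg(format, "bed")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) {
      abort(sprintf("invalid BED file '%s': %s", path, conditionMessage(e)))
    }
  )
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name) && !all(is.na(gr$name))) out$name <- as.character(gr$name)
  if (!is.null(gr$score) && !all(is.na(gr$score))) out$score <- as.numeric(gr$score)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand != "*")) out$strand <- strand
  if (any(out$end <= out$start)) {
    abort(sprintf("invalid BED file '%s': interval with end <= start", path))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Build TSS-centered windows
#'
#' Expands each transcription start site into a window of `2 * halfwidth` bp
#' centered on it (600 bp windows at `halfwidth = 300` for fly, 1400 bp at
#' `halfwidth = 700` for human), clipped at the chromosome start.
#'
#' @param records tibble with columns `chrom` and `tss` (0-based position of
#'   the TSS base); an optional `gene_id` column becomes the window name.
#' @param halfwidth window half-width in bp (> 0).
#' @return tibble of intervals `[tss - halfwidth, tss + halfwidth)`, clipped
#'   at 0.
#' @examples
#' tss_windows(tibble::tibble(chrom = "chr2L", tss = 1000), halfwidth = 300)
#' @export
tss_windows <- function(records, halfwidth) {
  if (!is.numeric(halfwidth) || length(halfwidth) != 1L || halfwidth <= 0) {
    abort("`halfwidth` must be a single positive number")
  }
  if (!all(c("chrom", "tss") %in% names(records))) {
    abort("`records` needs columns `chrom` and `tss`")
  }
  out <- tibble(
    chrom = records$chrom,
    start = pmax(0, records$tss - halfwidth),
    end = records$tss + halfwidth
  )
  if ("gene_id" %in% names(records)) out$name <- records$gene_id
  out
}

#' Classify genes as transcriptionally active
#'
#' Applies the expression-activity threshold: on the RPKM scale genes at or
#' above the threshold (default 300) are active; on the RMA scale activity
#' requires a value strictly above the threshold (default 6, "more than 6").
#'
#' @param records tibble with columns `gene_id` and `expression`; an
#'   optional `scale` column must be constant (mixing scales is an error).
#' @param threshold activity threshold; defaults to 300 (RPKM) or 6 (RMA).
#' @param scale `"rpkm"` or `"rma"`.
#' @return Character vector of active gene ids.
#' @export
classify_active <- function(records, threshold = NULL, scale = c("rpkm", "rma")) {
  scale <- match.arg(scale)
  if (!all(c("gene_id", "expression") %in% names(records))) {
    abort("`records` needs columns `gene_id` and `expression`")
  }
  if ("scale" %in% names(records)) {
    scales <- unique(tolower(records$scale))
    if (length(scales) > 1) abort("mixed expression scales in one call")
    if (length(scales) == 1 && scales != scale) {
      abort(sprintf("records are on the '%s' scale but scale = '%s' requested",
                    scales, scale))
    }
  }
  if (nrow(records) == 0) return(character())
  if (scale == "rpkm" && any(records$expression < 0)) {
    abort("RPKM expression values must be >= 0")
  }
  threshold <- threshold %||% if (scale == "rpkm") 300 else 6
  active <- if (scale == "rpkm") {
    records$expression >= threshold
  } else {
    records$expression > threshold
  }
  as.character(records$gene_id[active])
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param read_count reads mapped to the gene's exon model.
#' @param exon_length_bp exon model length in bp (> 0).
#' @param total_mapped_reads library size (> 0).
#' @return `read_count / (exon_length_bp/1000) / (total_mapped_reads/1e6)`,
#'   vectorized over its arguments.
#' @examples
#' rpkm(300, 1000, 1e6)
#' @export
rpkm <- function(read_count, exon_length_bp, total_mapped_reads) {
  if (any(exon_length_bp <= 0)) abort("`exon_length_bp` must be > 0")
  if (any(total_mapped_reads <= 0)) abort("`total_mapped_reads` must be > 0")
  read_count / (exon_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Write a per-probe profile as a genome-browser track
#'
#' Writes one record per probe carrying a defined value; probes whose value
#' is `NA` (e.g. smoothing windows with too few features) are omitted.
#' Values are rendered with fixed 6-digit decimal precision so reruns are
#' bit-identical.
#'
#' @param profile tibble with `chrom`, `start`, `length` and the value column.
#' @param path output file path.
#' @param format `"bedGraph"` or `"wig"` (variableStep; requires a constant
#'   probe length per chromosome).
#' @param value name of the value column (default `"smoothed"`, falling back
#'   to `"ratio"` if absent).
#' @return `path`, invisibly.
#' @seealso [read_track()]
#' @export
write_track <- function(profile, path, format = c("bedGraph", "wig"),
                        value = NULL) {
  format <- match.arg(format)
  value <- value %||% if ("smoothed" %in% names(profile)) "smoothed" else "ratio"
  if (!value %in% names(profile)) {
    abort(sprintf("profile has no '%s' column", value))
  }
  keep <- is.finite(profile[[value]])
  prof <- profile[keep, ]
  if (format == "bedGraph") {
    lines <- sprintf("%s\t%d\t%d\t%.6f",
                     prof$chrom, as.integer(prof$start),
                     as.integer(prof$start + prof$length), prof[[value]])
  } else {
    lines <- character()
    for (chr in unique(prof$chrom)) {
      p <- prof[prof$chrom == chr, ]
      span <- unique(as.integer(p$length))
      if (length(span) != 1) {
        abort("WIG variableStep needs a constant probe length per chromosome; use bedGraph")
      }
      lines <- c(lines,
                 sprintf("variableStep chrom=%s span=%d", chr, span),
                 sprintf("%d\t%.6f", as.integer(p$start) + 1L, p[[value]]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track back into a probe-value tibble
#'
#' Thin wrapper over `rtracklayer::import` used mainly to round-trip tracks
#' written by [write_track()].
#'
#' @param path bedGraph file path.
#' @return tibble with `chrom`, `start` (0-based), `end`, `value`.
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
}

#' Write bound regions or their peaks as BED6
#'
#' Region spans (or 6-feature peak windows) are written as BED6 with the
#' region id as name and the binding strength rescaled linearly to
#' `[0, 1000]` as the BED score.
#'
#' @param regions a [call_bound_regions()] tibble.
#' @param path output path.
#' @param what `"span"` or `"peak"`.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, what = c("span", "peak")) {
  what <- match.arg(what)
  if (nrow(regions) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  s <- regions$strength
  score <- if (max(s) > 0) as.integer(round(1000 * s / max(s))) else 0L
  if (what == "span") {
    from <- regions$start; to <- regions$end
  } else {
    from <- regions$peak_start; to <- regions$peak_end
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.",
                     regions$chrom, as.integer(from), as.integer(to),
                     regions$region_id, score),
             path)
  invisible(path)
}
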