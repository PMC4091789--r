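#' Plot an overlap-versus-strength curve
#'
#' Overlap fraction (as a percentage) against the fraction of strongest
#' sites retained, mirroring the way overlap curves are usually drawn:
#' moving right removes the weaker binding sites.
#'
#' @param object an `"overlap_curve"` tibble from [overlap_curve()], or a
#'   list of them for several site sets on one panel.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot overlap_curve
#' @export
autoplot.overlap_curve <- function(object, ...) {
  df <- mutate(as_tibble(object),
               set = attr(object, "site_label") %||% "sites")
  ggplot(df, aes(x = 1 - .data$retained_fraction,
                 y = 100 * .data$overlap_fraction, colour = .data$set)) +
    geom_line() +
    geom_point(size = 1) +
    scale_x_continuous(labels = function(x) sprintf("%d%%", round(100 * x))) +
    labs(
      x = "weaker sites removed",
      y = sprintf("%% overlap with %s",
                  attr(object, "reference_label") %||% "reference"),
      colour = NULL
    ) +
    theme_bw()
}

#' Plot binding-strength bin summaries
#'
#' Bar chart of per-bin means with 95% bootstrap confidence-interval
#' whiskers, one facet per summarized variable; bin 1 holds the strongest
#' sites.
#'
#' @param object a `"bin_summary"` tibble from [bin_and_summarize()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bin_summary
#' @export
autoplot.bin_summary <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = factor(.data$bin), y = .data$mean)) +
    geom_col(fill = "grey70", colour = "grey30") +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.25) +
    facet_wrap(~ .data$variable, scales = "free_y") +
    labs(x = "binding-strength bin (1 = strongest)", y = "mean") +
    theme_bw()
}

#' Plot a two-state binding comparison
#'
#' Paired per-PRE adjusted average binding signals in the repressed and
#' active states, joined by segments.
#'
#' @param object a `"state_comparison"` from [compare_states()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot state_comparison
#' @export
autoplot.state_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$signals,
                            c("signal_repressed", "signal_active"),
                            names_to = "state", values_to = "signal")
  df$state <- factor(ifelse(df$state == "signal_repressed",
                            "repressed", "active"),
                     levels = c("repressed", "active"))
  ggplot(df, aes(x = .data$state, y = .data$signal, group = .data$pre_id)) +
    geom_line(colour = "grey50") +
    geom_point(aes(colour = .data$state), size = 2) +
    labs(x = NULL, y = "adjusted average binding signal",
         subtitle = sprintf("Wilcoxon signed-rank (%s): p = %.4g",
                            object$test$alternative, object$test$p.value)) +
    guides(colour = "none") +
    theme_bw()
}

#' Plot a stretch of a smoothed profile
#'
#' @param profile tibble from [smooth_profile()].
#' @param chrom chromosome to show (default: first).
#' @param from,to optional bp bounds.
#' @return a ggplot object.
#' @export
plot_profile <- function(profile, chrom = NULL, from = NULL, to = NULL) {
  chrom <- chrom %||% profile$chrom[1]
  df <- filter(profile, .data$chrom == !!chrom)
  if (!is.null(from)) df <- filter(df, .data$midpoint >= from)
  if (!is.null(to)) df <- filter(df, .data$midpoint <= to)
  ggplot(df, aes(x = .data$midpoint, y = .data$smoothed)) +
    geom_line(na.rm = TRUE, colour = "steelblue") +
    labs(x = sprintf("%s position (bp)", chrom),
         y = "smoothed ChIP/Input ratio") +
    theme_bw()
}
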