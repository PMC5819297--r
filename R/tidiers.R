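#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a coverage profile
#'
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @return A plain tibble with `consensus`, `position`, `coverage`.
#' @export
tidy.coverage_profile <- function(x, ...) {
  tibble(consensus = attr(x, "consensus_name"),
         position = x$position, coverage = x$coverage)
}

#' One-row summary of a coverage profile
#'
#' @inheritParams tidy.coverage_profile
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble(consensus = attr(x, "consensus_name"),
         length = nrow(x),
         n_reads_total = attr(x, "n_reads_total"),
         n_aligned = attr(x, "n_aligned"),
         total_aligned_bases = sum(x$coverage),
         max_coverage = max(x$coverage),
         median_coverage = median(x$coverage),
         normalized = isTRUE(attr(x, "normalized")))
}

#' Tidy a composition table (family-level rows)
#'
#' @param x A `composition_table`.
#' @param ... Unused.
#' @export
tidy.composition_table <- function(x, ...) {
  as_tibble(x[x$level == "family",
              c("repclass", "subclass", "family", "count", "percent")])
}

#' One-row summary of a composition table
#'
#' @inheritParams tidy.composition_table
#' @export
glance.composition_table <- function(x, ...) {
  tibble(n_reads = attr(x, "n_total"),
         all_repeats_percent = sum(x$percent[x$level == "total"]),
         unassigned_percent = sum(x$percent[x$level == "unassigned"]),
         n_families = sum(x$level == "family"),
         zero_denominator = isTRUE(attr(x, "zero_denominator")))
}

#' Plot a coverage profile
#'
#' Line plot of per-position coverage, optionally shading called enrichment
#' segments.
#'
#' @param object A `coverage_profile`.
#' @param segments Optional segment tibble from
#'   [detect_enriched_segments()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, segments = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$position, y = .data$coverage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = sprintf("%s position (bp)",
                              attr(object, "consensus_name")),
                  y = if (isTRUE(attr(object, "normalized"))) {
                    "normalized coverage"
                  } else "read coverage") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments)) {
    p <- p + ggplot2::annotate("rect", xmin = segments$start,
                               xmax = segments$end, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "red")
  }
  p
}

#' Plot a composition table
#'
#' Bar chart of family percentages, coloured by repeat class.
#'
#' @param object A `composition_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_table <- function(object, ...) {
  df <- tidy(object)
  df$family <- stats::reorder(df$family, df$percent)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$percent,
                                   fill = .data$repclass)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of cleaned reads", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a contig structure map
#'
#' Draws the annotated intervals of one screened contig as coloured
#' segments (tandem arrays, TE internal parts, LTRs, unannotated).
#'
#' @param result One row of `screen_batch()$results` (or the output of
#'   [screen_contig()]).
#' @return A ggplot object.
#' @export
plot_structure_map <- function(result) {
  smap <- result$structure_map[[1]]
  smap$y <- 1
  ggplot2::ggplot(smap) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$y, yend = .data$y, colour = .data$type),
      linewidth = 6) +
    ggplot2::scale_colour_manual(values = c(
      TR_array = "#1b9e77", TE_internal = "#7570b3", TE_LTR = "#d95f02",
      unannotated = "grey80")) +
    ggplot2::labs(x = sprintf("%s (bp)", result$contig_id[[1]]), y = NULL,
                  colour = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::theme_minimal()
}
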