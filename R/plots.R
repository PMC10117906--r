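#' Plot strand-specific end counts around a locus
#'
#' Forward-strand N3E is drawn upward and reverse-strand N3E downward, the
#' standard way of eyeballing the two gap walls of a trapped cleavage site.
#'
#' @param object A `signal_tracks`.
#' @param from,to 0-based position range to draw.
#' @param metric "n3e", "n5e" or "coverage".
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_tracks <- function(object, from = 0L,
                                   to = object$length - 1L,
                                   metric = "n3e", ...) {
  dat <- tidy(object, from = from, to = to) |>
    filter(.data$metric == !!metric) |>
    mutate(value = ifelse(.data$strand == "-", -.data$value, .data$value))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$value,
                                    fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "position (bp)", y = paste0(metric, " (rev down)"),
                  title = object$sample) +
    ggplot2::theme_minimal()
}

#' Plot a fold-enrichment track
#'
#' @param object An `fe_track`.
#' @param from,to 0-based position range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fe_track <- function(object, from = 0L, to = object$length - 1L,
                              ...) {
  ggplot2::ggplot(tidy(object, from = from, to = to),
                  ggplot2::aes(x = .data$position, y = .data$fe)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "position (bp)", y = "fold enrichment") +
    ggplot2::theme_minimal()
}

#' Plot a motif as per-position information content
#'
#' A compact logo substitute: one column per motif position, height = column
#' information content (bits), coloured and labelled by the modal base. The
#' dyad axis between positions +2 and +3 is dashed.
#'
#' @param object A `motif_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_matrix <- function(object, ...) {
  dat <- tibble(
    position = object$positions,
    ic = unname(object$ic),
    base = strsplit(motif_consensus(object), "")[[1]]
  ) |>
    mutate(x = dplyr::if_else(.data$position > 0, .data$position - 0.5,
                              .data$position + 0.5))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$ic,
                                    fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), vjust = -0.3,
                       size = 2.6) +
    ggplot2::geom_vline(xintercept = 2, linetype = 2, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(A = "#33A02C", C = "#1F78B4",
                                          G = "#FF7F00", T = "#E31A1C")) +
    ggplot2::labs(x = "motif position (no 0; +1 = first overhang base)",
                  y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile
#'
#' @param profiles Output of [metagene()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profiles) {
  bounds <- profiles |>
    group_by(.data$region) |>
    summarise(b = min(.data$bin), .groups = "drop") |>
    filter(.data$region != "upstream")
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$bin, y = .data$mean_fe,
                               colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = bounds$b - 0.5, linetype = 2,
                        colour = "grey60") +
    ggplot2::labs(x = "oriented position (upstream | body bins | downstream)",
                  y = "mean fold enrichment", colour = "stratum") +
    ggplot2::theme_minimal()
}

#' Plot binned site density along the genome
#'
#' @param bins Output of [bin_density()].
#' @return A ggplot object.
#' @export
plot_bin_density <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                     y = .data$count)) +
    ggplot2::geom_col(width = bins$bin_end[1] - bins$bin_start[1]) +
    ggplot2::labs(x = "genome position (bp)", y = "sites per bin") +
    ggplot2::theme_minimal()
}
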