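#' Plot a G4 density profile
#'
#' Bar chart of density per kbp by feature region, faceted by gene set,
#' coloured by strand context.
#'
#' @param x A `g4_density` tibble from [density_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_density_profile <- function(x, ...) {
  ord <- x |>
    filter(.data$strand_context == "double", .data$gene_set == "all") |>
    arrange(desc(.data$density_per_kbp))
  lev <- unique(c(ord$region_class, x$region_class))
  ggplot2::ggplot(
    mutate(x, region_class = factor(.data$region_class, levels = lev)),
    ggplot2::aes(x = .data$region_class, y = .data$density_per_kbp,
                 fill = .data$strand_context)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~gene_set) +
    ggplot2::labs(x = "feature region", y = "G4 density (per kbp)",
                  fill = "strand context") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.g4_density <- function(object, ...) {
  plot_density_profile(object, ...)
}

#' Plot promoter G4-count gene classes
#'
#' Proportion of genes in each promoter G4-count class.
#'
#' @param x A `g4_promoter_classes` tibble from
#'   [promoter_class_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_promoter_classes <- function(x, ...) {
  d <- x |>
    dplyr::count(.data$promoter_class, .drop = FALSE) |>
    mutate(prop = .data$n / sum(.data$n))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$promoter_class,
                                  y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "G4s in promoter", y = "proportion of genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.g4_promoter_classes <- function(object, ...) {
  plot_promoter_classes(object, ...)
}

#' Plot binned genome tracks
#'
#' Line plot of per-bin GC fraction and gene/SSR/G4 counts along each
#' chromosome.
#'
#' @param tracks Tibble from [binned_tracks()].
#' @return A ggplot object.
#' @export
plot_genome_tracks <- function(tracks) {
  long <- tidyr::pivot_longer(
    tracks, c("gc_fraction", "gene_count", "ssr_count", "g4_count"),
    names_to = "track", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_start / 1e3,
                                     y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(track ~ chrom, scales = "free_y") +
    ggplot2::labs(x = "position (kbp)", y = NULL) +
    ggplot2::theme_minimal()
}
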