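#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the per-motif mutability ranking
#'
#' Bar chart of mean adjusted mutation frequency per motif, highlighting
#' the extended AGCTNT hotspot, its AGCTNV control and the WRCY family.
#'
#' @param ranking Output of [motif_mutability()].
#' @return A ggplot object.
#' @export
plot_motif_mutability <- function(ranking) {
  d <- ranking %>%
    dplyr::mutate(
      group = dplyr::case_when(
        .data$motif_name == "AGCTNT" ~ "AGCTNT",
        .data$motif_name == "AGCTNV" ~ "AGCTNV control",
        grepl("^[AT][AG]C[CT]$", .data$motif_name) |
          .data$motif_name %in% c("WRC", "WRCY") ~ "WRCY family",
        TRUE ~ "random"
      ),
      motif_name = stats::reorder(.data$motif_name, -.data$mean_freq)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$motif_name, y = .data$mean_freq,
                                  fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean adjusted mutation frequency",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the genotype comparison
#'
#' Boxplots of control-adjusted total mutation frequency per genotype over
#' the regions of the frequency matrix (typically restricted to called
#' targets).
#'
#' @param freq_matrix `freq_matrix` element of [compare_genotypes()].
#' @return A ggplot object.
#' @export
plot_genotype_comparison <- function(freq_matrix) {
  ggplot2::ggplot(freq_matrix,
                  ggplot2::aes(x = .data$genotype, y = .data$adj_freq)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "adjusted total mutation frequency") +
    ggplot2::theme_minimal()
}

#' Plot a per-base mutation-frequency track
#'
#' @param profile Output of [per_base_profile()].
#' @param region_id Region to draw.
#' @param hotspots Optional hotspot annotation; instances are marked along
#'   the x axis.
#' @return A ggplot object.
#' @export
plot_per_base_profile <- function(profile, region_id, hotspots = NULL) {
  d <- profile[profile$region_id == region_id, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$adj_freq)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::labs(x = "position (bp)",
                  y = "adjusted mutation frequency",
                  title = region_id) +
    ggplot2::theme_minimal()
  if (!is.null(hotspots)) {
    h <- hotspots[hotspots$region_id == region_id, ]
    if (nrow(h) > 0) {
      p <- p + ggplot2::geom_rug(
        data = h, ggplot2::aes(x = .data$position), inherit.aes = FALSE,
        sides = "b", colour = "red")
    }
  }
  p
}

#' Plot the positional base composition around mutated cytosines
#'
#' Stacked-bar rendering of the logo matrix from [position_composition()].
#'
#' @param composition Output of [position_composition()].
#' @return A ggplot object.
#' @export
plot_position_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$position, y = .data$percentage,
                               fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position relative to mutated C", y = "% of contexts",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
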