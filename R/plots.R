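# ggplot2 displays for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Histogram of per-frame loop RMSD
#'
#' @param object A `flexibility_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flexibility_result <- function(object, ...) {
  ggplot2::ggplot(object$per_frame, ggplot2::aes(x = .data$rmsd)) +
    ggplot2::geom_histogram(
      bins = length(object$histogram$counts),
      fill = "steelblue", colour = "white"
    ) +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(
      x = "loop RMSD (Å)", y = "frames",
      subtitle = sprintf("%.2f ± %.2f Å", object$mean, object$sd)
    ) +
    ggplot2::theme_minimal()
}

#' Donor-acceptor distance trace with the active-pose threshold
#'
#' @param object A `distance_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_series <- function(object, ...) {
  ggplot2::ggplot(
    object$series,
    ggplot2::aes(x = .data$frame, y = .data$distance, colour = .data$active)
  ) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "forestgreen", `FALSE` = "firebrick"),
      name = "active pose"
    ) +
    ggplot2::labs(
      x = "frame", y = "C4–N5 distance (Å)",
      subtitle = sprintf("active-pose occupancy %.1f%%", 100 * object$occupancy)
    ) +
    ggplot2::theme_minimal()
}

#' Free-energy surface heat map
#'
#' @param object A `free_energy_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df[!is.na(df$energy), ],
    ggplot2::aes(x = .data$pc1, y = .data$pc2, fill = .data$energy)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "free energy (kT)") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Per-condition latent-space scatter with temporal shading
#'
#' Lighter points mark frames from the start of each trajectory, darker
#' points the end.
#'
#' @param object A `landscape_model`.
#' @param states Optional `state_assignment`; when given, cluster centers
#'   are overlaid with their letters.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.landscape_model <- function(object, states = NULL, ...) {
  df <- tidy(object)
  df <- dplyr::mutate(dplyr::group_by(df, .data$condition),
    time = .data$frame / max(.data$frame)
  )
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$pc1, y = .data$pc2, alpha = .data$time)
  ) +
    ggplot2::geom_point(size = 0.5, colour = "navy") +
    ggplot2::scale_alpha(range = c(0.15, 0.9), name = "trajectory time") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
  if (!is.null(states)) {
    cen <- tibble::as_tibble(states$centers, rownames = "state")
    names(cen)[2:3] <- c("pc1", "pc2")
    p <- p +
      ggplot2::geom_label(
        data = cen,
        ggplot2::aes(x = .data$pc1, y = .data$pc2, label = .data$state),
        inherit.aes = FALSE
      )
  }
  p
}
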