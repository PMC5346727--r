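#' Scree plot of a principal network projection
#'
#' Bars show each component's eigenexpression fraction, the line its
#' cumulative sum; the dashed lines mark the energy threshold and the
#' selected component count.
#'
#' @param object A [pnp_decompose()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pnp_result <- function(object, ...) {
  df <- tibble(
    component = seq_along(object$energy_fraction),
    fraction = object$energy_fraction,
    cumulative = cumsum(object$energy_fraction)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction), fill = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$energy, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$m_selected, linetype = "dashed") +
    ggplot2::labs(x = "component", y = "eigenexpression fraction",
                  title = sprintf("%d of %d components carry %.0f%% of the network energy",
                                  object$m_selected, length(object$d),
                                  100 * object$energy)) +
    ggplot2::theme_minimal()
}

#' Projection distances by node role
#'
#' Ranks nodes by projection distance within each role; the nodes at the
#' top are the candidates for the core network.
#'
#' @param pnp A [pnp_decompose()] result.
#' @param top Label the `top` highest-distance nodes per role.
#' @return A ggplot object.
#' @export
plot_projection_distances <- function(pnp, top = 5) {
  df <- pnp$distances |>
    dplyr::group_by(.data$role) |>
    dplyr::arrange(dplyr::desc(.data$distance), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  label = ifelse(.data$rank <= top, .data$node, "")) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$distance,
                                   colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 2.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~role, scales = "free") +
    ggplot2::labs(x = "rank within role", y = "projection distance D(k)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname plot_projection_distances
#' @param object A [extract_core()] result.
#' @param ... Unused.
#' @export
autoplot.core_gen <- function(object, ...) {
  ggplot2::ggplot(object$nodes,
                  ggplot2::aes(x = stats::reorder(.data$node, .data$distance),
                               y = .data$distance, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~role, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "projection distance D(k)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
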