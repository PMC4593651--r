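#' Plot a star-value histogram
#'
#' Bar plot of the normalized star-value distribution: mass near 0 is
#' clique-like neighbourhoods, mass near 1 is star-like ones.
#'
#' @param object An `sv_dist` tibble from [sv_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sv_dist
#' @export
autoplot.sv_dist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$freq)) +
    ggplot2::geom_col(width = object$hi[1] - object$lo[1],
                      fill = "steelblue", colour = "grey20", linewidth = 0.2) +
    ggplot2::labs(x = "star value", y = "normalized frequency") +
    ggplot2::theme_minimal()
}

#' Plot workload closure per group
#'
#' Grouped bars of density, clustering coefficient and workload closure
#' coefficient for each group, ordered by ascending closure.
#'
#' @param object A `wcc_tbl` from [wcc_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wcc_tbl
#' @export
autoplot.wcc_tbl <- function(object, ...) {
  long <- object |>
    mutate(label = factor(.data$label, levels = .data$label)) |>
    tidyr::pivot_longer(c("density", "cc", "wcc"),
                        names_to = "measure", values_to = "value") |>
    mutate(measure = factor(.data$measure, levels = c("density", "cc", "wcc")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "group", y = "value", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a disparity profile
#'
#' Three panels against disparity: mean star value, mean hub degree and the
#' normalized count of local subnetworks.
#'
#' @param object A `disparity_profile` from [disparity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot disparity_profile
#' @export
autoplot.disparity_profile <- function(object, ...) {
  long <- object |>
    select("disparity", `mean SV` = "mean_sv", `mean hub degree` = "mean_degree",
           `fraction of subnetworks` = "freq") |>
    tidyr::pivot_longer(-"disparity", names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$disparity, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "disparity", y = NULL) +
    ggplot2::theme_minimal()
}

#' Brokerage role mix of each group
#'
#' Stacked bars of the five unnormalized role counts aggregated by group —
#' a headless counterpart of per-vertex pie charts.
#'
#' @param object A `brokerage_tbl` from [brokerage_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot brokerage_tbl
#' @export
autoplot.brokerage_tbl <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(all_of(.role_levels), names_to = "role", values_to = "count") |>
    group_by(.data$label, .data$role) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(role = factor(.data$role, levels = .role_levels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$count,
                                     fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "group", y = "unnormalized count", fill = "role") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
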