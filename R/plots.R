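#' Kaplan-Meier step curves
#'
#' @param km Tibble from [km_estimate()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  assert_cols(km, c("group", "time", "survival"), "KM table")
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (years)", y = "Survival probability",
                  colour = "Risk group") +
    ggplot2::theme_minimal()
}

#' Per-cohort fold-change heatmap of progression proteins
#'
#' @param progression Tibble from [concordant_progression_proteins()].
#' @return A ggplot object (log2 fold-change tiles, protein by cohort).
#' @export
plot_fold_changes <- function(progression) {
  assert_cols(progression, c("protein_symbol", "direction"),
              "progression table")
  long <- progression |>
    select("protein_symbol", "direction", dplyr::starts_with("fc_")) |>
    tidyr::pivot_longer(dplyr::starts_with("fc_"), names_to = "cohort",
                        values_to = "fc", names_prefix = "fc_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort,
                                     y = .data$protein_symbol,
                                     fill = log2(.data$fc))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$direction),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Cohort", y = NULL, fill = "log2 FC (M / non-M)") +
    ggplot2::theme_minimal()
}

#' Layered network diagram
#'
#' Draws the hierarchically layered interaction network: regulators on the
#' top layer, each node placed by its minimal step size to a regulator,
#' edges as segments.
#'
#' @param graph An [interaction_graph()].
#' @param layers Tibble from [assign_layers()].
#' @return A ggplot object.
#' @export
plot_network_layers <- function(graph, layers) {
  stopifnot(inherits(graph, "interaction_graph"))
  assert_cols(layers, c("protein_symbol", "layer"), "layer table")
  pos <- layers |>
    group_by(.data$layer) |>
    mutate(x = (dplyr::row_number() - (dplyr::n() + 1) / 2)) |>
    ungroup() |>
    mutate(y = -.data$layer)
  seg <- graph$edges |>
    left_join(select(pos, "protein_symbol", x1 = "x", y1 = "y"),
              by = c(protein1 = "protein_symbol")) |>
    left_join(select(pos, "protein_symbol", x2 = "x", y2 = "y"),
              by = c(protein2 = "protein_symbol")) |>
    filter(!is.na(.data$x1) & !is.na(.data$x2))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$protein_symbol),
                       vjust = -1, size = 2.5) +
    ggplot2::labs(x = NULL, y = "Layer (steps from regulator)") +
    ggplot2::theme_void()
}

#' Forest plot of Cox hazard ratios
#'
#' @param fit A `plasmasig_cox` object from [cox_fit()].
#' @return A ggplot object (HR with 95% CI per term, log scale).
#' @export
plot_cox_forest <- function(fit) {
  tb <- tidy(fit)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
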