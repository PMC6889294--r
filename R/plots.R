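#' Kaplan-Meier step plot
#'
#' @param km An `ec_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_km <- function(km, ...) {
  start <- km |>
    distinct(.data$group) |>
    mutate(time = 0, surv = 1)
  ggplot2::ggplot(bind_rows(start, km),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = km |> filter(.data$n_censor > 0), shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' @rdname plot_km
#' @param object An `ec_km` tibble.
#' @export
autoplot.ec_km <- function(object, ...) plot_km(object, ...)

#' Per-gene mutation frequency bars
#'
#' @param freq Tibble from [gene_frequencies()].
#' @return A ggplot object.
#' @export
plot_gene_frequencies <- function(freq) {
  ggplot2::ggplot(freq,
                  ggplot2::aes(x = stats::reorder(.data$gene, -.data$fraction),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Mutated samples (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Gini importance bars
#'
#' @param importance Tibble from [gini_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = stats::reorder(.data$gene, .data$gini),
                               y = .data$gini)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean decrease in Gini impurity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
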