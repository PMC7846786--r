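# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_tile scale_x_log10 labs theme_minimal facet_grid scale_fill_manual
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 4PL dose-response fit
#'
#' Observed points with the fitted curve on a log-dose axis.
#'
#' @param object A `fourpl_fit`.
#' @param n_curve Points along the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, n_curve = 200, ...) {
  rng <- range(object$data$dose)
  grid <- tibble(dose = exp(seq(log(rng[1]), log(rng[2]), length.out = n_curve)))
  grid$response <- predict(object, grid)
  ggplot(object$data, aes(x = .data$dose, y = .data$response)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point() +
    scale_x_log10() +
    labs(x = "dose", y = "response",
         title = sprintf("4PL fit: IC50 = %.3g, Hill = %.2f",
                         coef(object)["ic50"], coef(object)["hill"])) +
    theme_minimal()
}

#' Plot an interface footprint
#'
#' Per-residue buried surface area, facetted by chain group.
#'
#' @param object A `footprint_result`.
#' @param min_dsasa Hide residues burying less than this (A^2, default 0.1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot footprint_result
#' @export
autoplot.footprint_result <- function(object, min_dsasa = 0.1, ...) {
  d <- object$per_residue %>%
    filter(.data$dsasa >= min_dsasa) %>%
    mutate(res = paste0(.data$chain, .data$resno, .data$ins))
  ggplot(d, aes(x = stats::reorder(.data$res, .data$resno), y = .data$dsasa)) +
    geom_col(fill = "steelblue") +
    facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    labs(x = "residue", y = expression(Delta * SASA ~ (ring(A)^2)),
         title = sprintf("buried: A = %.0f, B = %.0f (A^2)",
                         object$side_a_buried, object$side_b_buried)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot merge provenance along the numbered chains
#'
#' One tile per position, coloured by provenance (scaffold / H-binder /
#' L-binder / mutation).
#'
#' @param object A `merge_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot merge_result
#' @export
autoplot.merge_result <- function(object, ...) {
  d <- object$merged %>%
    as_tibble() %>%
    mutate(pos = label_numeric(.data$label))
  cols <- c(scaffold = "grey85", `H-binder` = "#c23b22",
            `L-binder` = "#2a6fb0", mutation = "#e6b422")
  ggplot(d, aes(x = .data$pos, y = .data$chain, fill = .data$provenance)) +
    geom_tile(colour = "white", linewidth = 0.2) +
    scale_fill_manual(values = cols) +
    labs(x = "numeric Kabat position", y = NULL, fill = "source") +
    theme_minimal()
}
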