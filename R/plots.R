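# ggplot2 views of the result objects.

#' Plot an adequacy result: observed statistics against their null
#'
#' One panel per statistic: the parametric-bootstrap null distribution with
#' the observed value as a vertical line. Statistics that are `NA` on the
#' observed data are dropped.
#'
#' @param object An `adequacy_result` from [assess_adequacy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.adequacy_result <- function(object, ...) {
  null_long <- tibble::as_tibble(object$null) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "statistic", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  obs <- tidy(object) |> dplyr::filter(!is.na(.data$observed))
  null_long <- dplyr::semi_join(null_long, obs, by = "statistic")
  ggplot2::ggplot(null_long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "statistic value", y = "bootstrap count",
                  title = "Observed adequacy statistics vs. parametric-bootstrap null") +
    ggplot2::theme_minimal()
}

#' Bar chart of best-fit model proportions across genes
#'
#' @param genes Per-gene results tibble from [run_study()].
#' @return A ggplot object.
#' @export
plot_model_support <- function(genes) {
  df <- genes |>
    dplyr::filter(is.na(.data$skip_reason)) |>
    dplyr::count(.data$best_model) |>
    dplyr::mutate(prop = .data$n / sum(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$best_model, y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "best-fit model (AIC)", y = "proportion of genes") +
    ggplot2::theme_minimal()
}

#' Histograms of adequacy p-values per statistic across genes
#'
#' Under an adequate model the p-values are near-uniform; spikes below the
#' cutoff flag the statistics through which the model fails.
#'
#' @param genes Per-gene results tibble from [run_study()].
#' @param alpha_level Cutoff drawn as a vertical line (default 0.05).
#' @return A ggplot object.
#' @export
plot_adequacy_pvalues <- function(genes, alpha_level = 0.05) {
  df <- genes |>
    dplyr::select("gene_id", dplyr::starts_with("p_")) |>
    tidyr::pivot_longer(-"gene_id", names_to = "statistic",
                        values_to = "p", names_prefix = "p_") |>
    dplyr::filter(!is.na(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05), fill = "grey60") +
    ggplot2::geom_vline(xintercept = alpha_level, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::labs(x = "bootstrap p-value", y = "genes") +
    ggplot2::theme_minimal()
}
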