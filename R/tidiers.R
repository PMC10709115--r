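# broom-style tidiers for the package's fitted objects.

#' @rdname tidiers
#' @param x A fitted object (`model_fit`, `model_comparison` or
#'   `adequacy_result`).
#' @param ... Unused; for generic consistency.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.model_fit <- function(x, ...) {
  p <- x$params
  vals <- c(sigsq = p$sigsq, alpha = p$alpha, r = p$r, z0 = p$z0)
  tibble::tibble(model = x$model, term = names(vals), estimate = unname(unlist(vals)))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, lnL = x$lnL, k = x$k, AIC = x$aic, n_tips = x$n_tips,
    convergence = x$convergence, boundary = x$boundary, restarts = x$restarts
  )
}

#' Tidiers for model comparisons and adequacy results
#'
#' `tidy()` returns the per-model or per-statistic table; `glance()` a
#' one-row summary.
#'
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) x$table

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) {
  best <- x$fits[[x$best]]
  tibble::tibble(
    best_model = x$best,
    n_models = nrow(x$table),
    best_AIC = best$aic,
    best_weight = x$table$weight[x$table$model == x$best]
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.adequacy_result <- function(x, ...) {
  tibble::tibble(
    statistic = adequacy_stat_names,
    observed = unname(x$observed[adequacy_stat_names]),
    p_value = unname(x$p[adequacy_stat_names])
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.adequacy_result <- function(x, ...) {
  tibble::tibble(
    adequate = x$adequate, n_sim = x$n_sim, alpha = x$alpha,
    n_na_stats = sum(is.na(x$observed))
  )
}
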