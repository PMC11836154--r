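#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidy the per-realization results of a trial
#'
#' @param x An `hf_trial`.
#' @param ... Unused.
#' @return A tibble with one row per realization: `realization`,
#'   `n_fractures`, `n_evaluations`, `incidence`.
#' @method tidy hf_trial
#' @export
tidy.hf_trial <- function(x, ...) {
  dplyr::mutate(x$realizations, incidence = .data$n_fractures / x$n_patients)
}

#' One-row summary of a trial
#'
#' @param x An `hf_trial`.
#' @param ... Unused.
#' @return A one-row tibble: mean/sd/min/max fracture counts, incidence
#'   (fraction of the cohort), mean evaluations, and the convergence
#'   realization index (`NA` if not reached).
#' @method glance hf_trial
#' @export
glance.hf_trial <- function(x, ...) {
  n <- x$realizations$n_fractures
  tibble::tibble(
    n_realizations = length(n),
    mean_fractures = mean(n),
    sd_fractures = if (length(n) > 1) stats::sd(n) else 0,
    min_fractures = min(n),
    max_fractures = max(n),
    incidence = mean(n) / x$n_patients,
    mean_evaluations = mean(x$realizations$n_evaluations),
    converged_at = if (is.null(x$convergence)) NA_integer_ else
      attr(x$convergence, "converged_at")
  )
}

#' Tidy a convergence trace
#'
#' @param x An `hf_convergence`.
#' @param ... Unused.
#' @return The trace as a plain tibble.
#' @method tidy hf_convergence
#' @export
tidy.hf_convergence <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot per-realization fracture counts
#'
#' @param object An `hf_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_trial
#' @export
autoplot.hf_trial <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$realization),
                                  y = .data$n_fractures)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = mean(d$n_fractures), linetype = 2) +
    ggplot2::labs(x = "realization", y = "fractures",
                  title = sprintf("Predicted fractures over %d realizations",
                                  nrow(d))) +
    ggplot2::theme_minimal()
}

#' Plot a convergence trace
#'
#' Bootstrap and plain cumulative-mean relative differences against the
#' number of realizations, with the convergence threshold.
#'
#' @param object An `hf_convergence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_convergence
#' @export
autoplot.hf_convergence <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("plain_rel_diff", "bootstrap_rel_diff"),
                        names_to = "kind", values_to = "rel_diff")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$rel_diff,
                                  colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"), linetype = 2) +
    ggplot2::labs(x = "realizations included", y = "relative difference",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a strength surface over the direction grid
#'
#' @param object An `hf_strength_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_strength_surface
#' @export
autoplot.hf_strength_surface <- function(object, ...) {
  d <- tidyr::expand_grid(beta = 0:30, alpha = -30:30)[, c("alpha", "beta")]
  d$failure_load <- as.vector(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                  fill = .data$failure_load)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "failure load (N)") +
    ggplot2::labs(x = "alpha (deg)", y = "beta (deg)") +
    ggplot2::theme_minimal()
}
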