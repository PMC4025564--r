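#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solver result into its convergence history
#'
#' @param x A `solver_result` from [ess_solve()], [vns_solve()] or
#'   [cooperative_solve()].
#' @param ... Unused.
#' @return A tibble with columns `evaluations` and `best` (best penalized
#'   objective found by that evaluation count), one row per improvement.
#' @method tidy solver_result
#' @export
tidy.solver_result <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' One-row summary of a solver result
#'
#' @param x A `solver_result`.
#' @param ... Unused.
#' @return A tibble with `method`, `best`, `feasible`, `evaluations`,
#'   `seed`.
#' @method glance solver_result
#' @export
glance.solver_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    best = x$best$penalized,
    feasible = x$best$feasible,
    evaluations = x$total_evaluations,
    seed = x$seed[1]
  )
}

#' Per-parameter posterior estimates from a BayesFit run
#'
#' @param x A [bayesfit_sample()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, standard
#'   deviation, 95% credible bounds and the best-fit value, pooled across
#'   chains.
#' @method tidy bayesfit
#' @export
tidy.bayesfit <- function(x, ...) {
  m <- pooled_samples(x)
  tibble::tibble(
    term = paste0("p", seq_len(ncol(m))),
    estimate = colMeans(m),
    std.error = apply(m, 2, stats::sd),
    conf.low = apply(m, 2, stats::quantile, 0.025),
    conf.high = apply(m, 2, stats::quantile, 0.975),
    best_fit = x$best$x
  )
}

#' One-row summary of a BayesFit run
#'
#' @param x A [bayesfit_sample()] result.
#' @param ... Unused.
#' @return A tibble with chain/retention counts, the mean acceptance rate
#'   and the best log-posterior.
#' @method glance bayesfit
#' @export
glance.bayesfit <- function(x, ...) {
  tibble::tibble(
    n_chains = length(x$chains),
    retained = sum(vapply(x$chains, function(ch) nrow(ch$samples),
                          numeric(1))),
    acceptance = mean(vapply(x$chains, function(ch)
      ch$accepted_count / ch$n_proposals, numeric(1))),
    best_log_posterior = x$best$log_posterior
  )
}

#' Convergence-curve plot of a solver result
#'
#' Step plot of the best penalized objective against evaluations spent, on
#' a log axis when all values are positive.
#'
#' @param object A `solver_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.solver_result <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  }
  df <- tidy.solver_result(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$evaluations,
                                        y = .data$best)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "objective evaluations", y = "best penalized value",
                  title = object$method) +
    ggplot2::theme_minimal()
  if (all(df$best > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Marginal posterior histograms of a BayesFit run
#'
#' One panel per parameter, pooled across chains, with the best-fit value
#' marked — multimodal or flat panels flag non-identifiable parameters.
#'
#' @param object A [bayesfit_sample()] result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bayesfit <- function(object, bins = 30, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  }
  m <- pooled_samples(object)
  df <- data.frame(
    parameter = rep(paste0("p", seq_len(ncol(m))), each = nrow(m)),
    value = as.vector(m)
  )
  best <- data.frame(parameter = paste0("p", seq_len(ncol(m))),
                     value = object$best$x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(data = best,
                        ggplot2::aes(xintercept = .data$value),
                        colour = "red") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "pooled samples") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
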