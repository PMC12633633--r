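new_ppglm_fit <- function(weights, intercept, n_neurons, basis, estimator,
                          link = "exp", target = NA_integer_, meta = list()) {
  J <- basis$J
  stopifnot(length(weights) == n_neurons * J)
  structure(
    list(
      weights = as.numeric(weights),   # row-major per neuron: (n, j)
      intercept = as.numeric(intercept),
      n_neurons = as.integer(n_neurons),
      basis = basis,
      estimator = estimator,
      link = link,
      target = target,
      meta = meta
    ),
    class = "ppglm_fit"
  )
}

fit_params <- function(fit) {
  ppglm_params(matrix(fit$weights, fit$n_neurons, fit$basis$J, byrow = TRUE),
               w0 = fit$intercept, link = fit$link)
}

fit_from_params <- function(params, basis, estimator, target = NA_integer_,
                            meta = list()) {
  new_ppglm_fit(as.vector(t(params$W)), params$w0, params$n_neurons,
                basis, estimator, link = params$link, target = target,
                meta = meta)
}

#' @export
print.ppglm_fit <- function(x, ...) {
  cat(sprintf(
    "<ppglm_fit> estimator %s | target %s | N = %d presynaptic, J = %d (%s basis)\n",
    x$estimator, as.character(x$target), x$n_neurons, x$basis$J, x$basis$kind))
  cat(sprintf("  intercept %.4f (baseline %.3g Hz under %s link)\n",
              x$intercept, nonlinearity(x$link)$forward(x$intercept), x$link))
  invisible(x)
}

#' Tidy a fitted point-process GLM
#'
#' One row per (presynaptic neuron, basis function) weight, plus a final row
#' for the intercept (`neuron = NA`).
#'
#' @param x A `ppglm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `neuron`, `basis_index`, `estimate`.
#' @export
tidy.ppglm_fit <- function(x, ...) {
  J <- x$basis$J
  n <- rep(seq_len(x$n_neurons), each = J)
  j <- rep(seq_len(J), times = x$n_neurons)
  tibble::tibble(
    term = c(sprintf("w[%d,%d]", n, j), "(intercept)"),
    neuron = c(n, NA_integer_),
    basis_index = c(j, NA_integer_),
    estimate = c(x$weights, x$intercept)
  )
}

#' One-row summary of a fitted point-process GLM
#'
#' @param x A `ppglm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: estimator, parameter count, baseline rate,
#'   iterations and final objective (where the estimator records them).
#' @export
glance.ppglm_fit <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator,
    n_neurons = x$n_neurons,
    n_basis = x$basis$J,
    n_parameters = length(x$weights) + 1L,
    baseline_hz = nonlinearity(x$link)$forward(x$intercept),
    n_iter = x$meta$n_iter %||% NA_integer_,
    objective = x$meta$final_objective %||% NA_real_
  )
}

#' Coupling filters on a lag grid
#'
#' Reconstructs each presynaptic neuron's coupling filter
#' \eqn{f_n(\tau) = w_n^\top \phi(\tau)} (log-rate modulation) on a lag grid.
#'
#' @param fit A `ppglm_fit`, or a ground-truth object from the simulator.
#' @param lags Lags in seconds (default: 0.05 ms grid over `[0, H]`).
#' @param ... Unused.
#' @return A tibble with columns `neuron`, `lag`, `value`.
#' @export
coupling_filters <- function(fit, lags = NULL, ...) {
  UseMethod("coupling_filters")
}

#' @export
coupling_filters.ppglm_fit <- function(fit, lags = NULL, ...) {
  if (is.null(lags)) lags <- filter_grid(fit$basis$H)
  Phi <- eval_basis(fit$basis, lags)
  W <- matrix(fit$weights, fit$n_neurons, fit$basis$J, byrow = TRUE)
  vals <- Phi %*% t(W)
  tibble::tibble(
    neuron = rep(seq_len(fit$n_neurons), each = length(lags)),
    lag = rep(lags, fit$n_neurons),
    value = as.vector(vals)
  )
}

# default evaluation grid for filters: 0.05 ms
filter_grid <- function(H) seq(0, H, by = 5e-5)

#' Plot coupling filters of a fit
#'
#' @param object A `ppglm_fit`.
#' @param ... Unused.
#' @return A ggplot object, one facet per presynaptic neuron.
#' @export
autoplot.ppglm_fit <- function(object, ...) {
  df <- coupling_filters(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1000 * .data$lag, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~neuron, scales = "free_y") +
    ggplot2::labs(x = "lag (ms)", y = "log-rate modulation",
                  title = sprintf("Coupling filters (%s)", object$estimator))
}

#' Plot basis functions
#'
#' @param object A `temporal_basis`.
#' @param n_grid Number of lag points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.temporal_basis <- function(object, n_grid = 400, ...) {
  lags <- seq(0, object$H, length.out = n_grid)
  Phi <- eval_basis(object, lags)
  df <- tibble::tibble(
    lag = rep(lags, object$J),
    j = factor(rep(seq_len(object$J), each = n_grid)),
    value = as.vector(Phi)
  )
  ggplot2::ggplot(df, ggplot2::aes(1000 * .data$lag, .data$value,
                                   colour = .data$j)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = expression(phi(tau)),
                  colour = "basis", title = paste(object$kind, "basis"))
}
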