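#' Stratified sample of the recording interval
#'
#' Divides `[0, T]` into `M` equal strata and draws one uniform point per
#' stratum. The resulting CIF estimator is unbiased with lower variance than
#' plain uniform sampling at equal `M`.
#'
#' @param duration Recording duration `T` (seconds).
#' @param M Number of strata.
#' @return Numeric vector of `M` sample times, one per stratum, increasing.
#' @export
stratified_sample <- function(duration, M) {
  stopifnot(M >= 1, duration > 0)
  (seq_len(M) - stats::runif(M)) * duration / M
}

#' Plain uniform sample of the recording interval
#'
#' Comparison sampler for the variance-reduction property of
#' [stratified_sample()].
#'
#' @inheritParams stratified_sample
#' @return Numeric vector of `M` iid uniform times on `[0, duration]`.
#' @export
uniform_sample <- function(duration, M) {
  stats::runif(M, 0, duration)
}

#' Monte Carlo estimate of the cumulative intensity
#'
#' \eqn{(T/M) \sum_m \lambda(\tau_m)}, an unbiased estimator of
#' \eqn{\int_0^T \lambda(t) dt} when `taus` contains one uniform draw per
#' stratum (or iid uniforms).
#'
#' @inheritParams linear_predictor
#' @param taus Sample times from [stratified_sample()] or [uniform_sample()].
#' @param u_cap Linear-predictor cap.
#' @return Scalar CIF estimate.
#' @export
cif_mc_estimate <- function(pop, params, b, taus, u_cap = 30) {
  u <- pmin(linear_predictor(pop, params, b, taus), u_cap)
  lam <- nonlinearity(params$link)$forward(u)
  pop$duration / length(taus) * sum(lam)
}

#' Monte Carlo objective (negative log-likelihood for a fixed sample)
#'
#' \eqn{f(w, \tau) = (T/M)\sum_m \lambda(\tau_m) - \sum_k \log \lambda(y_k)},
#' optionally plus a ridge penalty \eqn{\beta \lVert w \rVert^2} excluding the
#' intercept. The spike term is exact.
#'
#' @inheritParams cif_mc_estimate
#' @param post_spikes Target neuron spike times.
#' @param ridge Ridge penalty \eqn{\beta \ge 0}.
#' @return Scalar objective value (to be minimized).
#' @export
mc_objective <- function(pop, post_spikes, params, b, taus, ridge = 0,
                         u_cap = 30) {
  cif_mc_estimate(pop, params, b, taus, u_cap = u_cap) -
    spike_term(pop, post_spikes, params, b) +
    ridge * sum(params$W^2)
}

#' Control settings for the Monte Carlo fit
#'
#' @param M Number of strata; `NULL` selects one stratum per 10 ms of
#'   recording (`M = ceiling(100 * T)`).
#' @param n_iter Number of optimization iterations (default 2000).
#' @param learning_rate Adam step size (default 0.01).
#' @param ridge Ridge penalty on coupling weights (intercept excluded).
#' @param seed RNG seed; the per-iteration samples and the fixed validation
#'   sample derive from it, so identical settings give bit-identical fits.
#' @param val_M Size of the fixed validation sample used for the objective
#'   trace (common random numbers across iterations).
#' @param u_cap Linear-predictor cap.
#' @param init `"zeros"` or `"warm"` (requires `init_params` in [fit_mc()]).
#' @return A list of class `mc_control`.
#' @export
mc_control <- function(M = NULL, n_iter = 2000, learning_rate = 0.01,
                       ridge = 0, seed = 1, val_M = 2000, u_cap = 30,
                       init = c("zeros", "warm")) {
  init <- match.arg(init)
  stopifnot(is.null(M) || M >= 1, ridge >= 0, n_iter >= 1)
  structure(list(M = M, n_iter = n_iter, learning_rate = learning_rate,
                 ridge = ridge, seed = seed, val_M = val_M, u_cap = u_cap,
                 init = init),
            class = "mc_control")
}

# stochastic gradient of the MC objective at a stratified sample; exp link
# uses the precomputed spike-feature vector k_vec
mc_gradient <- function(pop, post_spikes, params, b, taus, ridge, u_cap,
                        k_vec = NULL) {
  Tdur <- pop$duration
  M <- length(taus)
  u <- pmin(linear_predictor(pop, params, b, taus), u_cap)
  nl <- nonlinearity(params$link)
  wts <- nl$derivative(u) * (Tdur / M)
  acc <- accumulate_features(pop, b, taus, wts)
  g <- c(acc$g0, as.vector(t(acc$G)))
  if (params$link == "exp" && !is.null(k_vec)) {
    g <- g - k_vec
  } else {
    uy <- linear_predictor(pop, params, b, post_spikes)
    sw <- nl$derivative(uy) / pmax(nl$forward(uy), 1e-300)
    sa <- accumulate_features(pop, b, post_spikes, sw)
    g <- g - c(sa$g0, as.vector(t(sa$G)))
  }
  g + 2 * ridge * c(0, pack_params(params)[-1])
}

# spike-feature vector k = (K, psi_1, ..., psi_N) for the target neuron
spike_feature_vector <- function(pop, post_spikes, b) {
  acc <- accumulate_features(pop, b, post_spikes,
                             rep(1, length(post_spikes)))
  c(length(post_spikes), as.vector(t(acc$G)))
}

#' Fit the point-process GLM by stratified Monte Carlo
#'
#' Minimizes the MC objective with Adam, drawing a fresh stratified sample at
#' every iteration. The spike term is always exact. The objective trace is
#' evaluated on a fixed held-out validation sample (common random numbers) so
#' that successive iterations are comparable.
#'
#' @param pop A [spike_population()].
#' @param target Index of the postsynaptic neuron.
#' @param b A `temporal_basis`.
#' @param control An [mc_control()].
#' @param init_params Optional [ppglm_params()] used as a warm start (the
#'   hybrid estimator passes the PA-c solution here).
#' @param link `"exp"` or `"softplus"`.
#' @return A `ppglm_fit` with the objective trace in `$meta$trace`.
#' @export
fit_mc <- function(pop, target, b, control = mc_control(),
                   init_params = NULL, link = "exp") {
  stopifnot(inherits(pop, "spike_population"), inherits(b, "temporal_basis"))
  post_spikes <- neuron_times(pop, target)
  Tdur <- pop$duration
  N <- pop$n_neurons
  J <- b$J
  M <- control$M %||% ceiling(100 * Tdur)

  if (!is.null(init_params)) {
    theta <- pack_params(init_params)
    estimator <- if (identical(attr(init_params, "from"), "pa_c")) "hybrid" else "MC"
  } else {
    theta <- numeric(N * J + 1)
    estimator <- "MC"
  }

  set.seed(control$seed)
  val_taus <- stratified_sample(Tdur, control$val_M)
  k_vec <- if (link == "exp") spike_feature_vector(pop, post_spikes, b) else NULL

  # Adam state
  m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(control$n_iter)

  for (it in seq_len(control$n_iter)) {
    params <- unpack_params(theta, N, J, link)
    taus <- stratified_sample(Tdur, M)
    g <- mc_gradient(pop, post_spikes, params, b, taus,
                     ridge = control$ridge, u_cap = control$u_cap,
                     k_vec = k_vec)
    m1 <- b1 * m1 + (1 - b1) * g
    m2 <- b2 * m2 + (1 - b2) * g^2
    step <- control$learning_rate * (m1 / (1 - b1^it)) /
      (sqrt(m2 / (1 - b2^it)) + eps)
    theta <- theta - step
    params <- unpack_params(theta, N, J, link)
    trace[it] <- mc_objective(pop, post_spikes, params, b, val_taus,
                              ridge = control$ridge, u_cap = control$u_cap)
    if (!is.finite(trace[it]) || trace[it] > 1e10) {
      stop(sprintf("MC optimization diverged at iteration %d (objective %g).",
                   it, trace[it]), call. = FALSE)
    }
  }

  params <- unpack_params(theta, N, J, link)
  fit_from_params(
    params, b, estimator, target = target,
    meta = list(
      seed = control$seed, n_iter = control$n_iter,
      M = M, ridge = control$ridge,
      final_objective = trace[length(trace)],
      trace = tibble::tibble(iteration = seq_len(control$n_iter),
                             objective = trace)
    )
  )
}

#' Normalized stochastic-gradient error along an optimization path
#'
#' For each parameter checkpoint, estimates
#' \eqn{E\lVert \nabla - \tilde\nabla \rVert^2 / \lVert \nabla_1 \rVert^2}:
#' the expected squared error of the stochastic gradient about the exact
#' continuous-time gradient, normalized by the squared norm of the exact
#' gradient at the first checkpoint.
#'
#' @param pop A [spike_population()].
#' @param target Target neuron index.
#' @param checkpoints List of [ppglm_params()] (e.g. early and late points of
#'   an optimizer trace).
#' @param b A `temporal_basis`.
#' @param M Stratified sample size per stochastic gradient.
#' @param n_resamples Monte Carlo resamples per checkpoint (>= 100
#'   recommended).
#' @param exact_dt Midpoint-rule resolution for the exact gradient (seconds).
#' @param seed RNG seed.
#' @return A tibble with columns `checkpoint`, `error`.
#' @export
gradient_error_mc <- function(pop, target, checkpoints, b, M,
                              n_resamples = 100, exact_dt = 2e-5, seed = 1) {
  post_spikes <- neuron_times(pop, target)
  k_vec <- spike_feature_vector(pop, post_spikes, b)
  Tdur <- pop$duration
  g_exact <- lapply(checkpoints, function(p) {
    exact_gradient(pop, post_spikes, p, b, dt = exact_dt)
  })
  norm1 <- sum(g_exact[[1]]^2)
  if (norm1 == 0) stop("zero initial gradient: error undefined.", call. = FALSE)
  set.seed(seed)
  err <- vapply(seq_along(checkpoints), function(i) {
    p <- checkpoints[[i]]
    se <- vapply(seq_len(n_resamples), function(r) {
      taus <- stratified_sample(Tdur, M)
      g <- mc_gradient(pop, post_spikes, p, b, taus, ridge = 0,
                       u_cap = 30, k_vec = k_vec)
      sum((g - g_exact[[i]])^2)
    }, numeric(1))
    mean(se)
  }, numeric(1)) / norm1
  tibble::tibble(checkpoint = seq_along(checkpoints), error = err)
}

# first iteration at which an objective trace reaches a level (Inf if never)
iterations_to_reach <- function(trace, level) {
  hit <- which(trace <= level)
  if (length(hit)) hit[1] else Inf
}
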