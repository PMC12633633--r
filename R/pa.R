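#' Quadratic approximation to the link nonlinearity
#'
#' Least-squares fit of a second-order polynomial
#' \eqn{a_2 x^2 + a_1 x + a_0} to \eqn{\Phi(x)} on a dense uniform grid over
#' `[x0, x1]` (10^4 points). With this surrogate the CIF becomes quadratic in
#' the weights and the likelihood admits a closed-form maximizer.
#'
#' @param link `"exp"`, or a function to approximate.
#' @param x0,x1 Approximation range on the linear-predictor scale, `x0 < x1`.
#' @param n_grid Grid size.
#' @return An object of class `poly_approx` with fields `a0`, `a1`, `a2`,
#'   `range`, and `residual` (max-abs fit error over the range).
#' @export
fit_poly <- function(link = "exp", x0, x1, n_grid = 1e4) {
  if (x0 >= x1) stop("`x0` must be below `x1`.", call. = FALSE)
  f <- if (is.function(link)) link else nonlinearity(link)$forward
  x <- seq(x0, x1, length.out = n_grid)
  X <- cbind(1, x, x^2)
  y <- f(x)
  coefs <- qr.coef(qr(X), y)
  res <- max(abs(X %*% coefs - y))
  structure(
    list(a0 = unname(coefs[1]), a1 = unname(coefs[2]), a2 = unname(coefs[3]),
         range = c(x0, x1), residual = res,
         link = if (is.function(link)) "custom" else link),
    class = "poly_approx"
  )
}

#' @export
print.poly_approx <- function(x, ...) {
  cat(sprintf("<poly_approx> %.4g x^2 + %.4g x + %.4g on [%.3g, %.3g], max resid %.3g\n",
              x$a2, x$a1, x$a0, x$range[1], x$range[2], x$residual))
  invisible(x)
}

#' Select the approximation range for the nonlinearity
#'
#' Two modes. `"mean_centered"` (for recorded data): the range covers
#' `width_hz` Hz centred on the target's mean rate \eqn{\bar r = K/T}, mapped
#' through the inverse link — `[log(max(r - w/2, floor)), log(r + w/2)]` for
#' the exp link. `"percentile_sim"` (for simulations with known rates): the
#' 2.5th–97.5th percentiles of the supplied rates, mapped through the inverse
#' link; a degenerate range is widened to a documented minimum width of 0.1.
#'
#' @param pop A [spike_population()] (mean-centered mode).
#' @param target Target neuron index.
#' @param mode `"mean_centered"` or `"percentile_sim"`.
#' @param width_hz Range width in Hz (mean-centered mode; 3-7 Hz typical).
#' @param rates Rate samples in Hz (percentile mode).
#' @param link Link name.
#' @param floor_hz Lower rate floor (default 0.01 Hz).
#' @return Numeric `c(x0, x1)` on the linear-predictor scale.
#' @export
select_range <- function(pop = NULL, target = NULL,
                         mode = c("mean_centered", "percentile_sim"),
                         width_hz = 5, rates = NULL, link = "exp",
                         floor_hz = 0.01) {
  mode <- match.arg(mode)
  inv <- nonlinearity(link)$inverse
  if (mode == "mean_centered") {
    k <- length(neuron_times(pop, target))
    if (k == 0) stop("target has no spikes; mean rate undefined.", call. = FALSE)
    rbar <- k / pop$duration
    x <- c(inv(max(rbar - width_hz / 2, floor_hz)), inv(rbar + width_hz / 2))
  } else {
    if (is.null(rates)) stop("percentile mode needs `rates`.", call. = FALSE)
    q <- stats::quantile(rates, c(0.025, 0.975), names = FALSE)
    x <- inv(pmax(q, floor_hz))
  }
  if (diff(x) < 0.1) x <- mean(x) + c(-0.05, 0.05)  # degenerate-range rule
  x
}

#' Sufficient statistics of the polynomial-approximate likelihood
#'
#' Computes the three summaries from which the closed-form solve proceeds:
#' the spike-feature vector `k` (target spike count in the intercept slot,
#' then \eqn{\psi_n = \sum_k \sum_{t_s} \phi(y_k - t_s)} per presynaptic
#' neuron), the linear-integral vector `m` (`T` in the intercept slot, then
#' \eqn{S_n \bar\phi}), and the symmetric pair-integral matrix `M` whose
#' `(n, n')` block accumulates [pairwise_integrals()] over all spike pairs
#' within the interaction window (same-spike pairs once on the diagonal;
#' opposite orderings by transpose symmetry). Pairs are enumerated by a
#' two-pointer sweep over the time-sorted spikes, so cost is linear in the
#' number of in-window pairs. Right-edge truncation at `T` is ignored, as in
#' the defining integrals.
#'
#' @param pop A [spike_population()].
#' @param target Target neuron index (for `k`).
#' @param b A `temporal_basis`.
#' @return An object of class `pp_suffstats` with fields `k`, `m`, `M`, `K`,
#'   `T`, `n_neurons`, `J`.
#' @export
sufficient_stats <- function(pop, target, b) {
  stopifnot(inherits(pop, "spike_population"), inherits(b, "temporal_basis"))
  N <- pop$n_neurons
  J <- b$J
  D <- N * J + 1L
  Tdur <- pop$duration
  post_spikes <- neuron_times(pop, target)
  S_n <- tabulate(pop$spikes$neuron, nbins = N)
  phibar <- single_integrals(b)

  k <- spike_feature_vector(pop, post_spikes, b)
  m <- c(Tdur, as.vector(t(outer(S_n, phibar))))

  times <- pop$times_all
  neurons <- pop$neurons_all
  S <- length(times)

  # ordered pairs (later i, earlier i') with 0 <= t_i - t_i' <= H, i' < i
  lo <- findInterval(times - b$H, times, left.open = TRUE)
  counts <- pmax(seq_len(S) - 1L - lo, 0L)
  pidx <- rep.int(seq_len(S), counts)
  sidx <- sequence(counts) + rep.int(lo, counts)
  deltas <- times[pidx] - times[sidx]

  # slot of weight (n, j) in the packed vector: 1 + (n-1)*J + j (slot 1 is
  # the intercept)
  slot0 <- function(n) 1L + (n - 1L) * J
  Mmat <- matrix(0, D, D)

  if (length(deltas)) {
    n_late <- neurons[pidx]
    n_early <- neurons[sidx]
    if (gl_closed_form_ok(b)) {
      PV <- gl_pair_values(b, deltas)  # [pair, j, jp] = P(delta)[j, jp]
    } else {
      PV <- array(0, c(length(deltas), J, J))
      for (i in seq_along(deltas)) PV[i, , ] <- pairwise_integrals(b, deltas[i])
    }
    # accumulate earlier-block entries: block (n_early, n_late)[a, b'] += P[a, b']
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (a in seq_len(J)) {
      for (bb in seq_len(J)) {
        rows <- c(rows, slot0(n_early) + a)
        cols <- c(cols, slot0(n_late) + bb)
        vals <- c(vals, PV[, a, bb])
      }
    }
    Sp <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(D, D))
    Mpairs <- as.matrix(Sp)
    Mmat <- Mpairs + t(Mpairs)
  }

  # same-spike diagonal pairs: S_n copies of P(0) per neuron, counted once
  P0 <- pairwise_integrals(b, 0)
  for (n in seq_len(N)) {
    if (S_n[n] == 0) next
    idx <- (slot0(n) + 1L):(slot0(n) + J)
    Mmat[idx, idx] <- Mmat[idx, idx] + S_n[n] * P0
  }

  # intercept row/column and corner
  Mmat[1, 1] <- Tdur
  Mmat[1, 2:D] <- m[-1]
  Mmat[2:D, 1] <- m[-1]

  structure(
    list(k = k, m = m, M = Mmat, K = length(post_spikes), T = Tdur,
         n_neurons = N, J = J, target = target),
    class = "pp_suffstats"
  )
}

#' Closed-form MAP solve of the polynomial-approximate likelihood
#'
#' Maximizes \eqn{w^\top k - a_1 m^\top w - a_2 w^\top M w -
#' \beta \lVert w \rVert^2} (ridge excludes the intercept):
#' \eqn{w^* = (2 a_2 M + 2\beta I)^{-1}(k - a_1 m)} by a symmetric
#' positive-definite solve.
#'
#' @param stats A [sufficient_stats()] object.
#' @param pa A [fit_poly()] object.
#' @param ridge Ridge penalty \eqn{\beta \ge 0}.
#' @return A [ppglm_params()].
#' @export
solve_map <- function(stats, pa, ridge = 0) {
  stopifnot(inherits(stats, "pp_suffstats"), inherits(pa, "poly_approx"))
  if (pa$a2 <= 0 && ridge <= 0) {
    stop("need a2 > 0 or ridge > 0 for a strictly concave objective.",
         call. = FALSE)
  }
  D <- length(stats$k)
  A <- 2 * pa$a2 * stats$M
  diag(A)[-1] <- diag(A)[-1] + 2 * ridge
  rhs <- stats$k - pa$a1 * stats$m
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    if (ridge <= 0) {
      stop("sufficient-statistic system is rank deficient; supply ridge > 0.",
           call. = FALSE)
    }
    theta <- solve(A, rhs)
  } else {
    theta <- backsolve(ch, forwardsolve(t(ch), rhs))
  }
  unpack_params(as.numeric(theta), stats$n_neurons, stats$J, link = "exp")
}

#' Fit the continuous polynomial-approximate estimator (PA-c)
#'
#' Composes [select_range()] (or a supplied range), [fit_poly()],
#' [sufficient_stats()] and [solve_map()]. The sufficient statistics are
#' cached on the fit so re-solving at a different ridge via [refit_ridge()]
#' costs only a linear solve. Exp link only.
#'
#' @param pop A [spike_population()].
#' @param target Target neuron index.
#' @param b A `temporal_basis`.
#' @param range Either a numeric `c(x0, x1)` on the linear-predictor scale or
#'   a list of arguments for [select_range()] (e.g.
#'   `list(mode = "mean_centered", width_hz = 5)`).
#' @param ridge Ridge penalty (the screening workflow default is 1000;
#'   simulation default is 0).
#' @param stats Optional precomputed [sufficient_stats()].
#' @param link Link; must be `"exp"` (the closed-form PA path is derived for
#'   the canonical link).
#' @return A `ppglm_fit` with `$meta$stats` and `$meta$poly`.
#' @export
fit_pa_c <- function(pop, target, b,
                     range = list(mode = "mean_centered", width_hz = 5),
                     ridge = 0, stats = NULL, link = "exp") {
  if (link != "exp") {
    stop("the PA estimator supports the exp link only.", call. = FALSE)
  }
  rng <- if (is.numeric(range)) {
    range
  } else {
    do.call(select_range, c(list(pop = pop, target = target, link = link), range))
  }
  pa <- fit_poly("exp", rng[1], rng[2])
  if (is.null(stats)) stats <- sufficient_stats(pop, target, b)
  params <- solve_map(stats, pa, ridge = ridge)
  attr(params, "from") <- "pa_c"
  fit_from_params(
    params, b, "PA-c", target = target,
    meta = list(stats = stats, poly = pa, ridge = ridge, range = rng,
                seed = NA_integer_, n_iter = 1L,
                final_objective = pa_objective(stats, pa, params, ridge))
  )
}

# the (negated) quadratic surrogate objective, for reporting
pa_objective <- function(stats, pa, params, ridge = 0) {
  w <- pack_params(params)
  -(sum(w * stats$k) - pa$a1 * sum(stats$m * w) -
      pa$a2 * as.numeric(t(w) %*% stats$M %*% w) -
      ridge * sum(w[-1]^2)) + stats$T * pa$a0
}

#' Re-solve a PA-c fit at a different ridge
#'
#' Reuses the cached sufficient statistics bit-exactly.
#'
#' @param fit A PA-c `ppglm_fit`.
#' @param ridge New ridge penalty.
#' @return A new `ppglm_fit`.
#' @export
refit_ridge <- function(fit, ridge) {
  stopifnot(inherits(fit, "ppglm_fit"), !is.null(fit$meta$stats))
  params <- solve_map(fit$meta$stats, fit$meta$poly, ridge = ridge)
  attr(params, "from") <- "pa_c"
  fit_from_params(params, fit$basis, fit$estimator, target = fit$target,
                  meta = utils::modifyList(fit$meta, list(ridge = ridge)))
}

#' Fit the hybrid estimator (PA-c warm start, MC finetuning)
#'
#' Runs PA-c for a closed-form initial estimate, then refines it with the
#' stratified Monte Carlo fit, trading the PA approximation error for MC
#' iterations from a good starting point.
#'
#' @inheritParams fit_pa_c
#' @param control An [mc_control()] for the MC stage.
#' @param ridge_pa Ridge used in the PA-c stage.
#' @return A `ppglm_fit` with estimator tag `"hybrid"`.
#' @export
fit_hybrid <- function(pop, target, b,
                       range = list(mode = "mean_centered", width_hz = 5),
                       ridge_pa = 0, control = mc_control()) {
  pa_fit <- fit_pa_c(pop, target, b, range = range, ridge = ridge_pa)
  init <- fit_params(pa_fit)
  attr(init, "from") <- "pa_c"
  out <- fit_mc(pop, target, b, control = control, init_params = init)
  out$meta$pa_start <- pa_fit
  out
}

#' Cross-validated approximation-range width
#'
#' Scores a grid of mean-centred range widths by held-out log-likelihood on a
#' time split: PA-c is fitted on the first 80% of the recording and scored on
#' the last 20% with an MC-estimated log-likelihood (fixed stratified sample).
#'
#' @inheritParams fit_pa_c
#' @param widths Candidate widths in Hz.
#' @param frac_train Fraction of the recording used for fitting.
#' @param seed Seed for the scoring sample.
#' @return A tibble with columns `width_hz`, `heldout_loglik`, sorted by
#'   width; the attribute `"best"` holds the selected width.
#' @export
select_range_cv <- function(pop, target, b, widths = 3:7, ridge = 0,
                            frac_train = 0.8, seed = 1) {
  t_split <- frac_train * pop$duration
  train_df <- data.frame(
    neuron_id = pop$labels[pop$spikes$neuron],
    time = pop$spikes$time
  )
  train <- spike_population(train_df[train_df$time <= t_split, ],
                            duration = t_split)
  stats <- sufficient_stats(train, target, b)
  # held-out score: exact spike term minus stratified-MC CIF on (t_split, T]
  post_all <- neuron_times(pop, target)
  test_spikes <- post_all[post_all > t_split + b$H]
  set.seed(seed)
  M_test <- max(100L, ceiling(100 * (pop$duration - t_split)))
  taus <- t_split + stratified_sample(pop$duration - t_split, M_test)
  scores <- vapply(widths, function(w) {
    fit <- fit_pa_c(train, target, b,
                    range = list(mode = "mean_centered", width_hz = w),
                    ridge = ridge, stats = stats)
    params <- fit_params(fit)
    u <- pmin(linear_predictor(pop, params, b, taus), 30)
    cif <- (pop$duration - t_split) / M_test * sum(exp(u))
    spike_term(pop, test_spikes, params, b) - cif
  }, numeric(1))
  out <- tibble::tibble(width_hz = widths, heldout_loglik = scores)
  attr(out, "best") <- widths[which.max(scores)]
  out
}
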