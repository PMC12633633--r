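#' Model parameters for a point-process GLM
#'
#' One postsynaptic target's parameters: a `J`-vector of basis weights per
#' presynaptic neuron plus an intercept `w0` (log baseline rate under the exp
#' link), `N * J + 1` free parameters in total.
#'
#' @param W An `N x J` matrix of coupling weights.
#' @param w0 Intercept, in log(events/second) for the exp link.
#' @param link `"exp"` (canonical) or `"softplus"`.
#' @return An object of class `ppglm_params`.
#' @export
ppglm_params <- function(W, w0 = 0, link = c("exp", "softplus")) {
  link <- match.arg(link)
  W <- as.matrix(W)
  structure(list(W = W, w0 = w0, link = link,
                 n_neurons = nrow(W), J = ncol(W)),
            class = "ppglm_params")
}

# weight-vector layout: slot 1 = intercept, then (n-1)*J + j + 1
pack_params <- function(params) {
  c(params$w0, as.vector(t(params$W)))
}

unpack_params <- function(theta, n_neurons, J, link = "exp") {
  ppglm_params(matrix(theta[-1], n_neurons, J, byrow = TRUE),
               w0 = theta[1], link = link)
}

#' Link nonlinearities
#'
#' Returns the rate nonlinearity \eqn{\Phi} (monotone increasing, convex,
#' nonnegative) with its derivative and inverse.
#'
#' @param kind `"exp"` or `"softplus"`.
#' @return List with functions `forward`, `derivative`, `inverse` and the
#'   `kind` tag.
#' @export
nonlinearity <- function(kind = c("exp", "softplus")) {
  kind <- match.arg(kind)
  if (kind == "exp") {
    list(kind = "exp", forward = exp, derivative = exp, inverse = log)
  } else {
    sp <- function(u) ifelse(u > 30, u, log1p(exp(pmin(u, 30))))
    list(
      kind = "softplus",
      forward = sp,
      derivative = function(u) 1 / (1 + exp(-u)),
      inverse = function(r) ifelse(r > 30, r, log(expm1(pmax(r, 1e-12))))
    )
  }
}

# For each query time t, indices of spikes with t - H <= t_s < t (half-open at
# the right: a spike never drives the rate at its own time). Returns parallel
# vectors over all (query, in-window spike) pairs.
query_window_pairs <- function(pop, queries, H) {
  times <- pop$times_all
  hi <- findInterval(queries, times, left.open = TRUE)   # t_s <  t
  lo <- findInterval(queries - H, times, left.open = TRUE) # t_s < t - H
  counts <- hi - lo
  qidx <- rep.int(seq_along(queries), counts)
  sidx <- sequence(counts) + rep.int(lo, counts)
  list(qidx = qidx, sidx = sidx,
       lag = queries[qidx] - times[sidx],
       neuron = pop$neurons_all[sidx],
       counts = counts)
}

#' Linear predictor of the point-process GLM
#'
#' \eqn{u(t) = w_0 + \sum_{x_s \in X(t,H)} w_{n_s}^\top \phi(t - t_s)}, where
#' the history window `X(t, H)` contains spikes with \eqn{t-H \le t_s < t}.
#' Vectorized over `t`; the window contents are located by binary search so
#' cost is proportional to window occupancy.
#'
#' @param pop A [spike_population()].
#' @param params A [ppglm_params()].
#' @param b A `temporal_basis`.
#' @param t Evaluation times in seconds (vectorized).
#' @return Numeric vector `u(t)`.
#' @export
linear_predictor <- function(pop, params, b, t) {
  pr <- query_window_pairs(pop, t, b$H)
  u <- rep(params$w0, length(t))
  if (length(pr$qidx)) {
    Phi <- eval_basis(b, pr$lag)
    contrib <- rowSums(Phi * params$W[pr$neuron, , drop = FALSE])
    add <- rowsum(contrib, pr$qidx, reorder = FALSE)
    u[as.integer(rownames(add))] <- u[as.integer(rownames(add))] + add[, 1]
  }
  u
}

#' Conditional intensity (firing rate)
#'
#' \eqn{\lambda(t) = \Phi(u(t))} in events/second. The linear predictor is
#' capped at `u_cap` before the exp link to guard overflow; a warning is
#' issued when the cap is active.
#'
#' @inheritParams linear_predictor
#' @param u_cap Cap on the linear predictor (default 30).
#' @return Nonnegative rates, same length as `t`.
#' @export
pp_rate <- function(pop, params, b, t, u_cap = 30) {
  u <- linear_predictor(pop, params, b, t)
  if (any(u > u_cap)) {
    warning(sprintf("linear predictor capped at %g for %d time point(s).",
                    u_cap, sum(u > u_cap)), call. = FALSE)
    u <- pmin(u, u_cap)
  }
  nonlinearity(params$link)$forward(u)
}

#' Exact spike term of the log-likelihood
#'
#' \eqn{\sum_k \log \lambda(y_k)} over the target neuron's spike times. No
#' approximation is involved; under the exp link this is
#' \eqn{\sum_k u(y_k)}.
#'
#' @inheritParams linear_predictor
#' @param post_spikes Spike times of the target neuron (seconds).
#' @return Scalar log spike term.
#' @export
spike_term <- function(pop, post_spikes, params, b) {
  if (!length(post_spikes)) return(0)
  u <- linear_predictor(pop, params, b, post_spikes)
  if (params$link == "exp") return(sum(u))
  lam <- nonlinearity("softplus")$forward(u)
  if (any(lam <= 0)) {
    stop("zero rate at an observed spike: degenerate fit.", call. = FALSE)
  }
  sum(log(lam))
}

#' High-accuracy quadrature of the cumulative intensity
#'
#' Reference integrator for \eqn{\int_0^T \lambda(t) dt}: the recording is
#' subdivided at every spike time and every spike time plus `H` (the kinks of
#' the intensity), and each smooth segment is integrated adaptively. Intended
#' for small instances and as a test oracle.
#'
#' @inheritParams linear_predictor
#' @param tol Absolute tolerance on the integral.
#' @return The CIF value (expected event count over `[0, T]`).
#' @export
cif_quadrature <- function(pop, params, b, tol = 1e-8) {
  Tdur <- pop$duration
  kinks <- sort(unique(c(0, Tdur,
                         pop$times_all, pop$times_all + b$H)))
  kinks <- kinks[kinks >= 0 & kinks <= Tdur]
  phi <- nonlinearity(params$link)$forward
  f <- function(t) phi(linear_predictor(pop, params, b, t))
  n_seg <- length(kinks) - 1
  total <- 0
  for (i in seq_len(n_seg)) {
    lo <- kinks[i]; hi <- kinks[i + 1]
    if (hi - lo < 1e-15) next
    res <- tryCatch(
      stats::integrate(f, lo, hi, rel.tol = 1e-10,
                       abs.tol = tol / n_seg, subdivisions = 200L),
      error = function(e) {
        stop(sprintf("CIF quadrature failed on [%g, %g]: %s",
                     lo, hi, conditionMessage(e)), call. = FALSE)
      })
    total <- total + res$value
  }
  total
}

# Weighted feature accumulation: given per-query weights v(t_q), returns the
# gradient-shaped pair (g0 = sum v, G[n, j] = sum over pairs v[q] phi_j(lag)).
# This is the common kernel of the MC gradient, the exact fine-grid gradient
# and the psi (spike-feature) vector.
accumulate_features <- function(pop, b, queries, wts) {
  pr <- query_window_pairs(pop, queries, b$H)
  G <- matrix(0, pop$n_neurons, b$J)
  if (length(pr$qidx)) {
    Phi <- eval_basis(b, pr$lag) * wts[pr$qidx]
    agg <- rowsum(Phi, pr$neuron, reorder = FALSE)
    G[as.integer(rownames(agg)), ] <- agg
  }
  list(g0 = sum(wts), G = G)
}

# Exact gradient of the continuous negative log-likelihood
#   f(w) = int lambda - sum_k log lambda(y_k)
# CIF term by midpoint rule at resolution dt (the integrand has kinks at every
# spike and spike+H; midpoint error is O(dt^2) per segment and far below the
# stochastic errors this gradient is used to measure). Exp link only.
exact_gradient <- function(pop, post_spikes, params, b, dt = 2e-5,
                           u_cap = 30, chunk = 250000L) {
  stopifnot(params$link == "exp")
  Tdur <- pop$duration
  n_grid <- ceiling(Tdur / dt)
  g0 <- 0
  G <- matrix(0, pop$n_neurons, b$J)
  start <- 1L
  while (start <= n_grid) {
    end <- min(start + chunk - 1L, n_grid)
    mids <- (seq(start, end) - 0.5) * dt
    mids <- mids[mids < Tdur]
    lam <- exp(pmin(linear_predictor(pop, params, b, mids), u_cap)) * dt
    acc <- accumulate_features(pop, b, mids, lam)
    g0 <- g0 + acc$g0
    G <- G + acc$G
    start <- end + 1L
  }
  spike_acc <- accumulate_features(pop, b, post_spikes,
                                   rep(1, length(post_spikes)))
  c(g0 - length(post_spikes), as.vector(t(G - spike_acc$G)))
}

#' Deterministic continuous-likelihood reference fit
#'
#' Maximizes the continuous log-likelihood directly: the spike term is exact
#' (computed from true spike times, never binned) and the CIF integral is
#' evaluated by a midpoint rule at resolution `dt`, giving a smooth, strictly
#' convex objective solved by damped Newton iterations. Deterministic;
#' intended as a converged reference on small instances — e.g. as the
#' continuous limit that binned fits approach as the bin size shrinks — not
#' as a scalable estimator (cost grows with `T/dt`).
#'
#' @inheritParams linear_predictor
#' @param target Target neuron index.
#' @param dt Midpoint-rule resolution in seconds (default 0.02 ms).
#' @param ridge Ridge penalty (intercept excluded).
#' @param max_iter Newton iteration cap.
#' @param tol Max-abs gradient convergence threshold.
#' @param chunk Grid points per chunk.
#' @return A `ppglm_fit` (metadata variant `"continuous-ref"`).
#' @export
fit_continuous_ref <- function(pop, target, b, dt = 2e-5, ridge = 0,
                               max_iter = 50, tol = 1e-8, chunk = 200000L) {
  post_spikes <- neuron_times(pop, target)
  Tdur <- pop$duration
  N <- pop$n_neurons
  J <- b$J
  D <- N * J + 1L
  k_vec <- spike_feature_vector(pop, post_spikes, b)
  n_grid <- ceiling(Tdur / dt)

  # exact-lag feature rows for a block of grid midpoints
  grid_rows <- function(lo_i, hi_i) {
    mids <- (seq(lo_i, hi_i) - 0.5) * dt
    mids <- mids[mids < Tdur]
    pr <- query_window_pairs(pop, mids, b$H)
    X <- matrix(0, length(mids), D)
    X[, 1] <- 1
    if (length(pr$qidx)) {
      Phi <- eval_basis(b, pr$lag)
      for (j in seq_len(J)) {
        col <- 1L + (pr$neuron - 1L) * J + j
        key <- (pr$qidx - 1) * D + col
        agg <- rowsum(Phi[, j], key, reorder = FALSE)
        kk <- as.numeric(rownames(agg))
        X[cbind((kk - 1) %/% D + 1, (kk - 1) %% D + 1)] <- agg[, 1]
      }
    }
    X
  }

  theta <- numeric(D)
  theta[1] <- log(max(length(post_spikes) / Tdur, 1e-6))
  fn_g_h <- function(theta, need_h = TRUE) {
    f <- 0; g <- numeric(D)
    Hm <- if (need_h) matrix(0, D, D) else NULL
    start <- 1L
    while (start <= n_grid) {
      end <- min(start + chunk - 1L, n_grid)
      X <- grid_rows(start, end)
      mu <- exp(pmin(drop(X %*% theta), 30)) * dt
      f <- f + sum(mu)
      g <- g + drop(crossprod(X, mu))
      if (need_h) Hm <- Hm + crossprod(X * sqrt(mu))
      start <- end + 1L
    }
    f <- f - sum(theta * k_vec) + ridge * sum(theta[-1]^2)
    g <- g - k_vec + 2 * ridge * c(0, theta[-1])
    if (need_h) diag(Hm)[-1] <- diag(Hm)[-1] + 2 * ridge
    list(f = f, g = g, H = Hm)
  }

  cur <- fn_g_h(theta)
  gscale <- max(1, max(abs(k_vec)))
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$g)) < tol * gscale) break
    lam <- 1e-10 * mean(diag(cur$H))
    step <- NULL
    while (is.null(step)) {
      step <- tryCatch(solve(cur$H + lam * diag(D), cur$g),
                       error = function(e) NULL)
      lam <- max(lam * 100, 1e-8 * mean(diag(cur$H)))
    }
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      nxt <- fn_g_h(cand)
      # accept any non-increase up to additive rounding of the chunked sums
      if (is.finite(nxt$f) && nxt$f <= cur$f + 1e-9 * max(1, abs(cur$f))) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    theta <- theta - alpha * step
    cur <- nxt
  }
  params <- unpack_params(theta, N, J)
  fit_from_params(params, b, "MC", target = target,
                  meta = list(variant = "continuous-ref", dt = dt,
                              seed = NA_integer_, n_iter = it,
                              final_objective = cur$f,
                              grad_norm = max(abs(cur$g))))
}
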