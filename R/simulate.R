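#' Generate ground-truth coupling filters
#'
#' Each filter is a random mixture of 100 log-stretched raised cosine bumps on
#' `[0, window]`, with mixture coefficients drawn at a scale that decays with
#' bump index so filters have realistic fast-rise / slow-decay shapes. Each
#' filter is rescaled to a random sup-norm drawn from `amp_range` with random
#' sign (amplitudes are bounded well below 3 to keep simulated rates stable),
#' so the ground truth lies outside the span of any small fitting basis.
#'
#' @param n_filters Number of filters.
#' @param window Support `[0, H]` in seconds.
#' @param seed RNG seed (filters are deterministic given the seed).
#' @param n_rc Number of raised cosine bumps (default 100).
#' @param amp_range Range for the per-filter sup-norm (default `c(0.5, 2)`).
#' @param excitatory_prob Probability a filter is positive-going.
#' @return An object of class `truth_filters` holding the RC basis and the
#'   coefficient matrix.
#' @export
make_filters <- function(n_filters, window = 0.005, seed = 1, n_rc = 100,
                         amp_range = c(0.5, 2), excitatory_prob = 0.5) {
  set.seed(seed)
  rc <- rc_basis(n_rc, window = window)
  # unimodal gamma-like coefficient profile over bump index, peaking at a
  # random monosynaptic-range latency, plus smooth low-amplitude variability:
  # fast rise, slow decay, one dominant feature per filter
  kern <- stats::dnorm(seq(-36, 36), sd = 12)
  kern <- kern / sum(kern)
  idx <- seq_len(n_rc) - 1
  coef <- t(vapply(seq_len(n_filters), function(i) {
    m <- stats::runif(1, 0.25 * n_rc, 0.60 * n_rc)
    s <- stats::runif(1, 0.10 * n_rc, 0.22 * n_rc)
    prof <- exp(-(idx - m)^2 / (2 * s^2))
    noise <- stats::convolve(stats::rnorm(n_rc + 72), rev(kern),
                             type = "filter")[seq_len(n_rc)]
    prof + 0.15 * noise
  }, numeric(n_rc)))
  # rescale to target amplitude with random sign
  grid <- seq(0, window, length.out = 512)
  Phi <- eval_basis(rc, grid)
  sup <- apply(abs(coef %*% t(Phi)), 1, max)
  amp <- stats::runif(n_filters, amp_range[1], amp_range[2])
  sgn <- ifelse(stats::runif(n_filters) < excitatory_prob, 1, -1)
  keep <- sup > 0
  coef[keep, ] <- coef[keep, ] * (amp[keep] * sgn[keep] / sup[keep])
  structure(list(rc = rc, coef = coef, window = window, seed = seed),
            class = "truth_filters")
}

# evaluate truth filters: rows = lags, cols = filters
eval_filters <- function(tf, lags) {
  eval_basis(tf$rc, lags) %*% t(tf$coef)
}

#' @export
print.truth_filters <- function(x, ...) {
  cat(sprintf("<truth_filters> %d filters on [0, %g ms], %d RC bumps\n",
              nrow(x$coef), 1000 * x$window, x$rc$J))
  invisible(x)
}

# sup of the positive part of each filter (for thinning bounds)
filter_pos_sup <- function(tf, n_grid = 1024) {
  grid <- seq(0, tf$window, length.out = n_grid)
  apply(eval_filters(tf, grid), 2, function(v) max(c(v, 0)))
}

#' Simulate an all-to-one coupled GLM
#'
#' `n_pre` presynaptic neurons fire as independent homogeneous Poisson
#' processes; one postsynaptic neuron (index `n_pre + 1`) fires as an
#' inhomogeneous Poisson process whose log-rate is the baseline plus the sum
#' of ground-truth coupling filters over presynaptic spikes in the history
#' window. The postsynaptic neuron has no self-coupling, so its intensity is a
#' deterministic function of the presynaptic spikes and can be sampled
#' exactly by thinning: the recording is partitioned at filter onset/offset
#' times, a valid constant upper bound on the rate is computed per segment
#' from the positive parts of the active filters, candidate events are drawn
#' from the bounding homogeneous process, and each is accepted with
#' probability rate/bound. A fine-grid Bernoulli sampler is kept as a
#' cross-check (`method = "grid"`).
#'
#' @param n_pre Number of presynaptic neurons (default 7, giving an 8-neuron
#'   population).
#' @param duration Recording length `T` in seconds.
#' @param post_baseline_hz Postsynaptic baseline rate (default 3 Hz).
#' @param pre_rate_hz Presynaptic rates (default 5 Hz, recycled).
#' @param filters Optional [make_filters()] object with `n_pre` filters.
#' @param seed RNG seed; the full output is deterministic given it.
#' @param window Filter support `H` in seconds.
#' @param method `"thinning"` (exact) or `"grid"` (fine-grid Bernoulli
#'   oracle).
#' @param grid_dt Grid resolution for `method = "grid"`.
#' @param rate_cap Abort if the realized rate exceeds this (unstable
#'   filters).
#' @return A list with `population` (a [spike_population()], target neuron
#'   last), `truth` (filters, baselines, target index) — class
#'   `ppglm_simulation`.
#' @export
simulate_all_to_one <- function(n_pre = 7, duration = 100,
                                post_baseline_hz = 3, pre_rate_hz = 5,
                                filters = NULL, seed = 1, window = 0.005,
                                method = c("thinning", "grid"),
                                grid_dt = 1e-5, rate_cap = 1e4) {
  method <- match.arg(method)
  set.seed(seed)
  rates <- rep_len(pre_rate_hz, n_pre)
  pre <- lapply(seq_len(n_pre), function(n) {
    k <- stats::rpois(1, rates[n] * duration)
    sort(stats::runif(k, 0, duration))
  })
  if (is.null(filters)) {
    filters <- make_filters(n_pre, window = window,
                            seed = seed + 104729L)
  }
  stopifnot(nrow(filters$coef) == n_pre)
  set.seed(seed + 15485863L)  # post-process stream, decoupled from filters

  pre_times <- unlist(pre)
  pre_neuron <- rep.int(seq_len(n_pre), lengths(pre))
  ord <- order(pre_times)
  pre_times <- pre_times[ord]
  pre_neuron <- pre_neuron[ord]
  w0 <- log(post_baseline_hz)

  u_true <- function(t) {
    hi <- findInterval(t, pre_times, left.open = TRUE)
    lo <- findInterval(t - window, pre_times, left.open = TRUE)
    counts <- hi - lo
    u <- rep(w0, length(t))
    if (sum(counts)) {
      qidx <- rep.int(seq_along(t), counts)
      sidx <- sequence(counts) + rep.int(lo, counts)
      lags <- t[qidx] - pre_times[sidx]
      F <- eval_filters(filters, lags)
      contrib <- F[cbind(seq_along(lags), pre_neuron[sidx])]
      add <- rowsum(contrib, qidx, reorder = FALSE)
      u[as.integer(rownames(add))] <- u[as.integer(rownames(add))] + add[, 1]
    }
    u
  }

  if (method == "thinning") {
    sup_pos <- filter_pos_sup(filters)
    edges <- sort(unique(c(0, duration,
                           pre_times, pmin(pre_times + window, duration))))
    edges <- edges[edges >= 0 & edges <= duration]
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    len <- diff(edges)
    # constant per-segment bound from active filters' positive sups
    hi <- findInterval(mids, pre_times, left.open = TRUE)
    lo <- findInterval(mids - window, pre_times, left.open = TRUE)
    counts <- hi - lo
    ubound <- rep(w0, length(mids))
    if (sum(counts)) {
      qidx <- rep.int(seq_along(mids), counts)
      sidx <- sequence(counts) + rep.int(lo, counts)
      add <- rowsum(sup_pos[pre_neuron[sidx]], qidx, reorder = FALSE)
      ubound[as.integer(rownames(add))] <-
        ubound[as.integer(rownames(add))] + add[, 1]
    }
    B <- exp(ubound)
    if (any(B > rate_cap)) {
      stop("rate bound exceeds cap: unstable filters.", call. = FALSE)
    }
    n_cand <- stats::rpois(length(mids), B * len)
    seg <- rep.int(seq_along(mids), n_cand)
    cand <- edges[seg] + stats::runif(sum(n_cand)) * len[seg]
    lam <- exp(u_true(cand))
    if (any(lam > rate_cap)) {
      stop("rate exceeds cap: unstable filters.", call. = FALSE)
    }
    acc <- stats::runif(length(cand)) < lam / B[seg]
    post <- sort(cand[acc])
  } else {
    n_grid <- ceiling(duration / grid_dt)
    post <- numeric(0)
    start <- 1
    while (start <= n_grid) {
      end <- min(start + 500000 - 1, n_grid)
      mids <- (seq(start, end) - 0.5) * grid_dt
      p <- exp(u_true(mids)) * grid_dt
      if (any(p > rate_cap * grid_dt)) {
        stop("rate exceeds cap: unstable filters.", call. = FALSE)
      }
      hit <- stats::runif(length(mids)) < p
      post <- c(post, mids[hit])
      start <- end + 1
    }
  }

  df <- data.frame(
    neuron_id = c(paste0("pre", pre_neuron), rep("post", length(post))),
    time = c(pre_times, post)
  )
  # fix dense ids: pre1..pre_n first by first appearance; enforce order
  df$neuron_id <- factor(df$neuron_id,
                         levels = c(paste0("pre", seq_len(n_pre)), "post"))
  df <- df[order(df$neuron_id, df$time), ]
  df$neuron_id <- as.character(df$neuron_id)
  pop <- spike_population(df, duration = duration)

  structure(
    list(
      population = pop,
      truth = list(filters = filters, target = n_pre + 1L,
                   baseline_hz = post_baseline_hz,
                   pre_rate_hz = rates, seed = seed, window = window),
      u_true = u_true
    ),
    class = "ppglm_simulation"
  )
}

#' @export
print.ppglm_simulation <- function(x, ...) {
  print(x$population)
  invisible(x)
}

#' Ground-truth rate of a simulation
#'
#' Evaluates the simulated target's true intensity \eqn{\lambda(t)} (Hz).
#'
#' @param sim A [simulate_all_to_one()] result.
#' @param t Times in seconds.
#' @return Rates at `t`.
#' @export
true_rate <- function(sim, t) {
  stopifnot(inherits(sim, "ppglm_simulation"))
  exp(sim$u_true(t))
}

#' Ground-truth filters on a lag grid
#'
#' Returns the simulated coupling filters in the same tibble layout as
#' [coupling_filters()] on a fit, with a zero self-filter for the target, so
#' the two can be compared directly by [filter_mse()].
#'
#' @param fit A `ppglm_simulation`.
#' @param lags Lag grid (default 0.05 ms over the filter window).
#' @param ... Unused.
#' @export
coupling_filters.ppglm_simulation <- function(fit, lags = NULL, ...) {
  tf <- fit$truth$filters
  if (is.null(lags)) lags <- filter_grid(tf$window)
  F <- eval_filters(tf, lags)
  n_pre <- ncol(F)
  tibble::tibble(
    neuron = rep(seq_len(n_pre + 1L), each = length(lags)),
    lag = rep(lags, n_pre + 1L),
    value = c(as.vector(F), numeric(length(lags)))
  )
}

#' Simulate a sparse mutually-coupled GLM network
#'
#' A directed Erdős–Rényi connectivity mask (no self-edges) at the requested
#' density; every neuron is an exponential-link GLM driven by its presynaptic
#' partners' spikes through ground-truth filters. The joint process is sampled
#' exactly by Ogata thinning on the superposed process with piecewise-constant
#' upper bounds from the positive parts of the active filters. Stability is
#' guarded by scaling each neuron's incoming filters so that the excitatory
#' mass proxy (sum over inputs of baseline rate times the positive filter
#' integral) stays below 0.8.
#'
#' @param n_neurons Population size `N >= 2`.
#' @param sparsity Directed edge density (default 0.1).
#' @param duration Recording length in seconds (default 100).
#' @param seed RNG seed.
#' @param window Filter support in seconds.
#' @param baseline_range Per-neuron baseline rates are drawn uniformly from
#'   this range (Hz).
#' @param rate_cap Abort threshold on any neuron's rate (Hz).
#' @return A list with `population`, `truth` (mask, baselines, filters) —
#'   class `ppglm_network_sim`.
#' @export
simulate_network <- function(n_neurons, sparsity = 0.1, duration = 100,
                             seed = 1, window = 0.005,
                             baseline_range = c(1, 4), rate_cap = 1e4) {
  stopifnot(n_neurons >= 2, sparsity >= 0, sparsity <= 1)
  set.seed(seed)
  N <- n_neurons
  mask <- matrix(stats::runif(N * N) < sparsity, N, N)  # [pre, post]
  diag(mask) <- FALSE
  baselines <- stats::runif(N, baseline_range[1], baseline_range[2])
  n_edges <- sum(mask)
  tf <- if (n_edges > 0) {
    make_filters(n_edges, window = window, seed = seed + 7919L)
  } else {
    NULL
  }

  grid <- seq(0, window, length.out = 512)
  # per-edge positive sup and positive integral, for bounds and stability
  if (n_edges > 0) {
    Fg <- eval_filters(tf, grid)
    edge_idx <- which(mask, arr.ind = TRUE)  # cols: pre (row), post (col)
    pos_int <- apply(Fg, 2, function(v) sum(pmax(v, 0)) * (grid[2] - grid[1]))
    # stability: scale incoming filters per postsynaptic neuron
    for (post in seq_len(N)) {
      e <- which(edge_idx[, 2] == post)
      if (!length(e)) next
      mass <- sum(baselines[edge_idx[e, 1]] * pos_int[e])
      if (mass > 0.8) tf$coef[e, ] <- tf$coef[e, ] * (0.8 / mass)
    }
    Fg <- eval_filters(tf, grid)
    pos_sup <- apply(Fg, 2, function(v) max(c(v, 0)))
  } else {
    edge_idx <- matrix(integer(0), 0, 2)
    pos_sup <- numeric(0)
  }
  w0 <- log(baselines)

  # event-driven Ogata thinning on the superposed process
  set.seed(seed + 32452843L)
  sp_time <- numeric(0)
  sp_neuron <- integer(0)
  act_time <- numeric(0)   # active spikes (within window of current time)
  act_neuron <- integer(0)

  lam_all <- function(t) {
    u <- w0
    if (length(act_time)) {
      lags <- t - act_time
      keep <- lags > 0 & lags <= window
      if (any(keep)) {
        lt <- lags[keep]; ln <- act_neuron[keep]
        Fv <- if (n_edges > 0) eval_filters(tf, lt) else NULL
        for (i in seq_along(lt)) {
          e <- which(edge_idx[, 1] == ln[i])
          if (length(e)) {
            u[edge_idx[e, 2]] <- u[edge_idx[e, 2]] + Fv[i, e]
          }
        }
      }
    }
    exp(pmin(u, log(rate_cap)))
  }

  t <- 0
  repeat {
    # prune expired actives, recompute bound
    # prune with a tolerance: (act + window) - act can round below window,
    # which would pin next_expiry and stall the clock
    keep <- (t - act_time) < window - 1e-12
    act_time <- act_time[keep]; act_neuron <- act_neuron[keep]
    # bound: sum_n exp(w0_n + sum of active positive filter sups into n)
    u_b <- w0
    if (length(act_time)) {
      for (i in seq_along(act_time)) {
        n <- act_neuron[i]
        e <- which(edge_idx[, 1] == n)
        if (length(e)) {
          u_b[edge_idx[e, 2]] <- u_b[edge_idx[e, 2]] + pos_sup[e]
        }
      }
    }
    B <- sum(exp(pmin(u_b, log(rate_cap))))
    next_expiry <- if (length(act_time)) min(act_time) + window else Inf
    dt <- stats::rexp(1, B)
    if (t + dt > next_expiry) {
      t <- next_expiry
      if (t >= duration) break
      next
    }
    t <- t + dt
    if (t >= duration) break
    lam <- lam_all(t)
    tot <- sum(lam)
    if (max(lam) >= rate_cap) {
      stop("rate exceeds cap: unstable network.", call. = FALSE)
    }
    if (stats::runif(1) < tot / B) {
      n_new <- sample.int(N, 1, prob = lam)
      sp_time <- c(sp_time, t)
      sp_neuron <- c(sp_neuron, n_new)
      act_time <- c(act_time, t)
      act_neuron <- c(act_neuron, n_new)
    }
  }

  if (!length(sp_time)) stop("no spikes generated.", call. = FALSE)
  # ensure all neurons appear with dense ids 1..N in order: relabel via factor
  df <- data.frame(neuron_id = sprintf("n%03d", sp_neuron), time = sp_time)
  missing <- setdiff(seq_len(N), unique(sp_neuron))
  # silent neurons carry no spikes; note them in truth
  pop <- spike_population(df[order(df$neuron_id, df$time), ],
                          duration = duration)
  structure(
    list(
      population = pop,
      truth = list(mask = mask, baselines = baselines, filters = tf,
                   edge_index = edge_idx, silent = missing, seed = seed,
                   window = window)
    ),
    class = "ppglm_network_sim"
  )
}
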