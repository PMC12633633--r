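#' Scaled generalized Laguerre temporal basis
#'
#' Basis functions for coupling filters on the history window `[0, H]`:
#' \deqn{\phi_n(\tau) = L_n^{(\alpha)}(c\,\tau_{ms}) (c\,\tau_{ms})^{\alpha/2}
#'   e^{-c\,\tau_{ms}/2}, \quad n = 0, \dots, J-1,}
#' where \eqn{\tau_{ms} = 1000\,\tau} is the lag in milliseconds. These
#' functions are orthogonal on `[0, Inf)`, follow a gamma-like rise-decay
#' envelope matched to synaptic dynamics, and admit closed-form single and
#' pairwise integrals via the lower incomplete gamma function — the property
#' the polynomial-approximate estimator exploits.
#'
#' The lag variable is measured in milliseconds internally so that the default
#' scale `c = 1.5` and shape `alpha = 2` operate on millisecond-scale
#' dynamics; all public interfaces take and return seconds.
#'
#' @param n_basis Number of basis functions `J` (default 3).
#' @param window History window `H` in seconds (default 0.005).
#' @param alpha Shape parameter (> -1). Closed-form integrals require a
#'   nonnegative even integer; other values fall back to adaptive quadrature.
#' @param scale Time-scale parameter `c` per millisecond (default 1.5).
#' @return An object of class `temporal_basis`.
#' @export
gl_basis <- function(n_basis = 3, window = 0.005, alpha = 2, scale = 1.5) {
  if (alpha <= -1) stop("`alpha` must exceed -1.", call. = FALSE)
  stopifnot(n_basis >= 1, window > 0, scale > 0)
  structure(
    list(kind = "GL", J = as.integer(n_basis), H = window,
         alpha = alpha, c = scale),
    class = "temporal_basis"
  )
}

#' Log-stretched raised cosine temporal basis
#'
#' The standard comparison basis: `J` cosine bumps equally spaced in
#' `log(tau_ms + stretch)`, tiling `[0, H]`. Not orthogonal; all integrals are
#' computed by adaptive quadrature.
#'
#' @inheritParams gl_basis
#' @param stretch Log-time offset in milliseconds controlling how strongly
#'   bumps crowd toward short lags (default 1).
#' @return An object of class `temporal_basis`.
#' @export
rc_basis <- function(n_basis = 4, window = 0.005, stretch = 1) {
  stopifnot(n_basis >= 1, window > 0, stretch > 0)
  h_ms <- 1000 * window
  y0 <- log(stretch)
  y1 <- log(h_ms + stretch)
  centers <- if (n_basis == 1) (y0 + y1) / 2 else seq(y0, y1, length.out = n_basis)
  width <- if (n_basis == 1) (y1 - y0) / 2 else (centers[2] - centers[1])
  structure(
    list(kind = "RC", J = as.integer(n_basis), H = window,
         stretch = stretch, centers = centers, width = width),
    class = "temporal_basis"
  )
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat(sprintf("<temporal_basis> %s, J = %d, H = %g ms\n",
              x$kind, x$J, 1000 * x$H))
  invisible(x)
}

basis_descriptor <- function(b) {
  stopifnot(inherits(b, "temporal_basis"))
  if (b$kind == "GL") {
    list(kind = "GL", J = b$J, H_seconds = b$H, alpha = b$alpha, c = b$c)
  } else {
    list(kind = "RC", J = b$J, H_seconds = b$H, stretch = b$stretch)
  }
}

basis_from_descriptor <- function(d) {
  if (is.null(d$kind) || is.null(d$J) || is.null(d$H_seconds)) {
    stop("incomplete basis descriptor.", call. = FALSE)
  }
  if (d$kind == "GL") {
    gl_basis(d$J, d$H_seconds, alpha = d$alpha, scale = d$c)
  } else {
    rc_basis(d$J, d$H_seconds, stretch = d$stretch)
  }
}

# generalized Laguerre polynomial coefficients: L_n^(alpha)(x) = sum_k l_k x^k
laguerre_coefs <- function(n, alpha) {
  k <- 0:n
  (-1)^k * choose(n + alpha, n - k) / factorial(k)
}

# phi_n as a polynomial in y = c * tau_ms times exp(-y/2):
# coefficients a_r for y^r, r = 0..(n + alpha/2); requires even integer alpha
gl_poly_y <- function(n, alpha) {
  p <- alpha / 2
  a <- numeric(n + p + 1)
  a[(0:n) + p + 1] <- laguerre_coefs(n, alpha)
  a
}

gl_closed_form_ok <- function(b) {
  b$kind == "GL" && b$alpha >= 0 && b$alpha %% 2 == 0
}

#' Evaluate basis functions at lags
#'
#' @param b A [gl_basis()] or [rc_basis()].
#' @param taus Lags in seconds. Lags outside `[0, H]` map to 0.
#' @return A `length(taus) x J` matrix.
#' @export
eval_basis <- function(b, taus) {
  stopifnot(inherits(b, "temporal_basis"))
  t_ms <- 1000 * as.numeric(taus)
  h_ms <- 1000 * b$H
  inside <- t_ms >= 0 & t_ms <= h_ms
  out <- matrix(0, length(t_ms), b$J)
  if (!any(inside)) return(out)
  tin <- t_ms[inside]
  if (b$kind == "GL") {
    y <- b$c * tin
    env <- y^(b$alpha / 2) * exp(-y / 2)
    for (n in 0:(b$J - 1)) {
      lk <- laguerre_coefs(n, b$alpha)
      poly <- rep(lk[n + 1], length(y))
      if (n >= 1) for (k in n:1) poly <- poly * y + lk[k]
      out[inside, n + 1] <- poly * env
    }
  } else {
    yv <- log(tin + b$stretch)
    for (j in seq_len(b$J)) {
      arg <- (yv - b$centers[j]) * pi / (2 * b$width)
      arg <- pmin(pmax(arg, -pi), pi)
      out[inside, j] <- 0.5 * (1 + cos(arg))
    }
  }
  out
}

#' Lower incomplete gamma function
#'
#' \eqn{\gamma(a, x) = \int_0^x t^{a-1} e^{-t} dt}, the building block of the
#' closed-form Laguerre basis integrals. Computed via the regularized gamma
#' CDF.
#'
#' @param a Shape, positive.
#' @param x Upper limit, nonnegative (vectorized).
#' @return \eqn{\gamma(a, x)}.
#' @export
lower_inc_gamma <- function(a, x) {
  if (any(a <= 0)) stop("`a` must be positive.", call. = FALSE)
  if (any(x < 0)) stop("`x` must be nonnegative.", call. = FALSE)
  stats::pgamma(x, shape = a) * gamma(a)
}

# adaptive quadrature of one basis-function product on [lo, hi] (ms), abs tol
# 1e-12 in ms units (i.e. 1e-15 s after conversion)
quad_ms <- function(f, lo, hi) {
  if (hi <= lo) return(0)
  stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Single basis integrals
#'
#' \eqn{\bar\phi_j = \int_0^H \phi_j(\tau) d\tau} in seconds. For the GL basis
#' with even integer `alpha` the integral is exact, via monomial expansion and
#' [lower_inc_gamma()]; otherwise adaptive quadrature is used.
#'
#' @param b A `temporal_basis`.
#' @return Numeric vector of length `J` (seconds).
#' @export
single_integrals <- function(b) {
  stopifnot(inherits(b, "temporal_basis"))
  h_ms <- 1000 * b$H
  if (gl_closed_form_ok(b)) {
    xH <- b$c * h_ms / 2
    vapply(0:(b$J - 1), function(n) {
      a <- gl_poly_y(n, b$alpha)
      r <- seq_along(a) - 1
      # (1/c) * sum_r a_r 2^(r+1) gamma_inc(r+1, cH/2), then ms -> s
      1e-3 / b$c * sum(a * 2^(r + 1) * lower_inc_gamma(r + 1, xH))
    }, numeric(1))
  } else {
    vapply(seq_len(b$J), function(j) {
      1e-3 * quad_ms(function(t) eval_basis(b, t * 1e-3)[, j], 0, h_ms)
    }, numeric(1))
  }
}

# triplet expansion of A_j(y) * A_j'(y - d) for the closed-form pairwise
# integral: list of (q = power of y, e = power of d, coef)
gl_pair_triplets <- function(b) {
  polys <- lapply(0:(b$J - 1), gl_poly_y, alpha = b$alpha)
  out <- vector("list", b$J * b$J)
  for (j in seq_len(b$J)) {
    aj <- polys[[j]]
    for (jp in seq_len(b$J)) {
      am <- polys[[jp]]
      q <- integer(0); e <- integer(0); coef <- numeric(0)
      for (r in which(aj != 0) - 1) {
        for (m in which(am != 0) - 1) {
          i <- 0:m
          q <- c(q, r + i)
          e <- c(e, m - i)
          coef <- c(coef, aj[r + 1] * am[m + 1] * choose(m, i) * (-1)^(m - i))
        }
      }
      out[[(j - 1) * b$J + jp]] <- list(q = q, e = e, coef = coef)
    }
  }
  out
}

# closed-form pairwise integrals for a vector of nonnegative deltas (seconds);
# returns array (n_delta, J, J); entries [d, j, jp] = P(delta_d)[j, jp]
gl_pair_values <- function(b, deltas) {
  h_ms <- 1000 * b$H
  d_ms <- 1000 * deltas
  d <- b$c * d_ms            # delta in y units
  xH <- b$c * h_ms
  nd <- length(d)
  qmax <- 2 * (b$J - 1 + b$alpha / 2)
  # gamma-difference table: G[, q + 1] = gamma_inc(q+1, xH) - gamma_inc(q+1, d)
  G <- vapply(0:qmax, function(q) {
    lower_inc_gamma(q + 1, xH) - lower_inc_gamma(q + 1, d)
  }, numeric(nd))
  G <- matrix(G, nrow = nd)
  dpow <- vapply(0:qmax, function(e) d^e, numeric(nd))
  dpow <- matrix(dpow, nrow = nd)
  pref <- exp(d / 2) * 1e-3 / b$c
  trip <- gl_pair_triplets(b)
  out <- array(0, c(nd, b$J, b$J))
  zero <- deltas > b$H  # outside interaction window
  for (j in seq_len(b$J)) {
    for (jp in seq_len(b$J)) {
      tr <- trip[[(j - 1) * b$J + jp]]
      v <- numeric(nd)
      for (i in seq_along(tr$q)) {
        v <- v + tr$coef[i] * dpow[, tr$e[i] + 1] * G[, tr$q[i] + 1]
      }
      v <- v * pref
      v[zero] <- 0
      out[, j, jp] <- v
    }
  }
  out
}

#' Pairwise basis integrals
#'
#' The `J x J` matrix \eqn{P(\delta)} with entries
#' \eqn{P(\delta)_{jj'} = \int_\delta^H \phi_j(\tau)\phi_{j'}(\tau-\delta)
#' d\tau} for \eqn{\delta \ge 0}; for \eqn{\delta < 0} the transpose
#' \eqn{P(-\delta)^\top} is returned, and \eqn{|\delta| > H} yields zeros
#' (the spike pair is outside the interaction window). Units are seconds.
#' Closed form for the GL basis with even integer `alpha`; quadrature
#' otherwise.
#'
#' @param b A `temporal_basis`.
#' @param delta Lag difference in seconds, `|delta| <= H` for a nonzero
#'   result.
#' @return A `J x J` matrix.
#' @export
pairwise_integrals <- function(b, delta) {
  stopifnot(inherits(b, "temporal_basis"), length(delta) == 1)
  if (delta < 0) return(t(pairwise_integrals(b, -delta)))
  if (delta > b$H) return(matrix(0, b$J, b$J))
  if (gl_closed_form_ok(b)) {
    return(gl_pair_values(b, delta)[1, , , drop = TRUE] |>
             matrix(b$J, b$J))
  }
  h_ms <- 1000 * b$H
  d_ms <- 1000 * delta
  P <- matrix(0, b$J, b$J)
  for (j in seq_len(b$J)) {
    for (jp in seq_len(b$J)) {
      P[j, jp] <- 1e-3 * quad_ms(function(t) {
        eval_basis(b, t * 1e-3)[, j] * eval_basis(b, (t - d_ms) * 1e-3)[, jp]
      }, d_ms, h_ms)
    }
  }
  P
}

#' Gram matrix of the GL basis on `[0, Inf)`
#'
#' Numerically integrates \eqn{\phi_j \phi_{j'}} over the positive half-line;
#' off-diagonals vanish by the orthogonality of generalized Laguerre
#' polynomials under the weight \eqn{t^\alpha e^{-t}}. Diagonal entries equal
#' \eqn{\Gamma(n+\alpha+1)/n! / c} (in ms), converted to seconds.
#'
#' @param b A GL `temporal_basis`.
#' @return A `J x J` matrix (seconds).
#' @export
gl_orthogonality_check <- function(b) {
  stopifnot(inherits(b, "temporal_basis"))
  if (b$kind != "GL") {
    stop("orthogonality check applies to the GL basis only.", call. = FALSE)
  }
  G <- matrix(0, b$J, b$J)
  cutoff <- (80 + 20 * b$J) / b$c  # envelope exp(-c t / 2) is ~0 far out
  for (j in seq_len(b$J)) {
    for (jp in j:b$J) {
      v <- 1e-3 * stats::integrate(function(t) {
        eval_basis_unwindowed(b, t)[, j] * eval_basis_unwindowed(b, t)[, jp]
      }, 0, cutoff, rel.tol = 1e-10, abs.tol = 1e-12,
      subdivisions = 400L)$value
      G[j, jp] <- v
      G[jp, j] <- v
    }
  }
  G
}

# GL basis evaluated on [0, Inf) in ms without the [0, H] window (internal,
# used by the orthogonality check)
eval_basis_unwindowed <- function(b, t_ms) {
  y <- b$c * t_ms
  env <- y^(b$alpha / 2) * exp(-y / 2)
  out <- matrix(0, length(y), b$J)
  for (n in 0:(b$J - 1)) {
    lk <- laguerre_coefs(n, b$alpha)
    poly <- rep(lk[n + 1], length(y))
    if (n >= 1) for (k in n:1) poly <- poly * y + lk[k]
    out[, n + 1] <- poly * env
  }
  out
}
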