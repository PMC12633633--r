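test_that("quadratic fits project exactly and approach the Taylor limit", {
  # a quadratic target is recovered to machine precision
  pa <- fit_poly(function(x) 2.5 * x^2 - 1.2 * x + 0.3, -2, 3)
  expect_equal(c(pa$a0, pa$a1, pa$a2), c(0.3, -1.2, 2.5), tolerance = 1e-10)
  expect_lt(pa$residual, 1e-9)
  # exp on [-1, 1]: small residual, convex coefficient (the 0.085 bound is a
  # frozen regression value; the least-squares fit attains ~0.082 max-abs)
  pa_exp <- fit_poly("exp", -1, 1)
  expect_gt(pa_exp$a2, 0)
  expect_lt(pa_exp$residual, 0.085)
  # shrinking range: Taylor limit of exp
  pa_eps <- fit_poly("exp", -1e-3, 1e-3)
  expect_equal(c(pa_eps$a0, pa_eps$a1, pa_eps$a2), c(1, 1, 0.5),
               tolerance = 1e-4)
  expect_error(fit_poly("exp", 1, 1), "x0")
})

test_that("range selection follows the mean-centered and percentile rules", {
  set.seed(4)
  k <- rpois(1, 3 * 100)
  pop <- spike_population(
    data.frame(neuron_id = 1, time = sort(runif(k, 0, 100))), duration = 100)
  rbar <- k / 100
  rng <- select_range(pop, 1, mode = "mean_centered", width_hz = 4)
  expect_equal(rng, c(log(rbar - 2), log(rbar + 2)))
  # percentile mode on constant rates: degenerate range widened to 0.1
  rng2 <- select_range(mode = "percentile_sim", rates = rep(3, 1000))
  expect_equal(diff(rng2), 0.1)
  expect_equal(mean(rng2), log(3))
  # wider ranges cost approximation accuracy
  res <- vapply(c(3, 5, 7), function(w) {
    r <- select_range(pop, 1, mode = "mean_centered", width_hz = w)
    fit_poly("exp", r[1], r[2])$residual
  }, numeric(1))
  expect_true(all(diff(res) > 0))
  expect_error(select_range(pop, 1, mode = "percentile_sim"), "rates")
})

test_that("sufficient statistics have the documented shape and invariants", {
  pop <- pop_edge_free()
  b <- basis_default()
  st <- sufficient_stats(pop, 4, b)
  D <- pop$n_neurons * 3 + 1
  expect_equal(dim(st$M), c(D, D))
  expect_equal(st$M, t(st$M))
  expect_equal(st$m[1], pop$duration)
  expect_equal(st$k[1], st$K)
  expect_equal(st$K, length(neuron_times(pop, 4)))
  ev <- eigen(st$M, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(st$M)))
  # m blocks are S_n * phibar
  S_n <- tabulate(pop$spikes$neuron, pop$n_neurons)
  expect_equal(st$m[-1], as.vector(t(outer(S_n, single_integrals(b)))))
})

test_that("the pair sweep equals brute-force all-pairs enumeration", {
  pop <- pop_edge_free(n_pre = 2, duration = 3, seed = 12)
  b <- gl_basis(2, 0.005)
  st <- sufficient_stats(pop, 1, b)
  J <- 2
  D <- pop$n_neurons * J + 1
  Mb <- matrix(0, D, D)
  tms <- pop$times_all
  nrn <- pop$neurons_all
  slot <- function(n, j) 1 + (n - 1) * J + j
  for (i in seq_along(tms)) {
    for (k in seq_along(tms)) {
      delta <- tms[i] - tms[k]
      if (abs(delta) > b$H) next
      if (delta < 0) next
      if (delta == 0 && k > i) next      # unordered tie handled once
      B <- pairwise_integrals(b, delta)  # block (earlier k, later i)
      ri <- slot(nrn[k], 1:J); ci <- slot(nrn[i], 1:J)
      if (i == k) {
        Mb[ri, ci] <- Mb[ri, ci] + B
      } else {
        Mb[ri, ci] <- Mb[ri, ci] + B
        Mb[ci, ri] <- Mb[ci, ri] + t(B)
      }
    }
  }
  expect_equal(st$M[-1, -1], Mb[-1, -1], tolerance = 1e-12)
})

test_that("isolated spikes make M block diagonal with per-spike P(0) sums", {
  # spikes farther apart than H: no cross terms survive
  times <- seq(0.1, 0.9, by = 0.1)
  pop <- spike_population(
    data.frame(neuron_id = rep(1:3, 3), time = times), duration = 1)
  b <- basis_default()
  st <- sufficient_stats(pop, 1, b)
  P0 <- pairwise_integrals(b, 0)
  for (n in 1:3) {
    idx <- 1 + (n - 1) * 3 + (1:3)
    expect_equal(st$M[idx, idx], 3 * P0)
    for (n2 in setdiff(1:3, n)) {
      idx2 <- 1 + (n2 - 1) * 3 + (1:3)
      expect_equal(st$M[idx, idx2], matrix(0, 3, 3))
    }
  }
})

test_that("the quadratic form reproduces direct integration of the surrogate CIF", {
  b <- basis_default()
  pa <- fit_poly("exp", log(1), log(8))
  set.seed(3)
  for (s in 1:2) {
    pop <- pop_edge_free(n_pre = 2, duration = 3, seed = 40 + s)
    st <- sufficient_stats(pop, 3, b)
    for (r in 1:3) {
      w <- c(rnorm(1, 1, 0.3), rnorm(pop$n_neurons * 3, sd = 0.3))
      params <- ppglm:::unpack_params(w, pop$n_neurons, 3)
      qf <- pa$a2 * drop(t(w) %*% st$M %*% w) + pa$a1 * sum(st$m * w) +
        pop$duration * pa$a0
      direct <- quad_of_u(pop, params, b,
                          function(u) pa$a2 * u^2 + pa$a1 * u + pa$a0)
      expect_equal(qf, direct, tolerance = 1e-8)
    }
  }
})

test_that("the closed-form solve zeroes the surrogate gradient", {
  pop <- pop_edge_free()
  b <- basis_default()
  st <- sufficient_stats(pop, 4, b)
  pa <- fit_poly("exp", log(1), log(8))
  for (beta in c(0, 100)) {
    sol <- solve_map(st, pa, ridge = beta)
    w <- ppglm:::pack_params(sol)
    grad <- st$k - pa$a1 * st$m - 2 * pa$a2 * drop(st$M %*% w) -
      2 * beta * c(0, w[-1])
    expect_lt(max(abs(grad)), 1e-8 * sqrt(sum(st$k^2)))
  }
  # diagonal stub: elementwise closed form
  st2 <- st
  st2$M <- diag(length(st$k))
  sol2 <- ppglm:::pack_params(solve_map(st2, pa, ridge = 0))
  expect_equal(sol2, (st$k - pa$a1 * st$m) / (2 * pa$a2), tolerance = 1e-12)
})

test_that("PA-c caches statistics for ridge re-solves and obeys the ridge limit", {
  sim <- pop_small()
  pop <- sim$population
  b <- basis_default()
  fit0 <- fit_pa_c(pop, sim$truth$target, b, range = c(log(0.5), log(8)))
  fit1 <- refit_ridge(fit0, 50)
  expect_identical(fit1$meta$stats, fit0$meta$stats)  # bit-exact reuse
  direct <- fit_pa_c(pop, sim$truth$target, b, range = c(log(0.5), log(8)),
                     ridge = 50, stats = fit0$meta$stats)
  expect_identical(fit1$weights, direct$weights)
  # beta -> infinity drives coupling weights to zero
  big <- refit_ridge(fit0, 1e12)
  expect_lt(max(abs(big$weights)), 1e-6)
  expect_error(fit_pa_c(pop, 1, b, link = "softplus"), "exp link")
})

test_that("cross-validated width selection scores a grid and picks a winner", {
  sim <- pop_small()
  tab <- select_range_cv(sim$population, sim$truth$target, basis_default(),
                         widths = c(3, 5, 7), seed = 2)
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$heldout_loglik)))
  expect_true(attr(tab, "best") %in% c(3, 5, 7))
})
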