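# Shared fixtures, built in code and memoised for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 4-neuron all-to-one simulation, ~340 spikes
pop_small <- function() {
  fixture("pop_small", function() {
    simulate_all_to_one(n_pre = 3, duration = 20, seed = 5)
  })
}

# ~100-spike instance for MC checks
pop_tiny <- function() {
  fixture("pop_tiny", function() {
    simulate_all_to_one(n_pre = 2, duration = 4, seed = 15)
  })
}

# edge-free population (no spikes within H of T), where the PA sufficient
# statistics are an exact identity for the quadratic CIF
pop_edge_free <- function(n_pre = 3, duration = 5, seed = 7) {
  sim <- simulate_all_to_one(n_pre = n_pre, duration = duration, seed = seed)
  pop0 <- sim$population
  keep <- pop0$spikes$time <= duration - 0.0055
  spike_population(
    data.frame(neuron_id = pop0$labels[pop0$spikes$neuron[keep]],
               time = pop0$spikes$time[keep]),
    duration = duration
  )
}

basis_default <- function() gl_basis(3, window = 0.005)

random_params <- function(pop, J = 3, sd = 0.3, w0 = log(3), seed = 8) {
  set.seed(seed)
  ppglm_params(matrix(rnorm(pop$n_neurons * J, sd = sd), pop$n_neurons, J),
               w0 = w0)
}

# quadrature oracle for one basis-product integral, in seconds
quad_pair_oracle <- function(b, j, jp, delta) {
  dm <- 1000 * delta
  hm <- 1000 * b$H
  if (hm - dm < 1e-12) return(0)
  1e-3 * stats::integrate(function(t) {
    eval_basis(b, t * 1e-3)[, j] * eval_basis(b, (t - dm) * 1e-3)[, jp]
  }, dm, hm, rel.tol = 1e-10, abs.tol = 1e-13, subdivisions = 400L)$value
}

quad_single_oracle <- function(b, j) {
  1e-3 * stats::integrate(function(t) eval_basis(b, t * 1e-3)[, j],
                          0, 1000 * b$H, rel.tol = 1e-12,
                          abs.tol = 1e-13)$value
}

# piecewise quadrature of an arbitrary function of the linear predictor over
# [0, T], subdividing at the intensity kinks
quad_of_u <- function(pop, params, b, fun, rel.tol = 1e-11) {
  kinks <- sort(unique(c(0, pop$duration, pop$times_all,
                         pop$times_all + b$H)))
  kinks <- kinks[kinks <= pop$duration]
  total <- 0
  for (i in seq_len(length(kinks) - 1)) {
    if (kinks[i + 1] - kinks[i] < 1e-14) next
    total <- total + stats::integrate(function(t) {
      fun(linear_predictor(pop, params, b, t))
    }, kinks[i], kinks[i + 1], rel.tol = rel.tol,
    subdivisions = 300L)$value
  }
  total
}
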