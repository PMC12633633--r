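test_that("stratified samples place one point per stratum", {
  set.seed(1)
  taus <- stratified_sample(10, 25)
  expect_length(taus, 25)
  expect_true(all(taus >= 0 & taus <= 10))
  expect_identical(findInterval(taus, seq(0, 10, by = 10 / 25),
                                rightmost.closed = TRUE), 1:25)
})

test_that("constant integrands are integrated exactly by any sample", {
  pop1 <- spike_population(data.frame(neuron_id = 1, time = 0.5), duration = 3)
  b <- basis_default()
  const <- ppglm_params(matrix(0, 1, 3), w0 = log(5))
  set.seed(2)
  for (r in 1:5) {
    expect_equal(cif_mc_estimate(pop1, const, b, stratified_sample(3, 40)),
                 15, tolerance = 1e-12)
  }
  # no target spikes: objective is the CIF estimate alone
  expect_equal(
    mc_objective(pop1, numeric(0), const, b, stratified_sample(3, 40)),
    15, tolerance = 1e-12)
})

test_that("the stratified estimator is unbiased against the quadrature oracle", {
  sim <- pop_tiny()
  pop <- sim$population
  b <- basis_default()
  params <- random_params(pop, sd = 0.4)
  oracle <- cif_quadrature(pop, params, b, tol = 1e-9)
  set.seed(99)
  est <- replicate(2000, cif_mc_estimate(pop, params, b,
                                         stratified_sample(pop$duration, 200)))
  z <- (mean(est) - oracle) / (sd(est) / sqrt(length(est)))
  expect_lt(abs(z), 4)
})

test_that("stratification does not increase variance and helps at fine strata", {
  sim <- pop_tiny()
  pop <- sim$population
  b <- basis_default()
  params <- random_params(pop, sd = 0.4)
  set.seed(7)
  M <- 2000  # 2 ms strata resolve the history-window-scale rate structure
  strat <- replicate(800, cif_mc_estimate(pop, params, b,
                                          stratified_sample(pop$duration, M)))
  unif <- replicate(800, cif_mc_estimate(pop, params, b,
                                         uniform_sample(pop$duration, M)))
  expect_lt(var(strat), var(unif))
})

test_that("the MC objective averages to the exact negative log-likelihood", {
  sim <- pop_tiny()
  pop <- sim$population
  b <- basis_default()
  params <- random_params(pop, sd = 0.3)
  post <- neuron_times(pop, sim$truth$target)
  exact <- cif_quadrature(pop, params, b) - spike_term(pop, post, params, b)
  set.seed(13)
  obj <- replicate(1500, mc_objective(pop, post, params, b,
                                      stratified_sample(pop$duration, 150)))
  z <- (mean(obj) - exact) / (sd(obj) / sqrt(length(obj)))
  expect_lt(abs(z), 4)
})

test_that("MC fitting recovers a constant rate and is seed-deterministic", {
  set.seed(11)
  k <- rpois(1, 3 * 300)
  pop <- spike_population(
    data.frame(neuron_id = 1, time = sort(runif(k, 0, 300))), duration = 300)
  b <- basis_default()
  ctrl <- mc_control(n_iter = 300, seed = 3)
  fit <- fit_mc(pop, 1, b, control = ctrl)
  expect_equal(exp(fit$intercept), 3, tolerance = 0.1)
  fit2 <- fit_mc(pop, 1, b, control = ctrl)
  expect_identical(fit2$weights, fit$weights)
  expect_identical(fit2$meta$trace$objective, fit$meta$trace$objective)
})

test_that("objective at the truth beats the zero start on well-sized data", {
  sim <- pop_small()
  pop <- sim$population
  b <- basis_default()
  post <- neuron_times(pop, sim$truth$target)
  # project the true filters onto the fitting basis for a near-truth parameter
  g <- seq(1e-5, b$H, length.out = 400)
  Phi <- eval_basis(b, g)
  truth <- coupling_filters(sim, g)
  W <- t(vapply(seq_len(pop$n_neurons), function(n) {
    qr.coef(qr(Phi), truth$value[truth$neuron == n])
  }, numeric(3)))
  near_truth <- ppglm_params(W, w0 = log(sim$truth$baseline_hz))
  zero <- ppglm_params(matrix(0, pop$n_neurons, 3), w0 = 0)
  set.seed(5)
  taus <- stratified_sample(pop$duration, 4000)
  expect_lt(mc_objective(pop, post, near_truth, b, taus),
            mc_objective(pop, post, zero, b, taus))
})

test_that("warm-started optimization reaches the cold-start level in fewer iterations", {
  sim <- pop_small()
  pop <- sim$population
  b <- basis_default()
  tgt <- sim$truth$target
  ctrl <- mc_control(n_iter = 250, seed = 9)
  cold <- fit_mc(pop, tgt, b, control = ctrl)
  warm <- fit_hybrid(pop, tgt, b, range = c(log(0.5), log(8)),
                     control = ctrl)
  level <- cold$meta$trace$objective[ctrl$n_iter]
  it_warm <- ppglm:::iterations_to_reach(warm$meta$trace$objective, level)
  it_cold <- ppglm:::iterations_to_reach(cold$meta$trace$objective, level)
  expect_lt(it_warm, it_cold)
  expect_equal(warm$estimator, "hybrid")
})

test_that("normalized gradient error vanishes for exact gradients and scales as 1/M", {
  sim <- pop_tiny()
  pop <- sim$population
  b <- basis_default()
  tgt <- sim$truth$target
  params <- random_params(pop, sd = 0.2)
  # deterministic 'stochastic' gradient == exact gradient -> error 0
  g_exact <- ppglm:::exact_gradient(pop, neuron_times(pop, tgt), params, b,
                                    dt = 1e-5)
  expect_equal(sum((g_exact - g_exact)^2) / sum(g_exact^2), 0)
  errs <- vapply(c(50, 200, 800), function(M) {
    gradient_error_mc(pop, tgt, list(params), b, M = M, n_resamples = 60,
                      exact_dt = 2e-5, seed = 21)$error
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # variance scaling ~ 1/M: quadrupling M cuts the error by ~4
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.5)
})

test_that("the MC path supports the softplus link", {
  set.seed(17)
  k <- rpois(1, 3 * 200)
  pop <- spike_population(
    data.frame(neuron_id = 1, time = sort(runif(k, 0, 200))), duration = 200)
  b <- basis_default()
  fit <- fit_mc(pop, 1, b,
                control = mc_control(n_iter = 1000, learning_rate = 0.02,
                                     seed = 2),
                link = "softplus")
  expect_lt(abs(nonlinearity("softplus")$forward(fit$intercept) - 3), 0.3)
})
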