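make_filter_tbl <- function(pre, post, values, lags) {
  tibble::tibble(pre = pre, post = post, lag = lags, value = values)
}

# triangular filter in ms units: linear rise from onset to peak and back down
triangle_filter <- function(lags, onset_ms, peak_ms, amp) {
  gm <- 1000 * lags
  v <- numeric(length(gm))
  up <- gm >= onset_ms & gm <= peak_ms
  v[up] <- amp * (gm[up] - onset_ms) / (peak_ms - onset_ms)
  dn <- gm > peak_ms & gm < 2 * peak_ms - onset_ms
  v[dn] <- amp * (1 - (gm[dn] - peak_ms) / (peak_ms - onset_ms))
  v
}

test_that("filter MSE is the mean squared pointwise difference", {
  g <- seq(0, 0.005, by = 5e-5)
  a <- tibble::tibble(neuron = rep(1:2, each = length(g)),
                      lag = rep(g, 2), value = rnorm(2 * length(g)))
  expect_equal(filter_mse(a, a), 0)
  b <- a; b$value <- a$value + 0.3
  expect_equal(filter_mse(a, b), 0.09, tolerance = 1e-12)
  # 3-point toy grid by hand
  x <- tibble::tibble(neuron = 1, lag = c(0, 1e-3, 2e-3), value = c(1, 2, 3))
  y <- tibble::tibble(neuron = 1, lag = c(0, 1e-3, 2e-3), value = c(0, 0, 0))
  expect_equal(filter_mse(x, y), (1 + 4 + 9) / 3)
  bad <- x; bad$lag <- bad$lag + 1e-5
  expect_error(filter_mse(x, bad), "grids")
})

test_that("cross-correlograms count lagged pairs exactly", {
  pop <- spike_population(
    data.frame(neuron_id = c(1, 2), time = c(0, 0.00104)), duration = 0.01)
  cc <- compute_ccg(pop, 1, 2, bin_ms = 0.1, window = 0.005)
  hit <- cc$bins$count > 0
  expect_equal(sum(cc$bins$count), 1)
  expect_equal(sum(hit), 1)
  # the +1.04 ms pair lands in the bin centred at +1.05 ms
  expect_equal(cc$bins$lag[hit], 0.00105, tolerance = 1e-9)
  # auto-CCG excludes same-spike pairs at lag 0
  cc_auto <- compute_ccg(pop, 1, 1, bin_ms = 0.1, window = 0.005)
  expect_equal(sum(cc_auto$bins$count), 0)
})

test_that("the CCG sweep equals brute force on a moderate instance", {
  sim <- pop_small()
  pop <- sim$population
  cc <- compute_ccg(pop, 1, 4, bin_ms = 0.2, window = 0.005)
  tp <- neuron_times(pop, 1)
  tq <- neuron_times(pop, 4)
  lags <- as.vector(outer(tq, tp, "-"))
  n_half <- ceiling(0.005 / 2e-4)
  breaks <- seq(-n_half, n_half) * 2e-4
  lags <- lags[lags >= breaks[1] & lags <= breaks[length(breaks)]]
  bf <- tabulate(findInterval(lags, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = 2 * n_half)
  expect_equal(cc$bins$count, bf)
})

test_that("independent trains give flat CCGs within counting error", {
  set.seed(9)
  df <- data.frame(
    neuron_id = rep(1:2, each = 1500),
    time = c(sort(runif(1500, 0, 100)), sort(runif(1500, 0, 100)))
  )
  pop <- spike_population(df, duration = 100)
  cc <- compute_ccg(pop, 1, 2, bin_ms = 0.5, window = 0.005)
  expect_gt(stats::chisq.test(cc$bins$count)$p.value, 1e-3)
})

test_that("CCG-filter MSE lives on the log-rate scale", {
  # a synthetic CCG whose counts sit at a known multiple of the chance level
  b <- basis_default()
  cc <- compute_ccg(
    spike_population(data.frame(neuron_id = c(1, 2), time = c(0.1, 0.2)),
                     duration = 100),
    1, 2, bin_ms = 0.5, window = 0.005)
  cc$n_pre <- 10000L
  cc$n_post <- 300L                       # rbar = 3 Hz over T = 100
  expected <- cc$n_pre * cc$bin_width * 3 # chance level = 15 per bin
  zero_fit <- ppglm:::new_ppglm_fit(numeric(2 * 3), log(3), 2L, b, "PA-c",
                                    target = 2)
  # counts exactly at chance vs the zero filter: MSE = 0
  cc$bins$count <- rep(round(expected), nrow(cc$bins))
  expect_equal(ccg_filter_mse(cc, zero_fit), 0, tolerance = 1e-12)
  # doubling all counts shifts the empirical log-rate curve by log 2
  # uniformly, so against the zero filter the MSE becomes (log 2)^2
  cc2 <- cc
  cc2$bins$count <- 2 * cc$bins$count
  expect_equal(ccg_filter_mse(cc2, zero_fit), log(2)^2, tolerance = 1e-12)
})

test_that("screening flags planted filters by peak window, sign and amplitude", {
  g <- seq(0, 0.005, by = 5e-5)
  filters <- dplyr::bind_rows(
    make_filter_tbl(1, 2, triangle_filter(g, 0.5, 1.5, 1), g),   # flagged
    make_filter_tbl(2, 1, triangle_filter(g, 2.0, 3.5, 1), g),   # late peak
    make_filter_tbl(1, 3, -triangle_filter(g, 0.5, 1.5, 1), g),  # inhibitory
    make_filter_tbl(3, 1, triangle_filter(g, 0.4, 1.0, 0.01), g) # too small
  )
  regions <- tibble::tibble(neuron = 1:3, region = c("A", "A", "B"))
  rep <- screen_connections(filters, regions, amp_threshold = 0.1)
  flagged <- rep$pairs[rep$pairs$putative_e, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$pre, 1)
  expect_equal(flagged$post, 2)
  # onset at the 10%-of-peak crossing: 0.6 ms for the planted ramp
  expect_equal(flagged$delay_ms, 0.9, tolerance = 0.06)
  # zero filters everywhere: nothing flagged
  z <- filters
  z$value <- 0
  rep0 <- screen_connections(z, regions, amp_threshold = 0.1)
  expect_equal(sum(rep0$pairs$putative_e), 0)
  expect_true(all(rep0$blocks$fraction_pct == 0))
  expect_error(screen_connections(filters, NULL), "regions")
})

test_that("block pair counts are region-size products under random labelings", {
  g <- seq(0, 0.005, by = 1e-3)
  set.seed(14)
  for (r in 1:5) {
    n <- sample(6:20, 1)
    regions <- tibble::tibble(
      neuron = 1:n,
      region = sample(c("X", "Y", "Z"), n, replace = TRUE)
    )
    pairs <- expand.grid(pre = 1:n, post = 1:n)
    filters <- tibble::tibble(
      pre = rep(pairs$pre, each = length(g)),
      post = rep(pairs$post, each = length(g)),
      lag = rep(g, nrow(pairs)),
      value = 0
    )
    rep <- screen_connections(filters, regions, amp_threshold = 0.1)
    sizes <- table(regions$region)
    for (i in seq_len(nrow(rep$blocks))) {
      expect_equal(
        rep$blocks$pairs_total[i],
        unname(sizes[rep$blocks$region_pre[i]] *
                 sizes[rep$blocks$region_post[i]])
      )
    }
  }
})

test_that("autoplot methods return ggplot objects", {
  sim <- pop_small()
  fit <- fit_pa_c(sim$population, sim$truth$target, basis_default(),
                  range = c(0, 1))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(basis_default()), "ggplot")
  cc <- compute_ccg(sim$population, 1, 4)
  expect_s3_class(autoplot(cc), "ggplot")
})
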