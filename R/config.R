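run_config_keys <- c(
  "estimator", "link", "basis", "n_basis", "window", "alpha", "scale",
  "target", "M", "n_iter", "learning_rate", "ridge", "seed",
  "bin_ms", "batch_bins", "range_mode", "range_width_hz",
  "input", "output", "duration"
)

#' Parse a run configuration file
#'
#' Flat YAML key/value configuration for the fitting workflow. Unknown keys
#' and invalid estimator/link combinations (the PA estimators are derived for
#' the exp link only) are rejected at parse time. Command-line flags override
#' file values in the CLI wrapper.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list merged over the file values.
#' @return A validated list of class `run_config` (missing values filled with
#'   defaults: MC estimator, GL basis with J = 3, H = 5 ms, exp link,
#'   seed 1).
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (!is.list(cfg)) stop("config must be a key/value mapping.", call. = FALSE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad_over <- setdiff(names(overrides), run_config_keys)
  if (length(bad_over)) {
    stop("unknown config key(s): ", paste(bad_over, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(
    estimator = "mc", link = "exp", basis = "gl", n_basis = 3L,
    window = 0.005, alpha = 2, scale = 1.5, target = 1L,
    M = NULL, n_iter = 2000L, learning_rate = 0.01, ridge = 0,
    seed = 1L, bin_ms = 0.1, batch_bins = 10000L,
    range_mode = "mean_centered", range_width_hz = 5
  )
  cfg <- utils::modifyList(defaults, cfg)
  est_ok <- c("mc", "pa-c", "pa-d", "db", "hybrid")
  if (!cfg$estimator %in% est_ok) {
    stop("estimator must be one of: ", paste(est_ok, collapse = ", "),
         call. = FALSE)
  }
  if (!cfg$link %in% c("exp", "softplus")) {
    stop("link must be exp or softplus.", call. = FALSE)
  }
  if (cfg$link == "softplus" && cfg$estimator %in% c("pa-c", "pa-d", "hybrid")) {
    stop("the PA estimators support the exp link only.", call. = FALSE)
  }
  if (!cfg$basis %in% c("gl", "rc")) {
    stop("basis must be gl or rc.", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

config_basis <- function(cfg) {
  if (cfg$basis == "gl") {
    gl_basis(cfg$n_basis, cfg$window, alpha = cfg$alpha, scale = cfg$scale)
  } else {
    rc_basis(cfg$n_basis, cfg$window)
  }
}

#' Fit by estimator name
#'
#' Dispatcher used by the CLI and the benchmark: runs the estimator named in
#' a [parse_config()] object on a spike population.
#'
#' @param pop A [spike_population()].
#' @param cfg A `run_config`.
#' @return A `ppglm_fit`.
#' @export
fit_config <- function(pop, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  b <- config_basis(cfg)
  target <- cfg$target
  range <- list(mode = cfg$range_mode, width_hz = cfg$range_width_hz)
  ctrl <- mc_control(M = cfg$M, n_iter = cfg$n_iter,
                     learning_rate = cfg$learning_rate,
                     ridge = cfg$ridge, seed = cfg$seed)
  switch(
    cfg$estimator,
    "mc" = fit_mc(pop, target, b, control = ctrl, link = cfg$link),
    "hybrid" = fit_hybrid(pop, target, b, range = range, control = ctrl),
    "pa-c" = fit_pa_c(pop, target, b, range = range, ridge = cfg$ridge),
    "pa-d" = fit_pa_d(
      build_design(pop, target, b, cfg$bin_ms * 1e-3, materialize = FALSE),
      range = range, ridge = cfg$ridge),
    "db" = fit_discrete_batched(
      build_design(pop, target, b, cfg$bin_ms * 1e-3, materialize = FALSE),
      batch_bins = min(cfg$batch_bins,
                       ceiling(pop$duration / (cfg$bin_ms * 1e-3))),
      n_iter = cfg$n_iter, learning_rate = cfg$learning_rate,
      seed = cfg$seed, ridge = cfg$ridge)
  )
}

#' Benchmark estimators over simulated sweeps
#'
#' For each grid point the protocol simulates a dataset with known ground
#' truth, fits each requested estimator, and records the filter MSE against
#' the truth plus wall time (informational only). `"duration_sweep"` uses the
#' all-to-one protocol at varying `T`; `"population_sweep"` uses the sparse
#' network at fixed `T`. Per-cell failures are recorded and the sweep
#' continues.
#'
#' @param protocol `"duration_sweep"` or `"population_sweep"`.
#' @param grid Numeric vector: durations in seconds, or population sizes.
#' @param estimators Character subset of `c("mc", "pa-c", "pa-d", "hybrid")`.
#' @param seed Base seed (one simulation per grid point).
#' @param n_iter MC iterations for the mc/hybrid fits.
#' @param duration Recording length for the population sweep (default 100 s).
#' @return A tibble with one row per (grid point, estimator): `grid_value`,
#'   `estimator`, `mse`, `seconds`, `error` (NA unless the cell failed).
#' @export
run_benchmark <- function(protocol = c("duration_sweep", "population_sweep"),
                          grid, estimators = c("mc", "pa-c"), seed = 1,
                          n_iter = 300, duration = 100) {
  protocol <- match.arg(protocol)
  purrr::map_dfr(grid, function(g) {
    sim <- if (protocol == "duration_sweep") {
      simulate_all_to_one(duration = g, seed = seed)
    } else {
      simulate_network(n_neurons = g, duration = duration, seed = seed)
    }
    pop <- sim$population
    target <- if (protocol == "duration_sweep") sim$truth$target else 1L
    truth_filters <- if (protocol == "duration_sweep") {
      coupling_filters(sim)
    } else {
      NULL
    }
    b <- gl_basis(3, window = 0.005)
    purrr::map_dfr(estimators, function(est) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        cfg <- parse_config(overrides = list(
          estimator = est, target = target, n_iter = n_iter, seed = seed,
          range_mode = "mean_centered", range_width_hz = 4))
        fit <- fit_config(pop, cfg)
        mse <- if (!is.null(truth_filters)) {
          filter_mse(coupling_filters(fit), truth_filters)
        } else {
          NA_real_
        }
        list(mse = mse, error = NA_character_)
      }, error = function(e) list(mse = NA_real_,
                                  error = conditionMessage(e)))
      tibble::tibble(
        grid_value = g, estimator = est, mse = res$mse,
        seconds = proc.time()[["elapsed"]] - t0, error = res$error
      )
    })
  })
}
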