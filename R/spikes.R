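#' Construct a spike population from a spike-time table
#'
#' A spike population holds per-neuron sorted spike times on `[0, T]` together
#' with the recording duration `T`. It is the input object for every estimator
#' in the package. Neuron identifiers are relabelled to dense integers
#' `1..N` in order of first appearance; the original labels are retained and
#' reported by [tidy()][tidy.spike_population].
#'
#' @param spikes A data frame with columns `neuron_id` and `time` (seconds),
#'   and optionally `region` (a per-neuron region label used by
#'   [screen_connections()]).
#' @param duration Recording duration `T` in seconds. If `NULL`, the maximum
#'   spike time is used and a warning is issued (the rule used is recorded in
#'   the object's metadata).
#' @return An object of class `spike_population`: a list with elements
#'   `spikes` (tibble with dense integer `neuron` and sorted `time`),
#'   `n_neurons`, `duration`, `labels` (original ids, indexed by dense id),
#'   `regions` (per-neuron region label or `NA`), and `meta`.
#' @examples
#' pop <- spike_population(
#'   data.frame(neuron_id = c("a", "b", "a"), time = c(0.5, 0.1, 0.2)),
#'   duration = 1
#' )
#' pop$n_neurons
#' @export
spike_population <- function(spikes, duration = NULL) {
  stopifnot(is.data.frame(spikes))
  if (!all(c("neuron_id", "time") %in% names(spikes))) {
    stop("`spikes` must have columns `neuron_id` and `time`.", call. = FALSE)
  }
  if (nrow(spikes) == 0L) stop("no spikes supplied.", call. = FALSE)
  time <- as.numeric(spikes$time)
  if (anyNA(time)) stop("missing spike times.", call. = FALSE)
  bad <- which(time < 0)
  if (length(bad)) {
    stop(sprintf("negative spike time at row %d.", bad[1]), call. = FALSE)
  }
  duration_rule <- "supplied"
  if (is.null(duration)) {
    duration <- max(time)
    duration_rule <- "max_spike_time"
    warning("`duration` not supplied; using the last spike time as T.",
            call. = FALSE)
  }
  duration <- as.numeric(duration)
  stopifnot(duration > 0)
  late <- which(time > duration)
  if (length(late)) {
    stop(sprintf("spike time %g at row %d exceeds duration %g.",
                 time[late[1]], late[1], duration), call. = FALSE)
  }

  labels <- unique(as.character(spikes$neuron_id))
  neuron <- match(as.character(spikes$neuron_id), labels)
  n <- length(labels)

  regions <- rep(NA_character_, n)
  if ("region" %in% names(spikes)) {
    reg <- tapply(as.character(spikes$region), neuron, function(r) unique(r)[1])
    regions[as.integer(names(reg))] <- as.character(reg)
  }

  ord <- order(neuron, time)
  neuron <- neuron[ord]
  time <- time[ord]
  dup <- which(diff(time) == 0 & diff(neuron) == 0)
  if (length(dup)) {
    stop(sprintf("duplicate spike time %g for neuron '%s'.",
                 time[dup[1]], labels[neuron[dup[1]]]), call. = FALSE)
  }

  # globally time-sorted view used by all window queries
  gord <- order(time, neuron)
  structure(
    list(
      spikes = tibble::tibble(neuron = neuron, time = time),
      n_neurons = n,
      duration = duration,
      labels = labels,
      regions = regions,
      times_all = time[gord],
      neurons_all = neuron[gord],
      meta = list(duration_rule = duration_rule)
    ),
    class = "spike_population"
  )
}

#' @export
print.spike_population <- function(x, ...) {
  cat(sprintf("<spike_population> %d neurons, %d spikes, T = %g s\n",
              x$n_neurons, nrow(x$spikes), x$duration))
  invisible(x)
}

#' Spike times of one neuron
#'
#' @param pop A [spike_population()].
#' @param neuron Dense neuron index in `1..N`.
#' @return Numeric vector of sorted spike times (seconds).
#' @export
neuron_times <- function(pop, neuron) {
  stopifnot(inherits(pop, "spike_population"),
            neuron >= 1, neuron <= pop$n_neurons)
  pop$spikes$time[pop$spikes$neuron == neuron]
}

#' @export
tidy.spike_population <- function(x, ...) {
  counts <- tabulate(x$spikes$neuron, nbins = x$n_neurons)
  tibble::tibble(
    neuron = seq_len(x$n_neurons),
    label = x$labels,
    region = x$regions,
    n_spikes = counts,
    rate_hz = counts / x$duration
  )
}

#' Read spike times from delimited text
#'
#' Expects two or three columns: `neuron_id`, `time_seconds`, and optionally
#' `region_label`. Comma or tab delimiters are auto-detected, and a header
#' row is recognised when the second field of the first line is not numeric.
#'
#' @param path Path to a CSV/TSV file.
#' @param duration Recording duration in seconds; defaults to the last spike
#'   time with a warning.
#' @return A [spike_population()].
#' @export
read_spikes <- function(path, duration = NULL) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop("empty spike file.", call. = FALSE)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  fields <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- length(fields) >= 2 && is.na(suppressWarnings(as.numeric(fields[2])))
  df <- utils::read.table(path, sep = delim, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("spike file needs at least 2 columns.", call. = FALSE)
  names(df)[1:2] <- c("neuron_id", "time")
  if (ncol(df) >= 3) names(df)[3] <- "region"
  spike_population(df, duration = duration)
}

#' Write spike times to delimited text
#'
#' @param pop A [spike_population()].
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(pop, path) {
  stopifnot(inherits(pop, "spike_population"))
  df <- data.frame(
    neuron_id = pop$labels[pop$spikes$neuron],
    time_seconds = sprintf("%.9f", pop$spikes$time)
  )
  if (any(!is.na(pop$regions))) df$region_label <- pop$regions[pop$spikes$neuron]
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' The document is self-describing: weights, intercept, basis descriptor,
#' estimator tag and seed. [read_model()] reproduces the weights bit-exactly
#' (weights are stored as full-precision hex floats).
#'
#' @param model A `ppglm_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ppglm_fit"))
  doc <- list(
    package = "ppglm",
    estimator = model$estimator,
    n_neurons = model$n_neurons,
    target = model$target,
    weights_hex = sprintf("%a", model$weights),
    intercept_hex = sprintf("%a", model$intercept),
    basis = basis_descriptor(model$basis),
    link = model$link,
    seed = model$meta$seed,
    n_iter = model$meta$n_iter,
    final_objective = model$meta$final_objective
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `ppglm_fit` object.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("estimator", "n_neurons", "weights_hex", "intercept_hex", "basis")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("model file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  b <- basis_from_descriptor(doc$basis)
  new_ppglm_fit(
    weights = as.numeric(doc$weights_hex),
    intercept = as.numeric(doc$intercept_hex),
    n_neurons = doc$n_neurons,
    basis = b,
    estimator = doc$estimator,
    link = if (is.null(doc$link)) "exp" else doc$link,
    target = doc$target,
    meta = list(seed = doc$seed, n_iter = doc$n_iter,
                final_objective = doc$final_objective)
  )
}
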