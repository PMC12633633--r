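#' Mean squared error between filter sets
#'
#' Pointwise MSE on the linear-predictor (log-rate) scale between two filter
#' tables on a common lag grid, averaged over all neurons and lags.
#'
#' @param est,truth Tibbles with columns `neuron`, `lag`, `value` (e.g. from
#'   [coupling_filters()]); must share the same `(neuron, lag)` grid.
#' @return Scalar MSE.
#' @export
filter_mse <- function(est, truth) {
  est <- dplyr::arrange(est, .data$neuron, .data$lag)
  truth <- dplyr::arrange(truth, .data$neuron, .data$lag)
  if (nrow(est) != nrow(truth) ||
      !isTRUE(all.equal(est$lag, truth$lag)) ||
      !identical(est$neuron, truth$neuron)) {
    stop("filter grids do not match.", call. = FALSE)
  }
  mean((est$value - truth$value)^2)
}

#' Cross-correlogram between two spike trains
#'
#' Histogram of spike-time differences `t_post - t_pre` over all pairs with
#' `|lag| <= window`, found by a two-pointer sweep (cost linear in the number
#' of in-window pairs). For auto-CCGs (`pre == post`) same-spike pairs are
#' excluded from the zero-lag bin.
#'
#' @param pop A [spike_population()].
#' @param pre,post Neuron indices.
#' @param bin_ms Lag bin width in milliseconds (default 0.1).
#' @param window Maximum |lag| in seconds (default 5 ms).
#' @return An object of class `ccg`: a list with `bins` (tibble of `lag` bin
#'   centers in seconds and `count`), `pre`, `post`, `n_pre`, `n_post`,
#'   `bin_width`.
#' @export
compute_ccg <- function(pop, pre, post, bin_ms = 0.1, window = 0.005) {
  tp <- neuron_times(pop, pre)
  tq <- neuron_times(pop, post)
  bw <- bin_ms * 1e-3
  n_half <- ceiling(window / bw)
  breaks <- seq(-n_half * bw, n_half * bw, by = bw)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # pairs with |t_post - t_pre| <= edge of outermost bins
  lim <- n_half * bw
  lo <- findInterval(tq - lim, tp, left.open = TRUE)
  hi <- findInterval(tq + lim, tp)
  counts <- pmax(hi - lo, 0L)
  qidx <- rep.int(seq_along(tq), counts)
  sidx <- sequence(counts) + rep.int(lo, counts)
  lag <- tq[qidx] - tp[sidx]
  if (pre == post) lag <- lag[qidx != sidx]  # drop same-spike self pairs
  cnt <- if (length(lag)) {
    idx <- findInterval(lag, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = length(centers))
  } else {
    integer(length(centers))
  }
  structure(
    list(bins = tibble::tibble(lag = centers, count = cnt),
         pre = pre, post = post,
         n_pre = length(tp), n_post = length(tq),
         bin_width = bw, duration = pop$duration),
    class = "ccg"
  )
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> %d -> %d, %d bins of %.2g ms, %d pair counts\n",
              x$pre, x$post, nrow(x$bins), 1000 * x$bin_width,
              sum(x$bins$count)))
  invisible(x)
}

#' Plot a cross-correlogram
#'
#' @param object A [compute_ccg()] result.
#' @param ... Unused.
#' @export
autoplot.ccg <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(1000 * .data$lag, .data$count)) +
    ggplot2::geom_col(width = 1000 * object$bin_width) +
    ggplot2::labs(x = "lag (ms)", y = "pair count",
                  title = sprintf("CCG %d → %d", object$pre, object$post))
}

#' MSE between a CCG and a fitted coupling filter
#'
#' Converts the positive-lag half of the CCG into an empirical log-rate
#' modulation, `log(count / (n_pre * bin_width * rate_post))` (geometric-rate
#' units; empty bins floored at half a count), and compares it to the fitted
#' filter for the same presynaptic neuron on the bin-center grid.
#'
#' @param ccg A [compute_ccg()] result.
#' @param fit A `ppglm_fit` for the CCG's postsynaptic neuron.
#' @return Scalar MSE on the log-rate scale.
#' @export
ccg_filter_mse <- function(ccg, fit) {
  stopifnot(inherits(ccg, "ccg"), inherits(fit, "ppglm_fit"))
  rbar <- ccg$n_post / ccg$duration
  if (rbar <= 0) stop("target rate is zero.", call. = FALSE)
  pos <- ccg$bins[ccg$bins$lag > 0, ]
  expected <- ccg$n_pre * ccg$bin_width * rbar
  emp <- log(pmax(pos$count, 0.5) / expected)
  filt <- coupling_filters(fit, lags = pos$lag)
  est <- filt$value[filt$neuron == ccg$pre]
  mean((emp - est)^2)
}

#' Screen all-pairs filters for putative excitatory connections
#'
#' A directed pair is flagged putative-excitatory when its filter's global
#' maximum is positive, exceeds `amp_threshold`, and peaks at a lag inside
#' `peak_window` (0.3-2.5 ms by default, the monosynaptic latency range).
#' The onset-to-peak delay is measured from the earliest lag at which the
#' filter first exceeds `onset_frac` of its peak. Results are aggregated into
#' region-by-region blocks whose total pair counts are the products of region
#' sizes (self-pairs counted in diagonal blocks).
#'
#' @param filters Tibble with columns `pre`, `post`, `lag` (seconds), `value`
#'   — one filter per ordered neuron pair, on a fine common lag grid
#'   (0.05 ms recommended).
#' @param regions Data frame with columns `neuron`, `region` covering every
#'   neuron.
#' @param peak_window Numeric `c(min, max)` peak lag in seconds.
#' @param amp_threshold Minimum peak amplitude; default is twice the median
#'   absolute filter value across all pairs (a robust null scale).
#' @param onset_frac Fraction of peak defining filter onset (default 0.1).
#' @return An object of class `screening_report`: list with `pairs` (per-pair
#'   peak lag ms, onset-to-peak delay ms, flag) and `blocks` (pair counts,
#'   putative-E counts, fraction %, mean +/- sd delay ms).
#' @export
screen_connections <- function(filters, regions,
                               peak_window = c(0.3e-3, 2.5e-3),
                               amp_threshold = NULL, onset_frac = 0.1) {
  stopifnot(all(c("pre", "post", "lag", "value") %in% names(filters)))
  if (is.null(regions) || !all(c("neuron", "region") %in% names(regions))) {
    stop("`regions` must have columns `neuron` and `region`.", call. = FALSE)
  }
  if (is.null(amp_threshold)) {
    amp_threshold <- 2 * stats::median(abs(filters$value))
  }

  per_pair <- filters |>
    dplyr::group_by(.data$pre, .data$post) |>
    dplyr::summarise(
      peak_value = max(.data$value),
      peak_lag = .data$lag[which.max(.data$value)],
      onset_lag = {
        pk <- max(.data$value)
        idx <- which(.data$value > onset_frac * pk)
        if (length(idx) && pk > 0) .data$lag[idx[1]] else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      putative_e = .data$peak_value > 0 &
        .data$peak_value > amp_threshold &
        .data$peak_lag >= peak_window[1] &
        .data$peak_lag <= peak_window[2],
      delay_ms = 1000 * (.data$peak_lag - .data$onset_lag)
    )

  reg <- regions
  per_pair <- per_pair |>
    dplyr::left_join(dplyr::rename(reg, pre = "neuron", region_pre = "region"),
                     by = "pre") |>
    dplyr::left_join(dplyr::rename(reg, post = "neuron",
                                   region_post = "region"),
                     by = "post")
  if (anyNA(per_pair$region_pre) || anyNA(per_pair$region_post)) {
    stop("missing region labels for some neurons.", call. = FALSE)
  }

  sizes <- reg |> dplyr::count(.data$region, name = "size")
  blocks <- tidyr::expand_grid(
    region_pre = sizes$region, region_post = sizes$region
  ) |>
    dplyr::left_join(dplyr::rename(sizes, region_pre = "region",
                                   size_pre = "size"), by = "region_pre") |>
    dplyr::left_join(dplyr::rename(sizes, region_post = "region",
                                   size_post = "size"), by = "region_post") |>
    dplyr::mutate(pairs_total = .data$size_pre * .data$size_post)

  flagged <- per_pair |>
    dplyr::filter(.data$putative_e) |>
    dplyr::group_by(.data$region_pre, .data$region_post) |>
    dplyr::summarise(
      putative_e = dplyr::n(),
      mean_delay_ms = mean(.data$delay_ms, na.rm = TRUE),
      sd_delay_ms = stats::sd(.data$delay_ms),
      .groups = "drop"
    )

  blocks <- blocks |>
    dplyr::left_join(flagged, by = c("region_pre", "region_post")) |>
    dplyr::mutate(
      putative_e = dplyr::coalesce(.data$putative_e, 0L),
      fraction_pct = 100 * .data$putative_e / .data$pairs_total
    ) |>
    dplyr::select("region_pre", "region_post", "pairs_total", "putative_e",
                  "fraction_pct", "mean_delay_ms", "sd_delay_ms") |>
    dplyr::arrange(dplyr::desc(.data$fraction_pct))

  structure(list(pairs = per_pair, blocks = blocks,
                 amp_threshold = amp_threshold,
                 peak_window = peak_window, onset_frac = onset_frac),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d pairs screened, %d putative excitatory\n",
              nrow(x$pairs), sum(x$pairs$putative_e)))
  print(x$blocks, n = Inf)
  invisible(x)
}

#' Plot a screening report as a region-block matrix
#'
#' @param object A [screen_connections()] result.
#' @param ... Unused.
#' @export
autoplot.screening_report <- function(object, ...) {
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(.data$region_post, .data$region_pre,
                               fill = .data$fraction_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$putative_e, .data$pairs_total))) +
    ggplot2::labs(x = "postsynaptic region", y = "presynaptic region",
                  fill = "putative E (%)")
}
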