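# Spike binning on the imaging frame grid, Gaussian-kernel smoothing,
# z-scoring, stream alignment, and the CS-SS cross-correlogram QA utility.
#
# Rate series move through explicit stages (counts -> rate -> smoothed ->
# zscored), tracked in a `stage` attribute so each step can assert its
# precondition.

rate_stage <- function(x) attr(x, "stage") %||% "unknown"
`%||%` <- function(a, b) if (is.null(a)) b else a

set_stage <- function(x, stage) {
  attr(x, "stage") <- stage
  x
}

#' Bin spike trains onto the frame grid
#'
#' Bin edges are the frame timestamps themselves (nominally 33 ms at
#' ~30 Hz), which guarantees 1:1 alignment with the calcium frames; the
#' last bin is closed on the right. Counts are converted to rates by the
#' per-bin width. Spikes outside the session span are dropped and counted.
#'
#' @param spikes tibble (unit_id, t) of spike times in seconds; an optional
#'   `unit_class` column is carried through
#' @param timeline tibble (frame, t) as from [make_timeline()]
#' @return long tibble (unit_id, frame, t, value) with `stage = "rate"`;
#'   attribute `n_dropped` counts out-of-session spikes
#' @export
bin_spikes <- function(spikes, timeline) {
  check_cols(spikes, c("unit_id", "t"))
  check_cols(timeline, c("frame", "t"))
  dt <- timeline_dt(timeline)
  edges <- c(timeline$t, timeline$t[length(timeline$t)] + dt)
  widths <- diff(edges)
  n_frames <- nrow(timeline)

  in_session <- spikes$t >= edges[1] & spikes$t <= edges[n_frames + 1]
  n_dropped <- sum(!in_session)
  if (n_dropped > 0) {
    message(sprintf("bin_spikes: dropped %d spike(s) outside the session span",
                    n_dropped))
  }
  sp <- spikes[in_session, , drop = FALSE]

  out <- sp %>%
    group_by(.data$unit_id) %>%
    dplyr::group_modify(function(df, key) {
      idx <- findInterval(df$t, edges, rightmost.closed = TRUE)
      counts <- tabulate(idx, nbins = n_frames)
      tibble(frame = timeline$frame, t = timeline$t,
             value = counts / widths)
    }) %>%
    ungroup()
  # units with no in-session spikes still get all-zero series
  missing_units <- setdiff(unique(spikes$unit_id), unique(out$unit_id))
  if (length(missing_units) > 0) {
    out <- bind_rows(out, purrr::map_dfr(missing_units, function(u) {
      tibble(unit_id = u, frame = timeline$frame, t = timeline$t, value = 0)
    })) %>% arrange(.data$unit_id, .data$frame)
  }
  attr(out, "n_dropped") <- n_dropped
  set_stage(out, "rate")
}

# unit-area Gaussian kernel sampled on the frame grid, truncated at +/- 4 sd
gaussian_kernel <- function(sigma, dt) {
  half <- max(1L, ceiling(4 * sigma / dt))
  lags <- (-half):half
  k <- exp(-0.5 * (lags * dt / sigma)^2)
  k / sum(k)
}

# 1-D convolution with reflect or circular padding
smooth_vec <- function(x, kern, pad = c("reflect", "circular")) {
  pad <- match.arg(pad)
  half <- (length(kern) - 1L) / 2L
  n <- length(x)
  xp <- if (pad == "reflect") {
    c(x[pmin(half:1 + 1L, n)], x, x[pmax(n - (1:half), 1L)])
  } else {
    c(x[((n - half + 1L):n - 1L) %% n + 1L], x, x[(0:(half - 1L)) %% n + 1L])
  }
  sm <- stats::filter(xp, kern, method = "convolution", sides = 2)
  as.numeric(sm[(half + 1L):(half + n)])
}

#' Smooth rate series with a Gaussian kernel
#'
#' Convolution with a unit-area Gaussian (sigma 100 ms by default)
#' truncated at +/- 4 sigma. Reflect padding is the display default;
#' circular padding commutes exactly with circular shifts and is used
#' inside shuffle-validity checks.
#'
#' @param rates long tibble (unit_id, frame, t, value) at stage `"rate"`
#' @param sigma kernel standard deviation (s)
#' @param pad `"reflect"` or `"circular"` edge handling
#' @return same shape, stage `"smoothed"`
#' @export
smooth_rate <- function(rates, sigma = 0.1, pad = c("reflect", "circular")) {
  pad <- match.arg(pad)
  check_cols(rates, c("unit_id", "frame", "value"))
  if (!rate_stage(rates) %in% c("rate", "unknown")) {
    abort(paste0("smooth_rate expects stage 'rate', got '", rate_stage(rates), "'"))
  }
  dt <- if ("t" %in% names(rates)) {
    stats::median(diff(sort(unique(rates$t))))
  } else 1 / 30
  if (sigma < dt) {
    warn("kernel sigma is below the bin width; smoothing is under-resolved")
  }
  kern <- gaussian_kernel(sigma, dt)
  out <- rates %>%
    arrange(.data$unit_id, .data$frame) %>%
    group_by(.data$unit_id) %>%
    mutate(value = smooth_vec(.data$value, kern, pad)) %>%
    ungroup()
  set_stage(out, "smoothed")
}

#' Z-score activity per unit over the whole session
#'
#' Population standard deviation (divide by N). Zero-variance units are
#' flagged `degenerate` (values set to 0) rather than erroring, and should
#' be excluded from downstream tests.
#'
#' @param x long tibble with an id column (`unit_id` or `neuron_id`),
#'   `frame`, and `value`
#' @return same shape plus a logical `degenerate` column; stage `"zscored"`
#' @export
zscore_activity <- function(x) {
  id_col <- intersect(c("unit_id", "neuron_id"), names(x))[1]
  if (is.na(id_col)) abort("need a unit_id or neuron_id column")
  check_cols(x, c(id_col, "frame", "value"))
  if (min(table(x[[id_col]])) < 2) abort("need at least 2 frames per unit")
  out <- x %>%
    group_by(.data[[id_col]]) %>%
    mutate(
      .mu = mean(.data$value),
      .sd = sqrt(mean((.data$value - .data$.mu)^2)),
      degenerate = .data$.sd == 0,
      value = ifelse(.data$.sd > 0, (.data$value - .data$.mu) / .data$.sd, 0)
    ) %>%
    ungroup() %>%
    select(-".mu", -".sd")
  n_deg <- out %>% filter(.data$degenerate) %>%
    distinct(.data[[id_col]]) %>% nrow()
  if (n_deg > 0) {
    message(sprintf("zscore_activity: %d degenerate (zero-variance) unit(s) flagged",
                    n_deg))
  }
  set_stage(out, "zscored")
}

#' Align spike-rate and calcium streams to their common frame span
#'
#' Both streams must reference the same frame clock; they are truncated to
#' the overlapping frame range.
#'
#' @param rates long tibble with a `frame` column (cerebellar rate series)
#' @param traces long tibble with a `frame` column (calcium traces)
#' @return list (rates, traces, frames) truncated to the common span
#' @export
align_streams <- function(rates, traces) {
  check_cols(rates, "frame")
  check_cols(traces, "frame")
  lo <- max(min(rates$frame), min(traces$frame))
  hi <- min(max(rates$frame), max(traces$frame))
  if (lo > hi) abort("streams do not overlap in frames")
  st_r <- rate_stage(rates); st_t <- rate_stage(traces)
  list(
    rates = set_stage(filter(rates, .data$frame >= lo, .data$frame <= hi), st_r),
    traces = set_stage(filter(traces, .data$frame >= lo, .data$frame <= hi), st_t),
    frames = lo:hi)
}

#' Cross-correlogram of simple spikes relative to complex spikes
#'
#' Histogram of simple-spike lags (t_SS - t_CS) within +/- `window`,
#' normalized to a rate in Hz per complex spike. For a Purkinje cell this
#' shows the characteristic simple-spike pause immediately after each
#' complex spike.
#'
#' @param ss,cs numeric vectors of spike times (s)
#' @param window maximum absolute lag (s)
#' @param bin histogram bin width (s)
#' @return tibble (lag, count, rate) with `lag` at bin centers
#' @export
cs_ss_crosscorrelogram <- function(ss, cs, window = 0.1, bin = 0.002) {
  if (length(ss) == 0 || length(cs) == 0) {
    abort("both spike trains must be nonempty")
  }
  ss <- sort(ss)
  breaks <- seq(-window, window, by = bin)
  lags <- unlist(lapply(cs, function(ct) {
    lo <- findInterval(ct - window, ss) + 1L
    hi <- findInterval(ct + window, ss)
    if (hi >= lo) ss[lo:hi] - ct else numeric()
  }))
  counts <- if (length(lags) == 0) {
    rep(0L, length(breaks) - 1L)
  } else {
    # clamp exact +window lags into the last bin
    as.integer(table(cut(pmin(pmax(lags, -window), window - 1e-12),
                         breaks = breaks, include.lowest = TRUE)))
  }
  tibble(lag = breaks[-length(breaks)] + bin / 2,
         count = counts,
         rate = counts / (length(cs) * bin))
}
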