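# ROC/AUC modulation classification against a circular-shuffle null,
# peri-event time histograms, population summaries, and movement-confound
# checks.

#' Area under the ROC curve for activity vs a binary indicator
#'
#' AUC = P(activity in an interacting frame > activity in a non-interacting
#' frame) + 1/2 P(equal), computed through the tie-corrected (midrank)
#' Mann-Whitney identity AUC = U / (n1 * n0). 0.5 means no discrimination.
#'
#' @param activity numeric per-frame activity
#' @param indicator logical (or 0/1) per-frame interaction indicator
#' @return AUC in [0, 1]
#' @export
compute_auc <- function(activity, indicator) {
  indicator <- as.logical(indicator)
  if (length(activity) != length(indicator)) {
    abort("activity and indicator must have equal length")
  }
  if (anyNA(activity) || anyNA(indicator)) abort("inputs must not contain NA")
  n1 <- sum(indicator)
  n0 <- sum(!indicator)
  if (n1 == 0 || n0 == 0) {
    abort("indicator must contain both classes")
  }
  r <- rank(activity)
  (sum(r[indicator]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Circularly shift a series
#'
#' Rotation by `shift` frames: element i of the output is element
#' (i - shift) mod L of the input. Preserves the value multiset, mean,
#' variance, and circular autocorrelation exactly.
#'
#' @param x numeric vector
#' @param shift integer shift, `0 <= shift < length(x)`
#' @return rotated vector
#' @export
circular_shift <- function(x, shift) {
  L <- length(x)
  shift <- as.integer(shift)
  if (shift < 0 || shift >= L) abort("need 0 <= shift < length(x)")
  if (shift == 0) return(x)
  x[((seq_len(L) - 1L - shift) %% L) + 1L]
}

# AUC at many circular shifts of the activity, via the rank identity:
# rotating the activity permutes its (fixed) midranks, so each null AUC is
# the sum of ranks falling on indicator frames — a circular
# cross-correlation of the indicator with the rank vector, evaluated at
# every shift with one FFT. Midrank sums live on a half-integer grid, so
# rounding back onto it removes FFT floating error and keeps tie
# comparisons against the observed statistic exact.
shuffle_auc_null <- function(activity, pos_idx, shifts) {
  L <- length(activity)
  r <- rank(activity)
  n1 <- length(pos_idx)
  n0 <- L - n1
  ind <- numeric(L)
  ind[pos_idx] <- 1
  sums_all <- circ_delay(ind, r)
  sums <- round(2 * sums_all[shifts + 1L]) / 2
  (sums - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classify units as positively, negatively, or not modulated
#'
#' For each unit the observed AUC of its per-frame activity against the
#' interaction indicator is compared with a null of `n_shuffles` circular
#' shifts of the activity, with shifts drawn uniformly from
#' `[min_shift, L - min_shift]` frames so that bout-locking is broken
#' despite autocorrelation. Add-one permutation p-values per tail:
#' upper p = (1 + #\{null >= observed\}) / (1 + n_shuffles); a unit is
#' `positive` when the upper-tail p is below `alpha` (0.025 per tail, i.e.
#' two-tailed 0.05), `negative` analogously on the lower tail, else `ns`.
#'
#' @param activity long tibble with an id column (`unit_id` or
#'   `neuron_id`), `frame`, `value` — typically the smoothed z-scored rate
#'   or z-scored calcium trace; a logical `degenerate` column (from
#'   [zscore_activity()]) excludes flagged units
#' @param indicator logical per-frame interaction indicator, aligned to the
#'   frames present in `activity`
#' @param n_shuffles number of circular shifts in the null
#' @param alpha per-tail significance criterion
#' @param min_shift minimum shift (s)
#' @param min_class_frac units are only testable when both indicator
#'   classes occupy at least this fraction of frames; others are returned
#'   `ns` with `flag = "too_few_frames"`
#' @param context label carried into the result (e.g. "social", "object")
#' @param seed RNG seed for the shuffle draws
#' @return tibble of class `modulation_result`: one row per unit with
#'   `auc`, `p_low`, `p_high`, `label`, `flag`
#' @export
classify_modulation <- function(activity, indicator, n_shuffles = 1000,
                                alpha = 0.025, min_shift = 10,
                                min_class_frac = 0.01,
                                context = "social", seed = NULL) {
  id_col <- intersect(c("unit_id", "neuron_id"), names(activity))[1]
  if (is.na(id_col)) abort("need a unit_id or neuron_id column")
  check_cols(activity, c(id_col, "frame", "value"))
  if (alpha <= 0 || alpha >= 0.5) abort("alpha must lie in (0, 0.5)")

  frames <- sort(unique(activity$frame))
  L <- length(frames)
  if (length(indicator) != L) {
    abort("indicator length must match the number of frames in activity")
  }
  indicator <- as.logical(indicator)
  dt <- if ("t" %in% names(activity)) {
    stats::median(diff(sort(unique(activity$t))))
  } else 1 / 30
  min_shift_frames <- max(1L, as.integer(round(min_shift / dt)))
  if (2L * min_shift_frames >= L) {
    abort("min_shift leaves no admissible shifts for this session length")
  }
  pos_idx <- which(indicator)
  frac <- min(length(pos_idx), L - length(pos_idx)) / L

  units <- activity %>%
    arrange(.data[[id_col]], .data$frame) %>%
    dplyr::group_split(.data[[id_col]])

  run_one <- function(df) {
    uid <- df[[id_col]][1]
    degen <- "degenerate" %in% names(df) && isTRUE(df$degenerate[1])
    if (degen) {
      return(tibble(unit_id = uid, context = context, auc = NA_real_,
                    p_low = NA_real_, p_high = NA_real_, label = "ns",
                    flag = "degenerate"))
    }
    if (frac < min_class_frac) {
      return(tibble(unit_id = uid, context = context, auc = NA_real_,
                    p_low = NA_real_, p_high = NA_real_, label = "ns",
                    flag = "too_few_frames"))
    }
    x <- df$value
    obs <- compute_auc(x, indicator)
    shifts <- sample(min_shift_frames:(L - min_shift_frames),
                     n_shuffles, replace = TRUE)
    null <- shuffle_auc_null(x, pos_idx, shifts)
    p_high <- (1 + sum(null >= obs)) / (1 + n_shuffles)
    p_low <- (1 + sum(null <= obs)) / (1 + n_shuffles)
    label <- if (p_high < alpha) "positive"
             else if (p_low < alpha) "negative" else "ns"
    tibble(unit_id = uid, context = context, auc = obs,
           p_low = p_low, p_high = p_high, label = label, flag = NA_character_)
  }

  res <- if (is.null(seed)) {
    purrr::map_dfr(units, run_one)
  } else {
    with_substream(seed, "shuffles", purrr::map_dfr(units, run_one))
  }
  structure(res,
            class = c("modulation_result", class(res)),
            n_shuffles = n_shuffles, alpha = alpha,
            min_shift = min_shift, id_col = id_col)
}

#' @export
tidy.modulation_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.modulation_result <- function(x, ...) {
  tibble(
    n_units = nrow(x),
    n_positive = sum(x$label == "positive"),
    n_negative = sum(x$label == "negative"),
    n_ns = sum(x$label == "ns"),
    n_flagged = sum(!is.na(x$flag)),
    alpha = attr(x, "alpha"),
    n_shuffles = attr(x, "n_shuffles"))
}

#' Peri-event time histogram for one unit
#'
#' Extracts activity around each event at frame resolution, averages across
#' events, and reports the mean trace with its SEM. Events whose window
#' exits the session are excluded and counted. Optional per-event
#' normalization to the pre-event baseline: the baseline mean is
#' subtracted and, where the baseline SD is positive, divided out.
#'
#' @param series tibble (frame, t, value) for a single unit
#' @param event_times event times (s), aligned to `series$t`
#' @param window `c(pre, post)` seconds around the event (both positive)
#' @param baseline NULL, or `c(from, to)` seconds before the event used for
#'   per-event z-normalization (e.g. `c(1, 0)` = the 1 s preceding onset)
#' @return object of class `peth`: aligned events x lags matrix, lag grid,
#'   mean, sem, event bookkeeping
#' @export
compute_peth <- function(series, event_times, window = c(2, 4),
                         baseline = NULL) {
  check_cols(series, c("t", "value"))
  if (length(window) != 2 || any(window < 0)) {
    abort("window must be c(pre, post) with nonnegative entries")
  }
  t <- series$t
  v <- series$value
  dt <- stats::median(diff(t))
  pre_f <- as.integer(round(window[1] / dt))
  post_f <- as.integer(round(window[2] / dt))
  lags <- (-pre_f):post_f
  n <- length(t)

  ev_idx <- vapply(event_times, function(et) which.min(abs(t - et)), integer(1))
  usable <- ev_idx - pre_f >= 1 & ev_idx + post_f <= n
  n_excluded <- sum(!usable)
  ev_idx <- ev_idx[usable]
  if (length(ev_idx) == 0) abort("no events with a full window inside the session")

  mat <- t(vapply(ev_idx, function(i) v[i + lags], numeric(length(lags))))
  flag <- character()
  if (!is.null(baseline)) {
    b_lags <- which(lags * dt >= -abs(baseline[1]) & lags * dt <= -abs(baseline[2]))
    if (length(b_lags) < 2) abort("baseline window too narrow")
    for (r in seq_len(nrow(mat))) {
      mu <- mean(mat[r, b_lags])
      sdb <- sd(mat[r, b_lags])
      mat[r, ] <- mat[r, ] - mu
      if (isTRUE(sdb > 0)) mat[r, ] <- mat[r, ] / sdb
    }
  }
  m <- colMeans(mat)
  sem <- if (nrow(mat) > 1) {
    apply(mat, 2, sd) / sqrt(nrow(mat))
  } else {
    flag <- c(flag, "single_event")
    rep(0, ncol(mat))
  }
  structure(list(matrix = mat, lag = lags * dt, mean = m, sem = sem,
                 n_events = nrow(mat), n_excluded = n_excluded,
                 window = window, flag = flag),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d events (%d excluded), window -%g..+%g s\n",
              x$n_events, x$n_excluded, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
tidy.peth <- function(x, ...) {
  tibble(lag = x$lag, mean = x$mean, sem = x$sem)
}

#' Population summary of modulation labels
#'
#' @param results a `modulation_result` (or several row-bound together)
#' @return tibble (context, label, n, prop) with proportions over all units
#'   in each context
#' @export
population_summary <- function(results) {
  check_cols(results, c("unit_id", "context", "label"))
  results %>%
    group_by(.data$context) %>%
    mutate(.n_total = n()) %>%
    group_by(.data$context, .data$label) %>%
    summarise(n = n(), prop = n() / .data$.n_total[1], .groups = "drop") %>%
    tidyr::complete(context = unique(results$context),
                    label = c("positive", "negative", "ns"),
                    fill = list(n = 0L, prop = 0)) %>%
    arrange(.data$context, .data$label)
}

#' Overlap of significant populations across contexts
#'
#' Fraction of all units significantly modulated (per direction) in both
#' contexts, e.g. both socially and object excited. Unit identities must
#' match across the two result sets.
#'
#' @param res_a,res_b `modulation_result` tibbles over the same units
#' @return tibble (direction, n_overlap, prop) with `prop` a fraction of
#'   all units
#' @export
modulation_overlap <- function(res_a, res_b) {
  check_cols(res_a, c("unit_id", "label"))
  check_cols(res_b, c("unit_id", "label"))
  if (!setequal(res_a$unit_id, res_b$unit_id)) {
    off <- c(setdiff(res_a$unit_id, res_b$unit_id),
             setdiff(res_b$unit_id, res_a$unit_id))
    abort(paste0("unit sets differ between contexts: ",
                 paste(head(off, 10), collapse = ", ")))
  }
  j <- inner_join(select(as_tibble(res_a), "unit_id", label_a = "label"),
                  select(as_tibble(res_b), "unit_id", label_b = "label"),
                  by = "unit_id")
  n_all <- nrow(j)
  purrr::map_dfr(c(positive = "positive", negative = "negative"),
                 function(dir) {
    n_ov <- sum(j$label_a == dir & j$label_b == dir)
    tibble(direction = dir, n_overlap = n_ov, prop = n_ov / n_all)
  })
}

#' Movement-confound check: event-aligned activity vs shuffled event times
#'
#' For each unit, the mean post-event minus pre-event activity difference
#' across movement events is compared with a null built by redrawing the
#' event times uniformly over the admissible session span. A bout-modulated
#' unit whose movement events are placed independently of bouts should be
#' non-significant here at approximately the nominal rate.
#'
#' @param activity long tibble with an id column, `frame`, `t`, `value`
#' @param event_times movement event times (s)
#' @param window `c(pre, post)` seconds
#' @param n_shuffles event-time shuffles in the null
#' @param min_events minimum usable events; below it the unit is skipped
#' @param seed RNG seed
#' @return tibble (unit_id, n_events, delta, p, flag); `delta` is the
#'   post - pre mean difference, `p` a two-sided add-one permutation p
#' @export
movement_confound_check <- function(activity, event_times, window = c(1, 1),
                                    n_shuffles = 500, min_events = 5,
                                    seed = NULL) {
  id_col <- intersect(c("unit_id", "neuron_id"), names(activity))[1]
  if (is.na(id_col)) abort("need a unit_id or neuron_id column")
  check_cols(activity, c(id_col, "t", "value"))
  if (length(event_times) < min_events) {
    message("movement_confound_check: too few events; skipped")
    return(tibble(unit_id = character(), n_events = integer(),
                  delta = numeric(), p = numeric(), flag = character()))
  }
  run <- function() {
    activity %>%
      dplyr::group_split(.data[[id_col]]) %>%
      purrr::map_dfr(function(df) {
        t <- df$t; v <- df$value
        dt <- stats::median(diff(t))
        stat <- function(evs) {
          ds <- vapply(evs, function(et) {
            i <- which.min(abs(t - et))
            pre <- v[t >= et - window[1] & t < et]
            post <- v[t >= et & t <= et + window[2]]
            if (length(pre) == 0 || length(post) == 0) return(NA_real_)
            mean(post) - mean(pre)
          }, numeric(1))
          mean(ds, na.rm = TRUE)
        }
        lo <- min(t) + window[1]
        hi <- max(t) - window[2]
        evs <- event_times[event_times >= lo & event_times <= hi]
        if (length(evs) < min_events) {
          return(tibble(unit_id = df[[id_col]][1], n_events = length(evs),
                        delta = NA_real_, p = NA_real_, flag = "too_few_events"))
        }
        obs <- stat(evs)
        null <- vapply(seq_len(n_shuffles), function(s) {
          stat(runif(length(evs), lo, hi))
        }, numeric(1))
        p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_shuffles)
        tibble(unit_id = df[[id_col]][1], n_events = length(evs),
               delta = obs, p = p, flag = NA_character_)
      })
  }
  if (is.null(seed)) run() else with_substream(seed, "confound", run())
}

#' Empirical false-positive calibration of the modulation classifier
#'
#' Simulates homogeneous (unmodulated) Poisson units over a given bout
#' schedule and runs the full classification chain — frame binning,
#' Gaussian smoothing, z-scoring, AUC against the bout indicator, and the
#' circular-shuffle null — reporting how often each label is assigned.
#' Since the simulated units carry no modulation, the fraction labeled
#' positive estimates the per-tail false-positive rate of the criterion.
#'
#' @param bouts bout schedule (for the indicator)
#' @param timeline session timeline tibble (frame, t)
#' @param n_units number of simulated unmodulated units
#' @param rate homogeneous firing rate (Hz)
#' @param n_shuffles,alpha,min_shift classifier parameters
#' @param kernel_sigma smoothing sigma (s)
#' @param seed master seed (fans out per chunk)
#' @param chunk units processed per batch (memory control)
#' @return tibble (unit_id, label, auc, p_low, p_high)
#' @export
null_calibration <- function(bouts, timeline, n_units = 1000, rate = 20,
                             n_shuffles = 1000, alpha = 0.025, min_shift = 10,
                             kernel_sigma = 0.1, seed = 1, chunk = 50) {
  n_frames <- nrow(timeline)
  ind <- bout_indicator(bouts, n_frames)
  dur <- n_frames * timeline_dt(timeline)
  starts <- seq(1L, n_units, by = chunk)
  purrr::map_dfr(seq_along(starts), function(ci) {
    ids <- starts[ci]:min(starts[ci] + chunk - 1L, n_units)
    spikes <- with_substream(seed, paste0("nullcal-spikes-", ci), {
      purrr::map_dfr(ids, function(u) {
        tibble(unit_id = sprintf("null%04d", u),
               t = sort(runif(rpois(1, rate * dur), 0, dur)))
      })
    })
    z <- suppressMessages(
      zscore_activity(smooth_rate(bin_spikes(spikes, timeline),
                                  sigma = kernel_sigma)))
    res <- classify_modulation(z, ind, n_shuffles = n_shuffles,
                               alpha = alpha, min_shift = min_shift,
                               seed = substream_seed(seed, paste0("nullcal-", ci)))
    select(as_tibble(res), "unit_id", "label", "auc", "p_low", "p_high")
  })
}
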