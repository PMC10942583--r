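# Pairwise cerebellum-ACC Pearson correlations with circular-shift
# surrogate significance, in full-session or non-social (off-bout) epochs.
#
# Surrogates follow the shift-then-mask construction: the intact calcium
# trace is circularly shifted, then the epoch mask is applied, preserving
# the within-epoch autocorrelation structure of the surrogate. The null is
# evaluated exactly at every admissible shift via FFT cross-correlation
# identities and sampled at the drawn shifts.

#' Build an epoch usability mask
#'
#' `full` uses every frame; `offbout` excludes every bout frame dilated by
#' `pad` seconds on each side (to absorb the 1-4 s response tails that
#' outlast a bout).
#'
#' @param bouts bout tibble (`onset_frame`, `offset_frame`, half-open) or
#'   `onset_t`/`offset_t` in seconds
#' @param timeline tibble (frame, t)
#' @param mode `"full"` or `"offbout"`
#' @param pad dilation (s) applied around bouts in offbout mode
#' @param min_usable minimum usable frames required in offbout mode
#' @return tibble (frame, t, usable) with attribute `mode`
#' @export
build_epoch_mask <- function(bouts, timeline, mode = c("full", "offbout"),
                             pad = 1, min_usable = 300) {
  mode <- match.arg(mode)
  check_cols(timeline, c("frame", "t"))
  usable <- rep(TRUE, nrow(timeline))
  if (mode == "offbout" && nrow(bouts) > 0) {
    check_cols(bouts, c("onset_t", "offset_t"))
    for (i in seq_len(nrow(bouts))) {
      usable[timeline$t >= bouts$onset_t[i] - pad &
             timeline$t < bouts$offset_t[i] + pad] <- FALSE
    }
    if (sum(usable) < min_usable) {
      abort(sprintf(
        "offbout mask leaves %d usable frames (< %d required)",
        sum(usable), min_usable))
    }
  }
  out <- tibble(frame = timeline$frame, t = timeline$t, usable = usable)
  attr(out, "mode") <- mode
  out
}

#' Pearson correlation over usable frames
#'
#' Masked frames are removed and the remaining segments concatenated before
#' the correlation is taken.
#'
#' @param x,y aligned numeric series
#' @param mask logical usable-frame vector (NULL = all frames)
#' @return Pearson r, or NA (with a warning) when either series is
#'   constant on the mask
#' @export
pair_correlation <- function(x, y, mask = NULL) {
  if (length(x) != length(y)) abort("series must have equal length")
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  if (length(mask) != length(x)) abort("mask length must match the series")
  xs <- x[mask]; ys <- y[mask]
  if (length(xs) < 3) abort("fewer than 3 usable frames")
  if (sd(xs) == 0 || sd(ys) == 0) {
    warn("constant series on mask: correlation undefined (degenerate)")
    return(NA_real_)
  }
  cor(xs, ys)
}

# Exact surrogate r at every circular shift s of y (shift-then-mask), via
# three FFT cross-correlations. Returns a length-L vector indexed by shift.
surrogate_r_all_shifts <- function(x, y, mask) {
  m <- as.numeric(mask)
  nm <- sum(m)
  mx <- m * x
  Sx <- sum(mx)
  Sxx <- sum(m * x^2)
  vx <- Sxx - Sx^2 / nm
  dxy <- circ_delay(mx, y)
  dy <- circ_delay(m, y)
  dyy <- circ_delay(m, y^2)
  num <- dxy - Sx * dy / nm
  vy <- pmax(dyy - dy^2 / nm, 0)
  den <- sqrt(pmax(vx, 0) * vy)
  ifelse(den > 0, num / den, NA_real_)
}

#' Surrogate significance of one spike-rate / calcium-trace pair
#'
#' The observed Pearson r on usable frames is compared with `n_shuffles`
#' circular shifts of the full-length calcium trace (shift >= `min_shift`),
#' with the epoch mask applied after shifting. Two-sided add-one surrogate
#' p; significance at `corr_alpha` with the sign of the observed r.
#'
#' @param x cerebellar per-frame rate series (numeric)
#' @param y ACC calcium trace (numeric, same frames)
#' @param mask logical usable-frame vector (NULL = all frames)
#' @param n_shuffles surrogate count
#' @param corr_alpha two-sided significance level
#' @param min_shift minimum shift (s)
#' @param dt frame interval (s), used to convert `min_shift` to frames
#' @param seed RNG seed
#' @return one-row tibble (r, p, sig, sign, n_usable, flag)
#' @export
surrogate_significance <- function(x, y, mask = NULL, n_shuffles = 1000,
                                   corr_alpha = 0.05, min_shift = 10,
                                   dt = 1 / 30, seed = NULL) {
  L <- length(x)
  if (is.null(mask)) mask <- rep(TRUE, L)
  if (sd(x[mask]) == 0 || sd(y[mask]) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, sig = FALSE,
                  sign = NA_character_, n_usable = sum(mask),
                  flag = "degenerate"))
  }
  obs <- pair_correlation(x, y, mask)
  min_shift_frames <- max(1L, as.integer(round(min_shift / dt)))
  if (2L * min_shift_frames >= L) {
    abort("min_shift leaves no admissible shifts for this session length")
  }
  draw <- function() sample(min_shift_frames:(L - min_shift_frames),
                            n_shuffles, replace = TRUE)
  shifts <- if (is.null(seed)) draw() else with_substream(seed, "surrogates", draw())
  r_all <- surrogate_r_all_shifts(x, y, mask)
  null <- r_all[shifts + 1L]
  null <- null[!is.na(null)]
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + length(null))
  sig <- p < corr_alpha
  tibble(r = obs, p = p, sig = sig,
         sign = ifelse(sig, ifelse(obs > 0, "positive", "negative"), NA_character_),
         n_usable = sum(mask), flag = NA_character_)
}

#' Correlate every cerebellar-unit x ACC-neuron pair
#'
#' Runs [surrogate_significance()] for each pair over the given epoch mask.
#' Degenerate series (constant on the mask) are excluded with a diagnostic
#' flag. Modulation labels, when supplied, are attached to each pair for
#' class summaries.
#'
#' @param rates long tibble (unit_id, frame, value) of cerebellar rate
#'   series (smoothed z-scored)
#' @param traces long tibble (neuron_id, frame, value) of z-scored calcium
#'   traces on the same frames
#' @param mask epoch mask from [build_epoch_mask()] (NULL = full session)
#' @param cb_labels,acc_labels optional tibbles (unit_id/neuron_id, label)
#'   from [classify_modulation()]
#' @param n_shuffles,corr_alpha,min_shift,seed surrogate parameters
#' @return tibble of class `pair_corr`: one row per pair with labels, mode,
#'   r, p, sig, sign
#' @export
correlate_pairs <- function(rates, traces, mask = NULL,
                            cb_labels = NULL, acc_labels = NULL,
                            n_shuffles = 1000, corr_alpha = 0.05,
                            min_shift = 10, seed = NULL) {
  check_cols(rates, c("unit_id", "frame", "value"))
  check_cols(traces, c("neuron_id", "frame", "value"))
  al <- align_streams(rates, traces)
  frames <- al$frames
  L <- length(frames)
  dt <- if ("t" %in% names(rates)) stats::median(diff(sort(unique(rates$t)))) else 1 / 30

  usable <- if (is.null(mask)) rep(TRUE, L) else {
    check_cols(mask, c("frame", "usable"))
    mask$usable[match(frames, mask$frame)]
  }
  mode <- if (is.null(mask)) "full" else attr(mask, "mode") %||% "full"

  xm <- al$rates %>% arrange(.data$unit_id, .data$frame) %>%
    tidyr::pivot_wider(id_cols = "frame", names_from = "unit_id",
                       values_from = "value") %>% arrange(.data$frame)
  ym <- al$traces %>% arrange(.data$neuron_id, .data$frame) %>%
    tidyr::pivot_wider(id_cols = "frame", names_from = "neuron_id",
                       values_from = "value") %>% arrange(.data$frame)
  cb_ids <- setdiff(names(xm), "frame")
  acc_ids <- setdiff(names(ym), "frame")

  run <- function() {
    purrr::map_dfr(cb_ids, function(cu) {
      x <- xm[[cu]]
      purrr::map_dfr(acc_ids, function(an) {
        res <- surrogate_significance(x, ym[[an]], usable,
                                      n_shuffles = n_shuffles,
                                      corr_alpha = corr_alpha,
                                      min_shift = min_shift, dt = dt,
                                      seed = NULL)
        mutate(res, cb_unit = cu, acc_neuron = an, mode = mode,
               .before = 1)
      })
    })
  }
  out <- if (is.null(seed)) run() else with_substream(seed, "pairs", run())

  if (!is.null(cb_labels)) {
    out <- left_join(out, select(as_tibble(cb_labels), cb_unit = "unit_id",
                                 cb_label = "label"), by = "cb_unit")
  }
  if (!is.null(acc_labels)) {
    out <- left_join(out, select(as_tibble(acc_labels), acc_neuron = "neuron_id",
                                 acc_label = "label"), by = "acc_neuron")
  }
  structure(out, class = c("pair_corr", class(out)),
            corr_alpha = corr_alpha, n_shuffles = n_shuffles)
}

#' @export
tidy.pair_corr <- function(x, ...) as_tibble(x)

#' @export
glance.pair_corr <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_sig_positive = sum(x$sig & x$sign == "positive", na.rm = TRUE),
         n_sig_negative = sum(x$sig & x$sign == "negative", na.rm = TRUE),
         n_degenerate = sum(!is.na(x$flag) & x$flag == "degenerate"),
         corr_alpha = attr(x, "corr_alpha"))
}

#' Summarize pair correlations by modulation-class pair
#'
#' Cumulative r distributions keyed by (cerebellar label, ACC label, epoch
#' mode), and matrices of the percentage of pairs with significant positive
#' or negative correlations. Class cells with no pairs are reported as
#' missing, not zero.
#'
#' @param pairs a `pair_corr` tibble carrying `cb_label` and `acc_label`
#' @return list of class `pair_class_summary` with `distributions` (raw r
#'   values per class cell) and `matrices` (pct_sig_pos / pct_sig_neg per
#'   cell)
#' @export
class_summary <- function(pairs) {
  check_cols(pairs, c("cb_unit", "acc_neuron", "mode", "r", "sig",
                      "cb_label", "acc_label"))
  ok <- !is.na(pairs$r)
  dist <- pairs %>% filter(ok) %>%
    select("cb_label", "acc_label", "mode", "r") %>%
    arrange(.data$cb_label, .data$acc_label, .data$mode, .data$r)
  mats <- pairs %>% filter(ok) %>%
    group_by(.data$cb_label, .data$acc_label, .data$mode) %>%
    summarise(
      n_pairs = n(),
      pct_sig_pos = 100 * mean(.data$sig & !is.na(.data$sign) &
                                 .data$sign == "positive"),
      pct_sig_neg = 100 * mean(.data$sig & !is.na(.data$sign) &
                                 .data$sign == "negative"),
      median_r = stats::median(.data$r),
      .groups = "drop") %>%
    tidyr::complete(cb_label = unique(pairs$cb_label),
                    acc_label = unique(pairs$acc_label),
                    mode = unique(pairs$mode))
  structure(list(distributions = dist, matrices = mats),
            class = "pair_class_summary")
}

#' @export
print.pair_class_summary <- function(x, ...) {
  cat("<pair_class_summary>\n")
  print(x$matrices)
  invisible(x)
}
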