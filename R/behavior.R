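# Bout detection from position tracks and kinematic series (speed, head
# angular speed) with hysteresis movement-event detection.

#' Flag interaction frames by nose-to-target proximity
#'
#' A frame is flagged when the distance from the subject's nose to any of
#' the target's nose, body centroid, or tail base is at or below the
#' proximity threshold (2 cm in the standard protocol). The contact tag is
#' the nearest target part. Masked frames (target absent or tracking lost)
#' are never flagged.
#'
#' @param positions tibble with per-frame coordinates in mm:
#'   `sub_nose_x/y`, `tgt_nose_x/y`, `tgt_body_x/y`, `tgt_tail_x/y`, and
#'   optionally a logical `valid` mask, plus `frame` and `t`
#' @param threshold_mm proximity criterion (mm)
#' @return tibble (frame, t, interacting, tag, dist_mm); `tag` is one of
#'   nose-nose / nose-body / nose-rear, NA where not interacting
#' @export
detect_interaction_frames <- function(positions, threshold_mm = 20) {
  check_cols(positions, c("frame", "t", "sub_nose_x", "sub_nose_y",
                          "tgt_nose_x", "tgt_nose_y", "tgt_body_x",
                          "tgt_body_y", "tgt_tail_x", "tgt_tail_y"))
  if (threshold_mm <= 0) abort("threshold_mm must be > 0")
  d_part <- function(px, py) {
    sqrt((positions$sub_nose_x - px)^2 + (positions$sub_nose_y - py)^2)
  }
  d <- cbind(`nose-nose` = d_part(positions$tgt_nose_x, positions$tgt_nose_y),
             `nose-body` = d_part(positions$tgt_body_x, positions$tgt_body_y),
             `nose-rear` = d_part(positions$tgt_tail_x, positions$tgt_tail_y))
  masked <- apply(d, 1, function(r) all(is.na(r)))
  if (!is.null(positions$valid)) masked <- masked | !positions$valid
  if (all(masked)) {
    abort("all frames are masked: no valid target coordinates to test")
  }
  dmin <- suppressWarnings(apply(d, 1, min, na.rm = TRUE))
  dmin[masked | !is.finite(dmin)] <- NA_real_
  interacting <- !is.na(dmin) & dmin <= threshold_mm
  nearest <- colnames(d)[apply(replace(d, is.na(d), Inf), 1, which.min)]
  tibble(frame = positions$frame, t = positions$t,
         interacting = interacting,
         tag = ifelse(interacting, nearest, NA_character_),
         dist_mm = dmin)
}

#' Assemble interaction bouts from a per-frame indicator
#'
#' Maximal runs of flagged frames become bouts; runs separated by a gap
#' shorter than `merge_gap` are merged; merged runs shorter than
#' `min_duration` are dropped. Bouts are half-open frame intervals
#' `[onset_frame, offset_frame)`. Per-bout tags are the modal contact tag
#' over the bout's flagged frames when a `tag` column is present.
#'
#' @param frames output of [detect_interaction_frames()] (or any tibble
#'   with `frame`, `t`, and logical `interacting`)
#' @param min_duration minimum bout length (s); default suppresses
#'   single-frame tracking jitter
#' @param merge_gap gaps shorter than this (s) are bridged
#' @param frame_rate frames per second; inferred from `t` when NULL
#' @return tibble (bout, onset_frame, offset_frame, onset_t, offset_t,
#'   n_frames, tag) of class `bout_set`
#' @export
assemble_bouts <- function(frames, min_duration = 0.2, merge_gap = 0.5,
                           frame_rate = NULL) {
  check_cols(frames, c("frame", "interacting"))
  ind <- as.logical(frames$interacting)
  n <- length(ind)
  if (is.null(frame_rate)) {
    frame_rate <- if ("t" %in% names(frames) && n > 1) {
      1 / stats::median(diff(frames$t))
    } else 30
  }
  empty <- tibble(bout = integer(), onset_frame = integer(),
                  offset_frame = integer(), onset_t = numeric(),
                  offset_t = numeric(), n_frames = integer(),
                  tag = character())
  if (!any(ind)) return(structure(empty, class = c("bout_set", class(empty))))

  r <- rle(ind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])  # 1-based inclusive

  # merge runs separated by < merge_gap seconds
  gap_frames <- merge_gap * frame_rate
  if (nrow(runs) > 1) {
    keep_start <- runs$start
    keep_end <- runs$end
    merged <- list()
    cs <- keep_start[1]; ce <- keep_end[1]
    for (i in 2:nrow(runs)) {
      if ((keep_start[i] - ce - 1L) < gap_frames) {
        ce <- keep_end[i]
      } else {
        merged[[length(merged) + 1]] <- c(cs, ce)
        cs <- keep_start[i]; ce <- keep_end[i]
      }
    }
    merged[[length(merged) + 1]] <- c(cs, ce)
    runs <- tibble(start = vapply(merged, `[`, integer(1), 1),
                   end = vapply(merged, `[`, integer(1), 2))
  }

  min_frames <- min_duration * frame_rate
  runs <- runs %>% filter((.data$end - .data$start + 1L) >= min_frames)
  if (nrow(runs) == 0) return(structure(empty, class = c("bout_set", class(empty))))

  frame0 <- frames$frame[1]
  t_of <- function(idx) {
    if ("t" %in% names(frames)) frames$t[idx] else (idx - 1) / frame_rate
  }
  tags <- vapply(seq_len(nrow(runs)), function(i) {
    if (!"tag" %in% names(frames)) return(NA_character_)
    tg <- frames$tag[runs$start[i]:runs$end[i]]
    tg <- tg[!is.na(tg)]
    if (length(tg) == 0) NA_character_ else names(sort(table(tg), decreasing = TRUE))[1]
  }, character(1))

  out <- tibble(
    bout = seq_len(nrow(runs)),
    onset_frame = frame0 + runs$start - 1L,
    offset_frame = frame0 + runs$end,      # half-open
    onset_t = t_of(runs$start),
    offset_t = t_of(pmin(runs$end + 1L, n)),
    n_frames = runs$end - runs$start + 1L,
    tag = tags)
  structure(out, class = c("bout_set", class(out)))
}

#' Per-frame logical indicator from a bout set
#'
#' @param bouts tibble with `onset_frame`, `offset_frame` (half-open,
#'   0-based frames)
#' @param n_frames session length in frames
#' @return logical vector of length `n_frames`
#' @export
bout_indicator <- function(bouts, n_frames) {
  check_cols(bouts, c("onset_frame", "offset_frame"))
  indicator_from_bouts(bouts, n_frames)
}

#' Compute speed and head angular speed from the head-mounted LED track
#'
#' Speed is the centered-difference LED displacement over time; heading is
#' the direction of displacement; angular speed is the absolute wrapped
#' heading change per unit time. Both are median-filtered. Heading is
#' unreliable when the animal is nearly stationary, so angular speed is
#' reported as 0 and masked below `low_speed` mm/s.
#'
#' @param positions tibble with `frame`, `t`, `led_x`, `led_y`
#' @param median_width odd width (frames) of the median filter
#' @param low_speed speed (mm/s) below which heading is masked
#' @return tibble (frame, t, speed, ang_speed, speed_ok) with speed in
#'   mm/s and angular speed in deg/s
#' @export
compute_kinematics <- function(positions, median_width = 5, low_speed = 20) {
  check_cols(positions, c("frame", "t", "led_x", "led_y"))
  ok <- complete.cases(positions[, c("led_x", "led_y")])
  if (sum(ok) < 3) abort("need at least 3 valid LED frames")
  t <- positions$t
  x <- positions$led_x
  y <- positions$led_y
  n <- length(t)
  ip <- c(2:n, n)     # forward neighbor (one-sided at the ends)
  im <- c(1, 1:(n - 1))
  dtc <- t[ip] - t[im]
  vx <- (x[ip] - x[im]) / dtc
  vy <- (y[ip] - y[im]) / dtc
  speed <- sqrt(vx^2 + vy^2)
  heading <- atan2(vy, vx)
  dh <- (heading[ip] - heading[im] + pi) %% (2 * pi) - pi
  ang <- abs(dh) / dtc * 180 / pi
  if (median_width > 1) {
    w <- median_width + (median_width %% 2 == 0)  # runmed needs odd width
    speed <- as.numeric(runmed(speed, w, endrule = "median"))
    ang <- as.numeric(runmed(ang, w, endrule = "median"))
  }
  speed_ok <- speed >= low_speed
  ang[!speed_ok] <- 0
  tibble(frame = positions$frame, t = t, speed = speed, ang_speed = ang,
         speed_ok = speed_ok)
}

#' Detect locomotion and head-rotation events with hysteresis
#'
#' A locomotion onset fires when speed crosses above `on_thresh` after the
#' signal has stayed at or below `off_thresh` for at least `refractory`
#' seconds; offsets are symmetric (speed falls to or below `off_thresh`
#' after at least `refractory` above). Head-rotation onsets are detected
#' the same way on angular speed.
#'
#' @param kin output of [compute_kinematics()]
#' @param on_thresh,off_thresh locomotion thresholds (mm/s),
#'   `on_thresh > off_thresh`
#' @param refractory minimum dwell (s) in the opposite state
#' @param rot_on_thresh,rot_off_thresh angular-speed thresholds (deg/s)
#' @return tibble (event, frame, t) with event in
#'   {locomotion_onset, locomotion_offset, rotation_onset}
#' @export
detect_movement_events <- function(kin, on_thresh = 50, off_thresh = 20,
                                   refractory = 1,
                                   rot_on_thresh = 90, rot_off_thresh = 30) {
  check_cols(kin, c("frame", "t", "speed", "ang_speed"))
  if (on_thresh <= off_thresh) abort("need on_thresh > off_thresh (hysteresis)")
  if (rot_on_thresh <= rot_off_thresh) {
    abort("need rot_on_thresh > rot_off_thresh (hysteresis)")
  }
  loco <- hysteresis_events(kin$speed, kin$t, on_thresh, off_thresh, refractory)
  rot <- hysteresis_events(kin$ang_speed, kin$t, rot_on_thresh,
                           rot_off_thresh, refractory)
  bind_rows(
    tibble(event = "locomotion_onset", idx = loco$onsets),
    tibble(event = "locomotion_offset", idx = loco$offsets),
    tibble(event = "rotation_onset", idx = rot$onsets)) %>%
    mutate(frame = kin$frame[.data$idx], t = kin$t[.data$idx]) %>%
    select("event", "frame", "t") %>%
    arrange(.data$t, .data$event)
}

# shared hysteresis state machine; returns onset/offset indices
hysteresis_events <- function(x, t, on_thresh, off_thresh, refractory) {
  n <- length(x)
  onsets <- integer(); offsets <- integer()
  moving <- FALSE
  below_since <- t[1]   # start of the current continuous low period
  above_since <- -Inf   # start of the current continuous high period
  for (i in seq_len(n)) {
    if (!moving) {
      if (x[i] > off_thresh && x[i] < on_thresh) {
        # between thresholds: low dwell is interrupted
        below_since <- NA_real_
      }
      if (x[i] <= off_thresh && is.na(below_since)) below_since <- t[i]
      if (x[i] >= on_thresh) {
        if (!is.na(below_since) && (t[i] - below_since) >= refractory) {
          onsets <- c(onsets, i)
          moving <- TRUE
          above_since <- t[i]
        }
        below_since <- NA_real_
      }
    } else {
      if (x[i] < on_thresh && x[i] > off_thresh) above_since <- NA_real_
      if (x[i] >= on_thresh && is.na(above_since)) above_since <- t[i]
      if (x[i] <= off_thresh) {
        if (!is.na(above_since) && (t[i] - above_since) >= refractory) {
          offsets <- c(offsets, i)
          moving <- FALSE
          below_since <- t[i]
        }
        above_since <- NA_real_
      }
    }
  }
  list(onsets = onsets, offsets = offsets)
}
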