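# Synthetic joint-session generator: arena behavior, inhomogeneous Poisson
# spike trains, and calcium transients with planted bout-locked modulation
# and cross-region coupling. Ground truth is returned alongside every
# simulated stream so recovery can be tested end to end.

#' Configuration for a synthetic joint session
#'
#' Defaults emulate one recording session: a 48 x 48 cm arena, ~1 min of
#' baseline before the target animal is introduced followed by 7 min of
#' interaction, ~30 Hz frame clock, Purkinje-cell (PC) simple-spike trains
#' with high baseline rates, dentate-nucleus (DN) units, and a population of
#' anterior-cingulate (ACC) neurons observed through calcium transients.
#' Bout-locked suppression windows last 1--3 s (PC convention) and
#' excitation windows 2--4 s (DN convention) after each interaction onset.
#'
#' @param arena_size arena side length (mm)
#' @param session_duration total session length (s)
#' @param baseline_duration no-target baseline at the start (s)
#' @param frame_rate frame clock (Hz)
#' @param n_pc,n_dn,n_acc unit counts per region
#' @param class_fractions named list (pc, dn, acc) of label proportions
#'   (positive / negative / ns); each must sum to 1
#' @param baseline_rate_range named list (pc, dn, acc) of uniform ranges (Hz)
#'   for baseline spike or calcium-event rates
#' @param modulation_amplitude fractional rate change during a modulation
#'   window: negative units multiply the baseline by (1 - amplitude),
#'   positive units by (1 + amplitude)
#' @param suppression_duration range (s) of per-bout suppression windows
#' @param excitation_duration range (s) of per-bout excitation windows
#' @param n_bouts number of scheduled approach episodes
#' @param bout_duration_range range (s) of episode durations
#' @param proximity_threshold interaction distance criterion (mm)
#' @param contact_distance nose-to-part distance held during an episode (mm)
#' @param slowdown multiplicative speed factor applied to the subject during
#'   episodes (animals slow down upon interaction)
#' @param coupling_strength shared-latent gain for planted cerebello-cortical
#'   pairs (log-rate units; 0 disables coupling)
#' @param n_coupled number of planted coupled pairs
#' @param coupling_during `"always"` or `"bouts"`: whether the shared latent
#'   is delivered throughout the session or gated to interaction bouts
#' @param calcium_rise,calcium_decay double-exponential kernel time
#'   constants (s); GCaMP6f-like defaults
#' @param noise_sd additive Gaussian trace noise (kernel peak = 1)
#' @param cs_rate complex-spike rate (Hz) when PC complex spikes are simulated
#' @param cs_pause simple-spike pause after each complex spike (s)
#' @param simulate_cs whether to add complex-spike trains for PC units
#' @param seed master seed; all stages draw from named substreams of it
#' @return a `synth_config` list
#' @export
synth_config <- function(arena_size = 480,
                         session_duration = 480,
                         baseline_duration = 60,
                         frame_rate = 30,
                         n_pc = 4, n_dn = 5, n_acc = 100,
                         class_fractions = list(
                           pc  = c(positive = 0.11, negative = 0.29, ns = 0.60),
                           dn  = c(positive = 0.20, negative = 0.12, ns = 0.68),
                           acc = c(positive = 0.04, negative = 0.05, ns = 0.91)),
                         baseline_rate_range = list(
                           pc = c(40, 100), dn = c(20, 60), acc = c(0.15, 0.6)),
                         modulation_amplitude = 0.5,
                         suppression_duration = c(1, 3),
                         excitation_duration = c(2, 4),
                         n_bouts = 35,
                         bout_duration_range = c(1, 3),
                         proximity_threshold = 20,
                         contact_distance = 10,
                         slowdown = 0.4,
                         coupling_strength = 0,
                         n_coupled = 0,
                         coupling_during = c("always", "bouts"),
                         calcium_rise = 0.05,
                         calcium_decay = 0.4,
                         noise_sd = 0.1,
                         cs_rate = 1,
                         cs_pause = 0.04,
                         simulate_cs = FALSE,
                         seed = 1L) {
  coupling_during <- match.arg(coupling_during)
  cfg <- list(
    arena_size = arena_size, session_duration = session_duration,
    baseline_duration = baseline_duration, frame_rate = frame_rate,
    n_pc = n_pc, n_dn = n_dn, n_acc = n_acc,
    class_fractions = class_fractions,
    baseline_rate_range = baseline_rate_range,
    modulation_amplitude = modulation_amplitude,
    suppression_duration = suppression_duration,
    excitation_duration = excitation_duration,
    n_bouts = n_bouts, bout_duration_range = bout_duration_range,
    proximity_threshold = proximity_threshold,
    contact_distance = contact_distance, slowdown = slowdown,
    coupling_strength = coupling_strength, n_coupled = n_coupled,
    coupling_during = coupling_during,
    calcium_rise = calcium_rise, calcium_decay = calcium_decay,
    noise_sd = noise_sd, cs_rate = cs_rate, cs_pause = cs_pause,
    simulate_cs = simulate_cs, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$frame_rate <= 0) abort("frame_rate must be > 0")
  if (cfg$arena_size <= 0) abort("arena_size must be > 0")
  if (cfg$session_duration <= cfg$baseline_duration) {
    abort("session_duration must exceed baseline_duration")
  }
  for (rg in list(cfg$suppression_duration, cfg$excitation_duration,
                  cfg$bout_duration_range)) {
    if (length(rg) != 2 || any(rg <= 0) || rg[2] < rg[1]) {
      abort("duration ranges must be positive increasing pairs")
    }
  }
  for (nm in c("pc", "dn", "acc")) {
    fr <- cfg$class_fractions[[nm]]
    if (abs(sum(fr) - 1) > 1e-8) {
      abort(paste0("class_fractions$", nm, " must sum to 1"))
    }
    if (any(fr < 0)) abort("class fractions must be nonnegative")
    if (any(cfg$baseline_rate_range[[nm]] <= 0)) {
      abort("baseline rates must be positive")
    }
  }
  if (cfg$modulation_amplitude < 0 || cfg$modulation_amplitude > 1) {
    abort("modulation_amplitude must lie in [0, 1]")
  }
  if (cfg$calcium_decay <= cfg$calcium_rise) {
    abort("calcium_decay must exceed calcium_rise")
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Behavior

#' Simulate arena behavior with scheduled interaction episodes
#'
#' Subject and target follow Ornstein--Uhlenbeck smoothed random walks with
#' reflecting arena walls. During each scheduled approach episode the tagged
#' target body part is held at `contact_distance` from the subject's nose
#' (so the proximity rule recovers the schedule), and the subject slows
#' down by the configured factor. Outside episodes a minimum separation
#' comfortably above the proximity threshold is enforced, and during the
#' initial baseline the target is absent (masked frames).
#'
#' @param config a [synth_config()]
#' @return list with `timeline`, `positions` (one row per frame; subject
#'   nose/body/LED and target nose/body/tail coordinates in mm plus a
#'   `valid` mask), and `bouts` — the generating schedule as ground truth
#'   (onset/offset frames, half-open; times; contact tag)
#' @export
simulate_behavior <- function(config) {
  cfg <- config
  validate_synth_config(cfg)
  fr <- cfg$frame_rate
  n_frames <- round(cfg$session_duration * fr)
  dt <- 1 / fr
  timeline <- make_timeline(n_frames, fr)
  t <- timeline$t

  inter_start <- cfg$baseline_duration + 2
  inter_end <- cfg$session_duration - 5
  slot_need <- max(cfg$bout_duration_range) + 3
  if (cfg$n_bouts > 0 &&
      (inter_end - inter_start) < cfg$n_bouts * slot_need) {
    abort("session too short to place the requested number of bouts")
  }

  with_substream(cfg$seed, "behavior", {
    # episode schedule: one jittered episode per equal slot -> guaranteed
    # separation, reproducible under the seed
    bouts <- if (cfg$n_bouts > 0) {
      slot <- (inter_end - inter_start) / cfg$n_bouts
      dur <- runif(cfg$n_bouts, cfg$bout_duration_range[1],
                   cfg$bout_duration_range[2])
      onset <- inter_start + (seq_len(cfg$n_bouts) - 1) * slot +
        runif(cfg$n_bouts, 0, pmax(slot - dur - 2, 0))
      tag <- sample(c("nose-nose", "nose-body", "nose-rear"),
                    cfg$n_bouts, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25))
      tibble(
        bout = seq_len(cfg$n_bouts),
        onset_frame = as.integer(ceiling(onset * fr)),
        offset_frame = as.integer(floor((onset + dur) * fr)),
        tag = tag)
    } else {
      tibble(bout = integer(), onset_frame = integer(),
             offset_frame = integer(), tag = character())
    }
    bouts <- bouts %>%
      mutate(onset_t = .data$onset_frame / fr,
             offset_t = .data$offset_frame / fr)
    in_bout <- indicator_from_bouts(bouts, n_frames)
    bout_id <- rep(NA_integer_, n_frames)
    for (i in seq_len(nrow(bouts))) {
      bout_id[(bouts$onset_frame[i] + 1L):bouts$offset_frame[i]] <- i
    }

    sub <- ou_track(n_frames, dt, cfg$arena_size,
                    slowdown = ifelse(in_bout, cfg$slowdown, 1))
    tgt <- ou_track(n_frames, dt, cfg$arena_size, slowdown = rep(1, n_frames))

    # subject body parts from the heading of its own motion
    sub_nose <- sub$pos + 35 * sub$heading
    led <- sub$pos + 10 * sub$heading

    tgt_body <- tgt$pos
    tgt_nose <- tgt_body + 40 * tgt$heading
    tgt_tail <- tgt_body - 40 * tgt$heading

    # outside episodes keep every target part comfortably beyond the
    # threshold: relocate the target toward the arena center when any part
    # drifts too close to the subject's nose
    min_sep <- cfg$proximity_threshold + 15
    dmin <- pmin(
      sqrt(rowSums((tgt_nose - sub_nose)^2)),
      sqrt(rowSums((tgt_body - sub_nose)^2)),
      sqrt(rowSums((tgt_tail - sub_nose)^2)))
    too_close <- !in_bout & !is.na(dmin) & dmin < min_sep
    if (any(too_close)) {
      ctr <- cfg$arena_size / 2
      ux <- ctr - sub_nose[too_close, 1]
      uy <- ctr - sub_nose[too_close, 2]
      nn <- pmax(sqrt(ux^2 + uy^2), 1e-6)
      bx <- sub_nose[too_close, 1] + (min_sep + 80) * ux / nn
      by <- sub_nose[too_close, 2] + (min_sep + 80) * uy / nn
      h <- tgt$heading[too_close, , drop = FALSE]
      tgt_body[too_close, ] <- cbind(bx, by)
      tgt_nose[too_close, ] <- cbind(bx, by) + 40 * h
      tgt_tail[too_close, ] <- cbind(bx, by) - 40 * h
    }

    # during an episode place the tagged part at contact distance in front
    # of the subject's nose; remaining parts are laid out behind it
    if (any(in_bout)) {
      idx <- which(in_bout)
      u <- sub$heading[idx, , drop = FALSE]
      contact <- sub_nose[idx, , drop = FALSE] + cfg$contact_distance * u
      tagv <- bouts$tag[bout_id[idx]]
      perp <- cbind(-u[, 2], u[, 1])
      for (k in seq_along(idx)) {
        i <- idx[k]
        switch(tagv[k],
          "nose-nose" = {
            tgt_nose[i, ] <- contact[k, ]
            tgt_body[i, ] <- contact[k, ] + 40 * u[k, ]
            tgt_tail[i, ] <- contact[k, ] + 80 * u[k, ]
          },
          "nose-body" = {
            tgt_body[i, ] <- contact[k, ]
            tgt_nose[i, ] <- contact[k, ] + 40 * perp[k, ]
            tgt_tail[i, ] <- contact[k, ] - 40 * perp[k, ]
          },
          "nose-rear" = {
            tgt_tail[i, ] <- contact[k, ]
            tgt_body[i, ] <- contact[k, ] + 40 * u[k, ]
            tgt_nose[i, ] <- contact[k, ] + 80 * u[k, ]
          })
      }
    }

    clamp <- function(m) {
      m[, 1] <- pmin(pmax(m[, 1], 0), cfg$arena_size)
      m[, 2] <- pmin(pmax(m[, 2], 0), cfg$arena_size)
      m
    }
    sub_nose <- clamp(sub_nose); led <- clamp(led)
    tgt_nose <- clamp(tgt_nose); tgt_body <- clamp(tgt_body)
    tgt_tail <- clamp(tgt_tail)

    valid <- t >= cfg$baseline_duration
    tgt_nose[!valid, ] <- NA_real_
    tgt_body[!valid, ] <- NA_real_
    tgt_tail[!valid, ] <- NA_real_

    positions <- tibble(
      frame = timeline$frame, t = t,
      sub_nose_x = sub_nose[, 1], sub_nose_y = sub_nose[, 2],
      sub_body_x = sub$pos[, 1], sub_body_y = sub$pos[, 2],
      led_x = led[, 1], led_y = led[, 2],
      tgt_nose_x = tgt_nose[, 1], tgt_nose_y = tgt_nose[, 2],
      tgt_body_x = tgt_body[, 1], tgt_body_y = tgt_body[, 2],
      tgt_tail_x = tgt_tail[, 1], tgt_tail_y = tgt_tail[, 2],
      valid = valid)

    list(timeline = timeline, positions = positions, bouts = bouts)
  })
}

# OU-velocity random walk with reflecting walls; returns positions,
# unit heading vectors, and speeds. `slowdown` is a per-frame velocity factor.
ou_track <- function(n_frames, dt, arena, slowdown,
                     tau = 1.0, speed_scale = 60, margin = 15) {
  a <- exp(-dt / tau)
  sig <- speed_scale * sqrt(1 - a^2)
  vx <- numeric(n_frames); vy <- numeric(n_frames)
  x <- numeric(n_frames); y <- numeric(n_frames)
  x[1] <- runif(1, margin, arena - margin)
  y[1] <- runif(1, margin, arena - margin)
  vx[1] <- rnorm(1, 0, speed_scale); vy[1] <- rnorm(1, 0, speed_scale)
  ex <- rnorm(n_frames, 0, sig); ey <- rnorm(n_frames, 0, sig)
  for (i in 2:n_frames) {
    vx[i] <- a * vx[i - 1] + ex[i]
    vy[i] <- a * vy[i - 1] + ey[i]
    sx <- x[i - 1] + slowdown[i] * vx[i] * dt
    sy <- y[i - 1] + slowdown[i] * vy[i] * dt
    if (sx < margin || sx > arena - margin) { vx[i] <- -vx[i]; sx <- x[i - 1] + slowdown[i] * vx[i] * dt }
    if (sy < margin || sy > arena - margin) { vy[i] <- -vy[i]; sy <- y[i - 1] + slowdown[i] * vy[i] * dt }
    x[i] <- min(max(sx, 0), arena)
    y[i] <- min(max(sy, 0), arena)
  }
  sp <- sqrt(vx^2 + vy^2)
  heading <- cbind(vx, vy) / pmax(sp, 1e-6)
  list(pos = cbind(x, y), heading = heading, speed = sp * slowdown)
}

# per-frame logical indicator from half-open [onset_frame, offset_frame) bouts
indicator_from_bouts <- function(bouts, n_frames) {
  ind <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(bouts))) {
    a <- bouts$onset_frame[i] + 1L
    b <- bouts$offset_frame[i]
    if (b >= a) ind[a:min(b, n_frames)] <- TRUE
  }
  ind
}

# ---------------------------------------------------------------------------
# Spikes

# Draw per-unit labels for a region given configured fractions.
draw_labels <- function(n, fractions) {
  if (n == 0) return(character())
  counts <- floor(n * fractions)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * fractions - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(fractions), counts))
}

# Per-frame rate multiplier implementing bout-locked modulation windows.
# For each bout onset a window duration is drawn from dur_range; the unit's
# rate is multiplied by `factor` inside the union of windows.
modulation_profile <- function(bouts, n_frames, fr, dur_range, factor) {
  prof <- rep(1, n_frames)
  if (nrow(bouts) == 0 || factor == 1) return(prof)
  durs <- runif(nrow(bouts), dur_range[1], dur_range[2])
  for (i in seq_len(nrow(bouts))) {
    a <- bouts$onset_frame[i] + 1L
    b <- min(bouts$onset_frame[i] + as.integer(round(durs[i] * fr)), n_frames)
    if (b >= a) prof[a:b] <- factor
  }
  prof
}

# Inhomogeneous Poisson sampling by thinning a homogeneous train at max rate.
sample_inhomogeneous <- function(rate_per_frame, fr) {
  n_frames <- length(rate_per_frame)
  dur <- n_frames / fr
  rmax <- max(rate_per_frame)
  if (rmax <= 0) return(numeric())
  n <- rpois(1, rmax * dur)
  if (n == 0) return(numeric())
  tt <- sort(runif(n, 0, dur))
  fr_idx <- pmin(floor(tt * fr) + 1L, n_frames)
  keep <- runif(n) < rate_per_frame[fr_idx] / rmax
  tt[keep]
}

#' Simulate bout-modulated spike trains
#'
#' Inhomogeneous Poisson trains: negative units multiply their baseline rate
#' by (1 - amplitude) inside a drawn suppression window after each bout
#' onset, positive units elevate analogously, ns units fire at constant
#' rate. With `simulate_cs = TRUE`, PC units additionally get a low-rate
#' complex-spike train and simple spikes are deleted for `cs_pause` seconds
#' after every complex spike.
#'
#' @param bouts bout schedule tibble (as from [simulate_behavior()])
#' @param config a [synth_config()]
#' @param rate_mult optional units x frames matrix of extra rate multipliers
#'   (used internally to deliver shared coupling latents)
#' @return list with `spikes` (unit_id, unit_class, t) and `truth`
#'   (unit_id, region, label, baseline_rate, amplitude)
#' @export
simulate_spike_trains <- function(bouts, config, rate_mult = NULL) {
  cfg <- config
  validate_synth_config(cfg)
  fr <- cfg$frame_rate
  n_frames <- round(cfg$session_duration * fr)
  n_cb <- cfg$n_pc + cfg$n_dn
  if (n_cb == 0) {
    return(list(
      spikes = tibble(unit_id = character(), unit_class = character(),
                      t = numeric()),
      truth = tibble(unit_id = character(), region = character(),
                     unit_class = character(), label = character(),
                     baseline_rate = numeric(), amplitude = numeric())))
  }
  with_substream(cfg$seed, "spikes", {
    units <- tibble(
      unit_id = c(sprintf("pc%02d", seq_len(cfg$n_pc)),
                  sprintf("dn%02d", seq_len(cfg$n_dn))),
      region = rep(c("pc", "dn"), c(cfg$n_pc, cfg$n_dn)),
      unit_class = rep(c("PC_SS", "DN"), c(cfg$n_pc, cfg$n_dn)))
    units$label <- c(draw_labels(cfg$n_pc, cfg$class_fractions$pc),
                     draw_labels(cfg$n_dn, cfg$class_fractions$dn))
    units$baseline_rate <- purrr::map2_dbl(units$region, seq_len(n_cb),
      function(rg, i) runif(1, cfg$baseline_rate_range[[rg]][1],
                            cfg$baseline_rate_range[[rg]][2]))
    if (any(units$baseline_rate <= 0)) abort("baseline rate must be positive")
    units$amplitude <- ifelse(units$label == "ns", 0, cfg$modulation_amplitude)
    if (cfg$modulation_amplitude == 0) units$label <- "ns"

    spikes <- purrr::map(seq_len(n_cb), function(i) {
      dur_range <- if (units$region[i] == "pc") cfg$suppression_duration
                   else cfg$excitation_duration
      factor <- switch(units$label[i],
                       positive = 1 + units$amplitude[i],
                       negative = 1 - units$amplitude[i],
                       ns = 1)
      prof <- modulation_profile(bouts, n_frames, fr, dur_range, factor)
      rate <- units$baseline_rate[i] * prof
      if (!is.null(rate_mult)) rate <- rate * rate_mult[i, ]
      tt <- sample_inhomogeneous(rate, fr)
      out <- tibble(unit_id = units$unit_id[i],
                    unit_class = units$unit_class[i], t = tt)
      if (cfg$simulate_cs && units$region[i] == "pc") {
        cs <- sort(runif(rpois(1, cfg$cs_rate * cfg$session_duration),
                         0, cfg$session_duration))
        if (length(cs) > 0) {
          # enforce the post-CS simple-spike pause
          drop <- vapply(out$t, function(s) {
            j <- findInterval(s, cs)
            j >= 1 && (s - cs[j]) > 0 && (s - cs[j]) <= cfg$cs_pause
          }, logical(1))
          out <- out[!drop, , drop = FALSE]
        }
        out <- bind_rows(out, tibble(unit_id = units$unit_id[i],
                                     unit_class = "PC_CS", t = cs))
      }
      out
    }) %>% bind_rows() %>% arrange(.data$unit_id, .data$unit_class, .data$t)

    list(spikes = spikes, truth = units)
  })
}

# ---------------------------------------------------------------------------
# Calcium

#' Causal double-exponential calcium kernel sampled on the frame grid
#'
#' k(t) = exp(-t/decay) - exp(-t/rise) for t >= 0, normalized to unit peak.
#' The closed-form peak time is rise*decay/(decay-rise) * log(decay/rise).
#'
#' @param rise,decay time constants (s), decay > rise
#' @param frame_rate frame clock (Hz)
#' @param trunc truncate the kernel after this many decay constants
#' @return numeric kernel samples starting at lag 0
#' @export
calcium_kernel <- function(rise = 0.05, decay = 0.4, frame_rate = 30,
                           trunc = 6) {
  if (decay <= rise) abort("calcium_decay must exceed calcium_rise")
  tt <- seq(0, trunc * decay, by = 1 / frame_rate)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

#' Simulate calcium traces from latent event rates
#'
#' Per frame, event counts are drawn from the latent rate, convolved with a
#' causal double-exponential kernel, and additive Gaussian noise is applied.
#'
#' @param latent tibble (neuron_id, frame, rate) of per-frame latent event
#'   rates (Hz), aligned to the timeline
#' @param config a [synth_config()]
#' @return list with `traces` (neuron_id, frame, t, value) and `truth`
#'   (neuron_id, n_events)
#' @export
simulate_calcium <- function(latent, config) {
  cfg <- config
  if (cfg$calcium_decay <= cfg$calcium_rise) {
    abort("calcium_decay must exceed calcium_rise")
  }
  check_cols(latent, c("neuron_id", "frame", "rate"))
  fr <- cfg$frame_rate
  kern <- calcium_kernel(cfg$calcium_rise, cfg$calcium_decay, fr)
  with_substream(cfg$seed, "calcium", {
    out <- latent %>%
      arrange(.data$neuron_id, .data$frame) %>%
      group_by(.data$neuron_id) %>%
      dplyr::group_modify(function(df, key) {
        events <- rpois(nrow(df), pmax(df$rate, 0) / fr)
        tr <- conv_causal(as.numeric(events), kern)
        if (cfg$noise_sd > 0) tr <- tr + rnorm(nrow(df), 0, cfg$noise_sd)
        tibble(frame = df$frame, t = df$frame / fr, value = tr,
               n_events = sum(events))
      }) %>% ungroup()
    traces <- out %>% select("neuron_id", "frame", "t", "value")
    truth <- out %>% group_by(.data$neuron_id) %>%
      summarise(n_events = .data$n_events[1], .groups = "drop")
    list(traces = traces, truth = truth)
  })
}

# causal convolution: y[i] = sum_k kern[k+1] * x[i-k]
conv_causal <- function(x, kern) {
  n <- length(x)
  full <- convolve(x, rev(kern), type = "open")
  full[seq_len(n)]
}

# ---------------------------------------------------------------------------
# Full session

#' Simulate a complete joint session with ground truth
#'
#' Orchestrates behavior, cerebellar spike trains, ACC latent rates, and
#' calcium traces under one master seed fanned out into named substreams.
#' ACC neurons carry the same style of bout-locked modulation as cerebellar
#' units. Optionally, `n_coupled` cerebellar-unit / ACC-neuron pairs share a
#' standardized Ornstein--Uhlenbeck latent applied multiplicatively on the
#' log-rate scale with gain `coupling_strength`; with
#' `coupling_during = "bouts"` the latent is gated to interaction bouts.
#'
#' @param config a [synth_config()]
#' @return a `synth_session` list: `config`, `timeline`, `positions`,
#'   `bouts`, `spikes`, `spike_truth`, `traces`, `trace_truth`,
#'   `acc_truth`, `coupling` (pair table with gains)
#' @export
simulate_session <- function(config) {
  cfg <- config
  validate_synth_config(cfg)
  fr <- cfg$frame_rate
  n_frames <- round(cfg$session_duration * fr)
  beh <- simulate_behavior(cfg)
  ind <- indicator_from_bouts(beh$bouts, n_frames)

  n_cb <- cfg$n_pc + cfg$n_dn
  # planted coupled pairs share a latent; gains recorded as ground truth
  coupling <- tibble(
    pair = seq_len(cfg$n_coupled),
    cb_index = ((seq_len(cfg$n_coupled) - 1) %% max(n_cb, 1)) + 1,
    acc_index = ((seq_len(cfg$n_coupled) - 1) %% max(cfg$n_acc, 1)) + 1,
    gain = rep(cfg$coupling_strength, cfg$n_coupled))

  rate_mult_cb <- NULL
  acc_mult <- matrix(1, nrow = cfg$n_acc, ncol = n_frames)
  if (cfg$n_coupled > 0 && cfg$coupling_strength != 0) {
    rate_mult_cb <- matrix(1, nrow = n_cb, ncol = n_frames)
    lat <- with_substream(cfg$seed, "coupling", {
      purrr::map(seq_len(cfg$n_coupled), function(p) {
        u <- ou_noise(n_frames, 1 / fr, tau = 0.5)
        if (cfg$coupling_during == "bouts") u <- u * ind
        u
      })
    })
    g <- cfg$coupling_strength
    for (p in seq_len(cfg$n_coupled)) {
      m <- exp(g * lat[[p]] - g^2 / 2)
      rate_mult_cb[coupling$cb_index[p], ] <-
        rate_mult_cb[coupling$cb_index[p], ] * m
      acc_mult[coupling$acc_index[p], ] <-
        acc_mult[coupling$acc_index[p], ] * m
    }
  }

  sp <- simulate_spike_trains(beh$bouts, cfg, rate_mult = rate_mult_cb)

  acc <- with_substream(cfg$seed, "acc-latent", {
    labels <- draw_labels(cfg$n_acc, cfg$class_fractions$acc)
    base <- runif(cfg$n_acc, cfg$baseline_rate_range$acc[1],
                  cfg$baseline_rate_range$acc[2])
    amp <- ifelse(labels == "ns", 0, cfg$modulation_amplitude)
    latent <- purrr::map(seq_len(cfg$n_acc), function(i) {
      factor <- switch(labels[i],
                       positive = 1 + amp[i],
                       negative = 1 - amp[i],
                       ns = 1)
      prof <- modulation_profile(beh$bouts, n_frames, fr,
                                 cfg$suppression_duration, factor)
      base[i] * prof * acc_mult[i, ]
    })
    truth <- tibble(neuron_id = sprintf("acc%03d", seq_len(cfg$n_acc)),
                    label = labels, baseline_rate = base, amplitude = amp)
    rates <- tibble(
      neuron_id = rep(truth$neuron_id, each = n_frames),
      frame = rep(0:(n_frames - 1L), cfg$n_acc),
      rate = unlist(latent))
    list(truth = truth, rates = rates)
  })

  ca <- simulate_calcium(acc$rates, cfg)

  coupling$cb_unit <- sp$truth$unit_id[coupling$cb_index]
  coupling$acc_neuron <- acc$truth$neuron_id[coupling$acc_index]

  structure(list(
    config = cfg, timeline = beh$timeline, positions = beh$positions,
    bouts = beh$bouts, spikes = sp$spikes, spike_truth = sp$truth,
    traces = ca$traces, trace_truth = ca$truth, acc_truth = acc$truth,
    coupling = coupling), class = "synth_session")
}

# standardized OU noise series (mean 0, sd 1 stationary)
ou_noise <- function(n, dt, tau = 0.5) {
  a <- exp(-dt / tau)
  e <- rnorm(n, 0, sqrt(1 - a^2))
  u <- numeric(n)
  u[1] <- rnorm(1)
  for (i in 2:n) u[i] <- a * u[i - 1] + e[i]
  u
}

#' @export
print.synth_session <- function(x, ...) {
  cat("<synth_session>\n")
  cat(sprintf("  %d frames @ %g Hz (%g s), arena %g mm\n",
              nrow(x$timeline), x$config$frame_rate,
              x$config$session_duration, x$config$arena_size))
  cat(sprintf("  bouts: %d | cb units: %d | ACC neurons: %d | coupled pairs: %d\n",
              nrow(x$bouts), nrow(x$spike_truth), nrow(x$acc_truth),
              nrow(x$coupling)))
  invisible(x)
}
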