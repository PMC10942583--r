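# Bout detection from proximity, bout assembly, kinematics, movement events.

test_that("proximity rule flags frames and tags the nearest target part", {
  # body at 15 mm, threshold 20 mm -> flagged as nose-body
  pos <- part_positions(nose = c(0, 30), body = c(0, 15), tail = c(0, 40))
  fl <- detect_interaction_frames(pos, threshold_mm = 20)
  expect_true(all(fl$interacting))
  expect_true(all(fl$tag == "nose-body"))

  # exactly 25 mm at threshold 20 -> not flagged
  pos2 <- part_positions(nose = c(0, 25), body = c(0, 25), tail = c(0, 25))
  expect_false(any(detect_interaction_frames(pos2, 20)$interacting))

  # nearest part wins: distances nose 30, body 18, tail 12 -> nose-rear
  pos3 <- part_positions(nose = c(0, 30), body = c(0, 18), tail = c(0, 12))
  fl3 <- detect_interaction_frames(pos3, 20)
  expect_true(all(fl3$tag == "nose-rear"))
  # brute-force nearest-part check
  d <- c(`nose-nose` = 30, `nose-body` = 18, `nose-rear` = 12)
  expect_equal(unique(fl3$tag), names(which.min(d)))
})

test_that("masked frames are never flagged and all-masked input errors", {
  pos <- part_positions(body = c(0, 10))
  pos$valid[2:3] <- FALSE
  fl <- detect_interaction_frames(pos, 20)
  expect_false(any(fl$interacting[2:3]))
  expect_true(all(fl$interacting[c(1, 4, 5)]))

  pos$valid <- FALSE
  expect_error(detect_interaction_frames(pos, 20), "masked")
})

test_that("bout assembly merges short gaps and drops short runs", {
  n <- 60
  ind <- rep(FALSE, n)
  ind[11:21] <- TRUE   # frames 10-20 (0-based)
  ind[23:31] <- TRUE   # frames 22-30
  frames <- tibble::tibble(frame = 0:(n - 1), t = (0:(n - 1)) / 30,
                           interacting = ind)
  b <- assemble_bouts(frames, min_duration = 0, merge_gap = 5 / 30)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_frame, 10)
  expect_equal(b$offset_frame, 31)  # half-open: covers flagged frame 30

  # isolated 2-frame run with min_duration 0.2 s at 30 Hz (6 frames) dropped
  ind2 <- rep(FALSE, n); ind2[5:6] <- TRUE
  b2 <- assemble_bouts(tibble::tibble(frame = 0:(n - 1), t = (0:(n - 1)) / 30,
                                      interacting = ind2),
                       min_duration = 0.2, merge_gap = 0)
  expect_equal(nrow(b2), 0)
})

test_that("bout frame counts respect the flagged-frame budget", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- 100
      ind <- runif(n) < 0.3
      frames <- tibble::tibble(frame = 0:(n - 1), t = (0:(n - 1)) / 30,
                               interacting = ind)
      b0 <- assemble_bouts(frames, min_duration = 0, merge_gap = 0)
      expect_equal(sum(b0$n_frames), sum(ind))   # equality at zero params
      b1 <- assemble_bouts(frames, min_duration = 0.2, merge_gap = 0.2)
      expect_lte(sum(bout_indicator(b1, n) & ind), sum(ind))
      # regenerated indicator is consistent with the intervals
      expect_equal(sum(bout_indicator(b0, n)), sum(ind))
    }
  })
})

test_that("kinematics recover analytic speed and angular speed", {
  # LED moving (0,0) -> (30,40) mm over 1 s at constant velocity: 50 mm/s
  n <- 31
  pos <- tibble::tibble(frame = 0:(n - 1), t = seq(0, 1, length.out = n),
                        led_x = seq(0, 30, length.out = n),
                        led_y = seq(0, 40, length.out = n))
  kin <- compute_kinematics(pos, median_width = 1)
  expect_equal(kin$speed, rep(50, n), tolerance = 1e-9)

  # stationary LED: speed 0, angular speed reported 0 with low-speed mask
  pos0 <- pos; pos0$led_x <- 5; pos0$led_y <- 5
  kin0 <- compute_kinematics(pos0, median_width = 1)
  expect_true(all(kin0$speed == 0))
  expect_true(all(kin0$ang_speed == 0))
  expect_false(any(kin0$speed_ok))

  # circular motion at angular rate omega -> angular speed ~ omega (deg/s)
  omega <- 90  # deg/s
  tt <- seq(0, 4, by = 1 / 30)
  r <- 100
  posc <- tibble::tibble(frame = seq_along(tt) - 1, t = tt,
                         led_x = r * cospi(omega * tt / 180),
                         led_y = r * sinpi(omega * tt / 180))
  kinc <- compute_kinematics(posc, median_width = 1)
  mid <- 10:(length(tt) - 10)
  expect_equal(mean(kinc$ang_speed[mid]), omega, tolerance = 0.02)

  expect_error(compute_kinematics(pos[1:2, ], median_width = 1), "3 valid")
})

test_that("movement events follow hysteresis with refractory dwell", {
  tt <- seq(0, 30, by = 1 / 30)
  # step 0 -> 100 mm/s at t = 10 s: single onset at 10 s
  sp <- ifelse(tt >= 10, 100, 0)
  kin <- tibble::tibble(frame = seq_along(tt) - 1, t = tt, speed = sp,
                        ang_speed = 0)
  ev <- detect_movement_events(kin, on_thresh = 50, off_thresh = 20,
                               refractory = 1)
  loco_on <- ev$t[ev$event == "locomotion_onset"]
  expect_equal(length(loco_on), 1)
  expect_equal(loco_on, 10, tolerance = 1 / 30)

  # oscillation entirely below off_thresh: no events
  kin2 <- kin; kin2$speed <- 10 + 5 * sin(tt)
  expect_equal(nrow(detect_movement_events(kin2, 50, 20, 1)), 0)

  # square wave alternating every 5 s for 60 s (starting low), refractory 1 s:
  # 6 onsets and 6 offsets (enumerated crossings)
  tt3 <- seq(0, 60, by = 1 / 30)
  sp3 <- ifelse((floor(tt3 / 5) %% 2) == 1, 100, 0)
  kin3 <- tibble::tibble(frame = seq_along(tt3) - 1, t = tt3, speed = sp3,
                         ang_speed = 0)
  ev3 <- detect_movement_events(kin3, 50, 20, refractory = 1)
  expect_equal(sum(ev3$event == "locomotion_onset"), 6)
  expect_equal(sum(ev3$event == "locomotion_offset"), 6)
})

test_that("bout indicator is invariant to uniform translation of coordinates", {
  beh <- simulate_behavior(small_config(seed = 13))
  fl1 <- detect_interaction_frames(beh$positions, 20)
  shifted <- beh$positions
  for (cc in grep("_(x|y)$", names(shifted), value = TRUE)) {
    shifted[[cc]] <- shifted[[cc]] + 123.4
  }
  fl2 <- detect_interaction_frames(shifted, 20)
  expect_identical(fl1$interacting, fl2$interacting)
})

test_that("total interaction time is monotone in the distance threshold", {
  beh <- simulate_behavior(small_config(seed = 17))
  totals <- vapply(c(10, 15, 20, 30, 50), function(th) {
    sum(detect_interaction_frames(beh$positions, th)$interacting)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("detect -> assemble recovers planted bouts with high Jaccard", {
  beh <- simulate_behavior(small_config(seed = 23))
  fl <- detect_interaction_frames(beh$positions, 20)
  det <- assemble_bouts(fl, min_duration = 0.2, merge_gap = 0.5)
  n <- nrow(beh$timeline)
  truth <- bout_indicator(beh$bouts, n)
  got <- bout_indicator(det, n)
  jac <- sum(truth & got) / sum(truth | got)
  expect_gte(jac, 0.95)
})
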