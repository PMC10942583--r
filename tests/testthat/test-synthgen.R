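# Synthetic-session generator: determinism, arena confinement, planted
# bout schedules, Poisson statistics, CS-pause enforcement, calcium kernel.

test_that("fixed seed reproduces identical tracks and bout schedules", {
  cfg <- small_config(seed = 5)
  a <- simulate_behavior(cfg)
  b <- simulate_behavior(cfg)
  expect_identical(a$positions, b$positions)
  expect_identical(a$bouts, b$bouts)

  s1 <- simulate_session(small_config(seed = 9))
  s2 <- simulate_session(small_config(seed = 9))
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$traces, s2$traces)
})

test_that("all emitted positions lie within the arena or are masked", {
  beh <- simulate_behavior(small_config(seed = 2))
  pos <- beh$positions
  coord_cols <- grep("_(x|y)$", names(pos), value = TRUE)
  for (cc in coord_cols) {
    v <- pos[[cc]][!is.na(pos[[cc]])]
    expect_true(all(v >= 0 & v <= 480), info = cc)
  }
  # target is masked during the baseline period
  expect_true(all(is.na(pos$tgt_nose_x[!pos$valid])))
})

test_that("zero approach episodes give an empty truth schedule and no proximity", {
  beh <- simulate_behavior(small_config(seed = 3, n_bouts = 0))
  expect_equal(nrow(beh$bouts), 0)
  fl <- detect_interaction_frames(beh$positions, 20)
  expect_false(any(fl$interacting))
})

test_that("a session too short for the requested bouts fails explicitly", {
  expect_error(
    simulate_behavior(synth_config(session_duration = 30,
                                   baseline_duration = 10, n_bouts = 20)),
    "too short")
})

test_that("amplitude zero turns every unit's truth label to ns", {
  cfg <- small_config(seed = 4, modulation_amplitude = 0)
  beh <- simulate_behavior(cfg)
  sp <- simulate_spike_trains(beh$bouts, cfg)
  expect_true(all(sp$truth$label == "ns"))
})

test_that("unmodulated Poisson spike counts match analytic moments", {
  # rate 5 Hz over 30 s, 200 replicates: mean and variance both ~ lambda*T
  lam <- 5; T <- 30; n_rep <- 200
  counts <- withr::with_seed(42, {
    vapply(seq_len(n_rep), function(i) {
      length(socroc:::sample_inhomogeneous(rep(lam, T * 30), 30))
    }, numeric(1))
  })
  expect_lt(abs(mean(counts) - lam * T), 3 * sqrt(lam * T / n_rep))
  var_se <- sqrt(2 / (n_rep - 1)) * lam * T
  expect_lt(abs(var(counts) - lam * T), 3 * var_se)
})

test_that("complex spikes enforce the simple-spike pause", {
  cfg <- small_config(seed = 6, simulate_cs = TRUE, cs_pause = 0.04,
                      n_pc = 2, n_dn = 0)
  beh <- simulate_behavior(cfg)
  sp <- simulate_spike_trains(beh$bouts, cfg)
  for (u in unique(sp$truth$unit_id[sp$truth$region == "pc"])) {
    ss <- sp$spikes$t[sp$spikes$unit_id == u & sp$spikes$unit_class == "PC_SS"]
    cs <- sp$spikes$t[sp$spikes$unit_id == u & sp$spikes$unit_class == "PC_CS"]
    expect_gt(length(cs), 0)
    for (c in cs) {
      expect_false(any(ss > c & ss - c <= 0.04))
    }
  }
})

test_that("zero latent rate and zero noise give an identically zero trace", {
  cfg <- small_config(seed = 7, noise_sd = 0)
  latent <- tibble::tibble(neuron_id = "n1", frame = 0:299, rate = 0)
  ca <- simulate_calcium(latent, cfg)
  expect_true(all(ca$traces$value == 0))
})

test_that("a single event reproduces the kernel with closed-form peak location", {
  k <- calcium_kernel(rise = 0.05, decay = 0.4, frame_rate = 30)
  ev <- rep(0, 200); ev[50] <- 1
  tr <- socroc:::conv_causal(ev, k)
  expect_equal(tr[50:(49 + length(k))], k, tolerance = 1e-12)
  t_star <- 0.05 * 0.4 / (0.4 - 0.05) * log(0.4 / 0.05)
  expect_lte(abs((which.max(k) - 1) - t_star * 30), 1)
  expect_error(calcium_kernel(rise = 0.5, decay = 0.4), "exceed")
})

test_that("uncoupled regions are statistically indistinguishable from independent controls", {
  cfg <- synth_config(session_duration = 120, baseline_duration = 10,
                      n_bouts = 6, n_pc = 0, n_dn = 6, n_acc = 6,
                      class_fractions = list(pc = c(positive = 0, negative = 0, ns = 1),
                                             dn = c(positive = 0, negative = 0, ns = 1),
                                             acc = c(positive = 0, negative = 0, ns = 1)),
                      coupling_strength = 0, seed = 21)
  ses <- simulate_session(cfg)
  rates <- suppressMessages(
    zscore_activity(smooth_rate(bin_spikes(ses$spikes, ses$timeline))))
  traces <- suppressMessages(zscore_activity(ses$traces))
  al <- align_streams(rates, traces)
  rw <- tidyr::pivot_wider(al$rates, id_cols = "frame",
                           names_from = "unit_id", values_from = "value")
  tw <- tidyr::pivot_wider(al$traces, id_cols = "frame",
                           names_from = "neuron_id", values_from = "value")
  same_session <- abs(cor(as.matrix(rw[-1]), as.matrix(tw[-1])))
  # independent control: traces from a different seed
  ses2 <- simulate_session(synth_config(session_duration = 120,
                                        baseline_duration = 10, n_bouts = 6,
                                        n_pc = 0, n_dn = 0, n_acc = 6,
                                        seed = 77))
  t2 <- suppressMessages(zscore_activity(ses2$traces))
  t2w <- tidyr::pivot_wider(align_streams(rates, t2)$traces,
                            id_cols = "frame", names_from = "neuron_id",
                            values_from = "value")
  control <- abs(cor(as.matrix(rw[-1]), as.matrix(t2w[-1])))
  # mean |r| within Monte-Carlo error of each other (r ~ N(0, 1/sqrt(neff)))
  se <- sd(c(same_session, control)) / sqrt(length(same_session))
  expect_lt(abs(mean(same_session) - mean(control)), 4 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(frame_rate = 0), "frame_rate")
  expect_error(synth_config(class_fractions = list(
    pc = c(positive = 0.5, negative = 0.1, ns = 0.1),
    dn = c(positive = 0.2, negative = 0.12, ns = 0.68),
    acc = c(positive = 0.04, negative = 0.05, ns = 0.91))), "sum to 1")
  expect_error(synth_config(calcium_rise = 0.5, calcium_decay = 0.4), "exceed")
  expect_error(synth_config(baseline_rate_range = list(
    pc = c(0, 10), dn = c(20, 60), acc = c(0.15, 0.6))), "positive")
})
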