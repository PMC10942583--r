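# AUC identity, circular shift, classification, PETH, population
# summaries, movement confounds.

test_that("AUC equals brute-force pairwise probability including ties", {
  expect_equal(compute_auc(c(0.1, 0.2, 0.9, 1.0), c(0, 0, 1, 1)), 1.0)
  expect_equal(compute_auc(c(1, 3, 2, 4), c(0, 1, 1, 0)), 0.5)
  expect_equal(compute_auc(c(1, 1, 2), c(0, 1, 1)), 0.75)

  withr::with_seed(3, {
    for (rep in 1:25) {
      n <- sample(10:200, 1)
      x <- sample(rnorm(max(3, n %/% 3)), n, replace = TRUE)  # many ties
      ind <- runif(n) < runif(1, 0.2, 0.8)
      if (sum(ind) == 0 || sum(ind) == n) next
      expect_equal(compute_auc(x, ind), auc_brute_force(x, ind))
    }
  })
  expect_error(compute_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC complements under sign flip and survives monotone transforms", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- 150
      x <- rnorm(n)
      ind <- runif(n) < 0.3
      if (sum(ind) == 0 || sum(ind) == n) next
      expect_equal(compute_auc(x, ind) + compute_auc(-x, ind), 1)
      expect_equal(compute_auc(x, ind), compute_auc(exp(2 * x) + 5, ind))
      expect_equal(compute_auc(x, ind), compute_auc(rank(x), ind))
    }
  })
})

test_that("circular shift is a group action preserving the value multiset", {
  x <- rnorm(20)
  expect_identical(circular_shift(x, 0), x)
  expect_equal(circular_shift(circular_shift(x, 10), 10), x)  # L = 2*shift
  withr::with_seed(23, {
    for (rep in 1:20) {
      s <- sample(0:19, 1)
      y <- circular_shift(x, s)
      expect_equal(sort(y), sort(x))
      expect_equal(mean(y), mean(x))
      expect_equal(var(y), var(x))
    }
  })
  expect_error(circular_shift(x, 20), "shift")
})

test_that("shuffle null matches shifting then recomputing AUC exactly", {
  withr::with_seed(29, {
    for (rep in 1:5) {
      L <- sample(60:200, 1)
      x <- sample(rnorm(L %/% 2), L, replace = TRUE)
      ind <- runif(L) < 0.3
      if (sum(ind) < 2 || sum(ind) > L - 2) next
      shifts <- sample(0:(L - 1), 40, replace = TRUE)
      got <- socroc:::shuffle_auc_null(x, which(ind), shifts)
      want <- vapply(shifts, function(s) {
        compute_auc(circular_shift(x, s), ind)
      }, numeric(1))
      expect_identical(got, want)
    }
  })
})

test_that("classification labels binary-identical activity positive and flags edge cases", {
  n <- 3000
  tl <- make_timeline(n, 30)
  ind <- rep(FALSE, n); ind[501:800] <- TRUE; ind[1501:1900] <- TRUE
  act <- tibble::tibble(unit_id = "u", frame = tl$frame, t = tl$t,
                        value = as.numeric(ind))
  res <- classify_modulation(act, ind, n_shuffles = 100, min_shift = 5, seed = 2)
  expect_equal(res$auc, 1.0)
  expect_equal(res$label, "positive")

  # too few interaction frames -> ns with diagnostic, not silent
  ind2 <- rep(FALSE, n); ind2[5] <- TRUE
  res2 <- classify_modulation(act, ind2, n_shuffles = 50, min_shift = 5,
                              min_class_frac = 0.01, seed = 2)
  expect_equal(res2$label, "ns")
  expect_equal(res2$flag, "too_few_frames")

  # degenerate unit excluded
  act3 <- act; act3$value <- 0; act3$degenerate <- TRUE
  res3 <- classify_modulation(act3, ind, n_shuffles = 50, min_shift = 5, seed = 2)
  expect_equal(res3$flag, "degenerate")

  g <- glance(res)
  expect_equal(g$n_positive, 1)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("PETH recovers planted step responses within smoothing blur", {
  n <- 6000
  tl <- make_timeline(n, 30)
  # constant z-scored input -> mean identically 0
  cst <- tibble::tibble(frame = tl$frame, t = tl$t, value = 0)
  events <- c(50, 80, 110, 140)
  p0 <- compute_peth(cst, events, window = c(2, 4))
  expect_true(all(p0$mean == 0))

  # step suppression of known depth/duration at each event, smoothed:
  # compare trough against the analytic convolution of the step with the kernel
  depth <- -1; dur <- 2
  v <- rep(0, n)
  for (et in events) {
    i0 <- round(et * 30); v[(i0 + 1):(i0 + dur * 30)] <- depth
  }
  series <- tibble::tibble(unit_id = "u", frame = tl$frame, t = tl$t, value = v)
  sm <- smooth_rate(socroc:::set_stage(series, "rate"), sigma = 0.1)
  p <- compute_peth(dplyr::select(sm, "frame", "t", "value"), events,
                    window = c(2, 4))
  lag_in <- p$lag > 0.3 & p$lag < dur - 0.3    # interior of the step
  expect_equal(mean(p$mean[lag_in]), depth, tolerance = 0.02)
  expect_lt(abs(p$mean[which.min(abs(p$lag - dur / 2))] - depth), 0.02)
  # trough duration at half depth ~ planted duration
  half <- p$lag[p$mean < depth / 2]
  expect_equal(max(half) - min(half), dur, tolerance = 0.2)

  # single event: SEM reported as zeros with a flag
  p1 <- compute_peth(cst, events[1], window = c(2, 4))
  expect_true(all(p1$sem == 0))
  expect_true("single_event" %in% p1$flag)
  # events whose window exits the session are excluded and counted
  p2 <- compute_peth(cst, c(events, 199.9), window = c(2, 4))
  expect_equal(p2$n_excluded, 1)
  expect_error(compute_peth(cst, 1e6, window = c(2, 4)), "no events")
})

test_that("population proportions and overlaps match brute-force counting", {
  labels <- c(rep("positive", 20), rep("negative", 12), rep("ns", 67))
  res <- tibble::tibble(unit_id = sprintf("u%03d", 1:99), context = "social",
                        label = labels)
  ps <- population_summary(res)
  # 20 positive of 99 units -> 20.2%
  expect_equal(round(100 * ps$prop[ps$label == "positive"], 1), 20.2)

  withr::with_seed(37, {
    for (rep in 1:10) {
      lab <- sample(c("positive", "negative", "ns"), 50, replace = TRUE)
      r2 <- tibble::tibble(unit_id = sprintf("u%02d", 1:50),
                           context = "object", label = lab)
      p2 <- population_summary(r2)
      for (l in c("positive", "negative", "ns")) {
        expect_equal(p2$n[p2$label == l], sum(lab == l))
        expect_equal(p2$prop[p2$label == l], sum(lab == l) / 50)
      }
    }
  })

  # disjoint significant sets -> overlap 0
  a <- tibble::tibble(unit_id = sprintf("u%02d", 1:10),
                      label = c(rep("positive", 5), rep("ns", 5)))
  b <- tibble::tibble(unit_id = sprintf("u%02d", 1:10),
                      label = c(rep("ns", 5), rep("positive", 5)))
  ov <- modulation_overlap(a, b)
  expect_true(all(ov$n_overlap == 0))
  # mismatched unit sets are rejected with offenders listed
  expect_error(modulation_overlap(a, dplyr::mutate(b, unit_id = paste0("x", unit_id))),
               "unit sets differ")
})

test_that("movement-confound test flags speed-driven units but spares bout-driven ones", {
  withr::with_seed(53, {
    n <- 4500
    tl <- make_timeline(n, 30)
    speed <- abs(100 * socroc:::ou_noise(n, 1 / 30, tau = 2))
    events <- tl$t[which(diff(speed > 60) == 1)]
    events <- events[events > 3 & events < max(tl$t) - 3]
    # positive control: activity directly driven by speed
    driven <- tibble::tibble(unit_id = "drv", frame = tl$frame, t = tl$t,
                             value = scale(speed)[, 1])
    res_d <- movement_confound_check(driven, events, window = c(1, 1),
                                     n_shuffles = 200, seed = 4)
    expect_lt(res_d$p, 0.05)
    # bout-driven unit with independently placed movement events
    v <- rep(0, n); v[2000:2300] <- 2
    ind <- tibble::tibble(unit_id = "bout", frame = tl$frame, t = tl$t,
                          value = v + rnorm(n, 0, 0.5))
    res_b <- movement_confound_check(ind, events, window = c(1, 1),
                                     n_shuffles = 200, seed = 4)
    expect_gt(res_b$p, 0.05)
    # no events -> skipped, empty output
    expect_message(
      empty <- movement_confound_check(driven, numeric(), n_shuffles = 10),
      "skipped")
    expect_equal(nrow(empty), 0)
  })
})
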