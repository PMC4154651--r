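test_that("baseline estimation discards transients and removes drift", {
  # constant trace
  bl <- estimate_baseline(rep(100, 50))
  expect_equal(bl$f0, 100)
  expect_equal(bl$background_sd, 0)

  # baseline 100 with 5% of frames at 1000: transient frames discarded
  x <- withr::with_seed(1, {
    x <- rnorm(1000, 100, 1)
    x[sample.int(1000, 50)] <- 1000
    x
  })
  bl2 <- estimate_baseline(x)
  expect_equal(bl2$f0, 100, tolerance = 0.02)
  expect_lt(bl2$background_sd, 2)

  # pure linear ramp: f0 = ramp mean, near-zero residual sd
  ramp <- seq(50, 150, length.out = 200)
  bl3 <- estimate_baseline(ramp)
  expect_equal(bl3$f0, mean(ramp), tolerance = 1e-8)
  expect_lt(bl3$background_sd, 1e-8)
  expect_equal(bl3$drift$slope_per_s,
               (ramp[2] - ramp[1]) * 33, tolerance = 1e-6)

  expect_error(estimate_baseline(rep(1, 5)), "too short")
})

test_that("normalization is (F - F0)/F0 and scale invariant", {
  bl <- estimate_baseline(rep(100, 50))
  expect_equal(normalize_trace(rep(100, 50), bl), rep(0, 50))
  x <- rep(100, 50); x[25] <- 200
  expect_equal(normalize_trace(x, bl)[25], 1.0)
  # affine scale invariance of the full pipeline input
  y <- withr::with_seed(2, rnorm(300, 100, 2))
  n1 <- normalize_trace(baseline = estimate_baseline(y))
  n2 <- normalize_trace(baseline = estimate_baseline(3.7 * y))
  expect_equal(n1, n2, tolerance = 1e-10)

  blbad <- list(f0 = 0, detrended = rep(0, 10))
  expect_error(normalize_trace(baseline = blbad), "positive")
})

test_that("onset detection obeys threshold, duration and flatness rules", {
  # flat noiseless signal: nothing
  expect_equal(nrow(detect_onsets(rep(0, 200), 0.01)), 0L)

  # clean transient starting at frame 101 (0-based 100)
  sig <- rep(0, 300)
  sig[101:103] <- c(1, 2, 3) / 3 * 0.2
  sig[104:300] <- 0.2 * exp(-(1:197) / 66)
  ev <- detect_onsets(sig, 0.01)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$frame - 100), 1)

  # 3-frame blip with min_frames = 5: rejected
  blip <- rep(0, 100); blip[51:53] <- 1
  expect_equal(nrow(detect_onsets(blip, 0.01, min_frames = 5, smooth_window = 1)), 0L)
})

test_that("synthetic transients are recovered at the true onset frame", {
  tp <- trace_params(noise_sd = 0)
  tr <- event_train("a", 10.00)
  m <- synthesize_fluorescence(tr, tp, seed = 1)
  ev <- detect_events(m, refine = FALSE)
  expect_equal(nrow(ev), 1L)
  det_frame <- round(ev$time * tp$frame_rate)
  expect_equal(det_frame, floor(10.00 * 33))

  # SNR 10, several nodes and events: all recovered within a frame,
  # nothing spurious
  gt <- suppressWarnings(generate_planted_network(5, 2, target_assortativity = 0, seed = 3))
  trn <- simulate_bursts(gt, cascade_params(n_bursts = 12, inter_burst_interval_mean = 10), seed = 4)
  tp2 <- trace_params(amplitude = 20, noise_sd = 2)
  m2 <- synthesize_fluorescence(trn, tp2, seed = 5)
  ev2 <- detect_events(m2)
  expect_equal(nrow(ev2), nrow(trn))
  hit <- vapply(seq_len(nrow(trn)), function(i) {
    cand <- ev2$time[ev2$node == trn$node[i]]
    any(abs(cand - trn$time[i]) < 2 / tp2$frame_rate)
  }, logical(1))
  expect_true(all(hit))
})

test_that("false-positive rate on event-free noise is below 1 per 1e4 frames", {
  n_fp <- withr::with_seed(8, {
    total <- 0L
    for (r in 1:10) {
      x <- rnorm(10000, 100, 1)
      bl <- estimate_baseline(x)
      ns <- normalize_trace(baseline = bl)
      total <- total + nrow(detect_onsets(ns, bl$background_sd / bl$f0))
    }
    total
  })
  expect_lt(n_fp / 1e5, 1 / 1e4)
})

test_that("two-line refinement recovers exact and noisy sub-frame onsets", {
  fr <- 100
  # exact piecewise-linear kink at t* = 3.07 s
  tt <- (0:699) / fr
  x <- pmax(0, tt - 3.07)
  onset_frame <- floor(3.07 * fr)   # 0-based last baseline frame
  rf <- refine_onset_subframe(x, onset_frame, frame_rate = fr)
  expect_true(rf$refined)
  expect_equal(rf$time, 3.07, tolerance = 1e-10)

  # parallel lines: flagged fallback at the frame time
  flat <- 0.5 * tt
  rf2 <- refine_onset_subframe(flat, 300, frame_rate = fr)
  expect_false(rf2$refined)
  expect_equal(rf2$time, 300 / fr)

  # too few frames before the onset: unrefined
  rf3 <- refine_onset_subframe(x, 3, frame_rate = fr)
  expect_false(rf3$refined)

  # noisy transient at 33 fps: refined within one frame of the truth
  errs <- withr::with_seed(9, {
    vapply(1:20, function(r) {
      t_true <- 5 + runif(1)
      tr <- event_train("a", t_true)
      tp <- trace_params(noise_sd = 0.5)
      m <- synthesize_fluorescence(tr, tp, seed = r)
      ev <- detect_events(m, refine = TRUE)
      abs(ev$time[1] - t_true)
    }, numeric(1))
  })
  expect_lt(median(errs), 1 / 33)
  expect_true(all(errs < 2 / 33))
})
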