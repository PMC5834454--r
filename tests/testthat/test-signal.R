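test_that("Gaussian low-pass has unit DC gain and the right -3 dB point", {
  rate <- 50000
  # constant trace unchanged
  tr <- trace_record(rep(2.5, 1000), 100, rate)
  expect_equal(gaussian_lowpass(tr)$current, rep(2.5, 1000), tolerance = 1e-12)
  # sinusoid at the cutoff attenuated to 1/sqrt(2) within 2%
  t <- (0:99999) / rate
  x <- sin(2 * pi * 1000 * t)
  y <- gaussian_lowpass(x, cutoff = 1000, rate = rate)
  mid <- 20000:80000
  att <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_equal(att, 1 / sqrt(2), tolerance = 0.02)
  # white-noise variance strictly reduced
  withr::with_seed(1, n <- rnorm(20000))
  expect_lt(var(gaussian_lowpass(n, 1000, rate)), var(n))
  expect_error(gaussian_lowpass(n, cutoff = 30000, rate = rate), "Nyquist")
})

test_that("zap segmentation splits traces at voltage reversals", {
  gen <- generate_current_trace(n_events = 3, noise_sd = 0, seed = 2,
                                sample_rate = 10000)
  segs <- segment_by_zaps(gen$trace)
  expect_length(segs, 4) # 3 zaps -> 4 segments
  # segments ordered in time
  starts <- vapply(segs, function(s) attr(s, "t_start"), numeric(1))
  expect_true(all(diff(starts) > 0))
  # no zaps -> single segment
  flat <- trace_record(rep(3.78, 5000), 100, 10000)
  expect_length(segment_by_zaps(flat), 1)
  expect_warning(out <- segment_by_zaps(flat, expect_zaps = TRUE), "No zaps")
  expect_true(attr(out[[1]], "no_zaps_found"))
  # zap at t = 0: leading segment dropped
  v <- c(rep(-100, 100), rep(100, 5000))
  i <- 3.78 * v / 1000
  segs0 <- segment_by_zaps(trace_record(i, v, 10000))
  expect_length(segs0, 1)
  expect_gt(attr(segs0[[1]], "t_start"), 0)
})

test_that("level detection recovers programmed two- and three-level traces", {
  rate <- 10000
  withr::with_seed(3, {
    g <- c(rep(10, 20000), rep(8, 20000)) + rnorm(40000, sd = 0.05)
    tr <- trace_record(g * 100 / 1000, 100, rate)
    lf <- detect_levels(tr)
    expect_equal(lf$baseline, 10, tolerance = 0.05)
    expect_equal(lf$ring, 8, tolerance = 0.05)
    # constant trace: baseline only, no ring level
    cst <- trace_record(rep(10, 5000) * 0.1, 100, rate)
    lf2 <- detect_levels(cst)
    expect_equal(lf2$baseline, 10, tolerance = 0.01)
    expect_true(is.na(lf2$ring))
    # three levels: ring = mean of the two non-baseline peaks
    g3 <- c(rep(10, 20000), rep(8.5, 20000), rep(8.0, 20000)) +
      rnorm(60000, sd = 0.05)
    lf3 <- detect_levels(trace_record(g3 * 0.1, 100, rate))
    expect_equal(lf3$baseline, 10, tolerance = 0.05)
    expect_equal(lf3$ring, 8.25, tolerance = 0.05)
    # invariance to voltage polarity / current sign
    lf4 <- detect_levels(trace_record(-g * 0.1, -100, rate))
    expect_equal(lf4$baseline, lf$baseline)
    expect_equal(lf4$ring, lf$ring)
  })
  expect_error(detect_levels(trace_record(numeric(0), 100, rate)),
               "Zero-length")
})

test_that("event selection enforces baseline tolerance and minimal length", {
  ev <- tibble::tibble(
    segment = 1:4,
    t_start = c(0, 1, 2, 3), t_end = c(0.5, 1.2, 2.9, 3.6),
    duration = c(0.5, 0.2, 0.9, 0.6),
    baseline = c(37.8, 37.8, 36.5, 37.9),
    ring = c(32.9, 32.9, 32.0, 33.0),
    relative = c(0.87, 0.87, 0.877, 0.871))
  out <- select_events(ev, avg_baseline = 37.8)
  # 0.2 s event rejected; baseline 1.3 nS off rejected
  expect_equal(out$segment, c(1L, 4L))
  # an event meeting both criteria is retained unchanged
  expect_equal(out[out$segment == 1, ], ev[1, ])
})

test_that("docking events are recovered end to end from synthetic traces", {
  gen <- generate_current_trace(baseline_nS = 37.8, ring_nS = 32.9,
                                n_events = 3, noise_sd = 0.2,
                                sample_rate = 25000, seed = 11)
  ev <- extract_docking_events(gen$trace)
  ev <- select_events(ev)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$relative, gen$truth$relative, tolerance = 0.01)
  expect_equal(ev$duration, gen$truth$duration, tolerance = 0.05)
})

test_that("blockade summaries follow the notched-boxplot conventions", {
  x <- c(2, 4, 4, 5, 7, 9, 11)
  s <- summarize_blockades(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(s$median, q[2])
  expect_equal(s$q25, q[1])
  expect_equal(s$q75, q[3])
  expect_equal(s$notch_half, 1.57 * (q[3] - q[1]) / sqrt(7))
  # n = 1 degenerates gracefully
  s1 <- summarize_blockades(5)
  expect_equal(s1$median, 5)
  expect_equal(s1$q75 - s1$q25, 0)
  # symmetric sample: median ~ mean
  withr::with_seed(2, xs <- rnorm(4001, mean = 3))
  ss <- summarize_blockades(xs)
  expect_equal(ss$median, mean(xs), tolerance = 0.05)
  # whiskers stay inside the 1.5 IQR fences
  expect_gte(ss$whisker_lo, ss$q25 - 1.5 * (ss$q75 - ss$q25))
  expect_lte(ss$whisker_hi, ss$q75 + 1.5 * (ss$q75 - ss$q25))
})

test_that("IV fits recover ohmic conductance", {
  v <- seq(-200, 200, by = 2.5)
  fit <- fit_iv(v, 37.8 * v / 1000)
  expect_equal(fit$slope_nS, 37.8, tolerance = 1e-9)
  expect_equal(fit$intercept_nA, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # all-zero currents
  fit0 <- fit_iv(v, rep(0, length(v)))
  expect_equal(fit0$slope_nS, 0)
  # offset recovered
  fit2 <- fit_iv(v, 20 * v / 1000 + 0.5)
  expect_equal(fit2$intercept_nA, 0.5, tolerance = 1e-9)
  expect_equal(tidy(fit2)$estimate[1], 20, tolerance = 1e-9)
  expect_equal(glance(fit2)$r_squared, 1)
})
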