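#' Nanopore current/voltage trace record
#'
#' A sampled time series of ionic current with the applied-voltage channel.
#' Current is in nA, voltage in mV, so conductance in nS is
#' `1000 * current / voltage`.
#'
#' @param current Numeric current samples, nA.
#' @param voltage Voltage samples (mV), either a vector of the same length
#'   or a scalar applied voltage.
#' @param sample_rate Sampling rate in Hz.
#' @return A `trace_record` tibble with columns `time`, `current`,
#'   `voltage` and attribute `sample_rate`.
#' @export
trace_record <- function(current, voltage = 100, sample_rate) {
  stopifnot(sample_rate > 0)
  n <- length(current)
  if (length(voltage) == 1L) voltage <- rep(voltage, n)
  if (length(voltage) != n) {
    abort("Current and voltage series must have equal length.")
  }
  out <- tibble(time = (seq_len(n) - 1) / sample_rate,
                current = current, voltage = voltage)
  structure(out, class = c("trace_record", class(out)),
            sample_rate = sample_rate)
}

#' Sampling rate of a trace
#' @param trace A `trace_record`.
#' @return Rate in Hz.
#' @export
sample_rate <- function(trace) attr(trace, "sample_rate")

#' Gaussian low-pass filter
#'
#' Convolves the current channel with a discrete Gaussian kernel whose -3 dB
#' point sits at `cutoff` (kernel standard deviation
#' `sqrt(log(2)) / (2 pi f_c)`). The kernel is normalized to unit sum, so
#' the DC gain is exactly 1; edges are padded with the boundary values.
#'
#' @param trace A `trace_record` (or numeric vector, with `rate` supplied).
#' @param cutoff -3 dB frequency in Hz (default 1 kHz). Must be below the
#'   Nyquist frequency.
#' @param rate Sampling rate in Hz when `trace` is a plain vector.
#' @return Filtered trace of the same type as the input.
#' @export
gaussian_lowpass <- function(trace, cutoff = 1000, rate = sample_rate(trace)) {
  if (cutoff >= rate / 2) {
    abort("Filter cutoff must be below the Nyquist frequency.")
  }
  x <- if (is.data.frame(trace)) trace$current else as.numeric(trace)
  sigma_n <- sqrt(log(2)) / (2 * pi * cutoff) * rate
  half <- max(1L, ceiling(5 * sigma_n))
  k <- exp(-((-half):half)^2 / (2 * sigma_n^2))
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  y <- as.numeric(y)[(half + 1):(half + length(x))]
  if (is.data.frame(trace)) {
    trace$current <- y
    trace
  } else y
}

#' Split a trace at voltage-reversal zaps
#'
#' A docked ring is released by briefly reversing the applied voltage
#' ("zap"). This finds the reversal intervals (samples whose voltage sign
#' differs from the dominant polarity), removes them together with a guard
#' margin, and returns the per-docking segments in time order. A leading
#' empty segment (zap at t = 0) is dropped.
#'
#' @param trace A `trace_record` with a voltage channel.
#' @param guard Guard margin stripped on both sides of each zap, s.
#' @param expect_zaps If `TRUE` and no zap is found, the single returned
#'   segment carries attribute `no_zaps_found = TRUE` and a warning is
#'   raised.
#' @return List of `trace_record` segments, each with attribute `t_start`.
#' @export
segment_by_zaps <- function(trace, guard = 0.02, expect_zaps = FALSE) {
  rate <- sample_rate(trace)
  pol <- sign(median(sign(trace$voltage[trace$voltage != 0])))
  if (is.na(pol) || pol == 0) pol <- 1
  zap <- sign(trace$voltage) == -pol
  if (!any(zap)) {
    if (expect_zaps) {
      warn("No zaps found although at least one was expected.")
      out <- trace
      attr(out, "no_zaps_found") <- TRUE
      attr(out, "t_start") <- 0
      return(list(out))
    }
    attr(trace, "t_start") <- 0
    return(list(trace))
  }
  g <- ceiling(guard * rate)
  bad <- zap
  idx <- which(zap)
  for (k in idx) bad[max(1, k - g):min(length(bad), k + g)] <- TRUE
  runs <- rle(!bad)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    if (runs$lengths[k] < 2) next
    sub <- trace[starts[k]:ends[k], ]
    seg <- trace_record(sub$current, sub$voltage, rate)
    attr(seg, "t_start") <- trace$time[starts[k]]
    segs[[length(segs) + 1]] <- seg
  }
  segs
}

#' Detect baseline and ring conductance levels in a trace segment
#'
#' The segment is converted to conductance, histogrammed at 1000 bins per
#' nS, smoothed with a short moving average, and peaks at least
#' `min_peak_sep` nS apart are selected. The highest-conductance peak is the
#' baseline (open pore); the ring conductance is the mean of the remaining
#' peak positions. The result is invariant to the overall sign of the
#' current (voltage polarity).
#'
#' @param segment A `trace_record`.
#' @param applied_voltage Fallback scalar voltage (mV) when the segment has
#'   no voltage channel information.
#' @param bins_per_ns Histogram resolution, bins per nS.
#' @param smooth_bins Moving-average window, bins.
#' @param min_peak_sep Minimal distance between selected peaks, nS.
#' @param prominence_frac Minimum peak height as a fraction of the tallest
#'   peak.
#' @return A `level_fit` list: `baseline` (nS), `ring` (nS or `NA` when only
#'   one level is present), `peaks` tibble, `conductance` series.
#' @export
detect_levels <- function(segment, applied_voltage = 100, bins_per_ns = 1000,
                          smooth_bins = 25, min_peak_sep = 0.75,
                          prominence_frac = 0.01) {
  if (nrow(segment) == 0) abort("Zero-length segment.")
  v <- segment$voltage
  v[v == 0 | is.na(v)] <- applied_voltage
  g <- abs(1000 * segment$current / v)
  rng <- range(g)
  if (diff(rng) < 2 / bins_per_ns) rng <- rng + c(-1, 1) / bins_per_ns
  binw <- 1 / bins_per_ns
  nbin <- ceiling((rng[2] - rng[1]) / binw) + 1L
  idx <- pmin(nbin, 1L + as.integer(floor((g - rng[1]) / binw)))
  counts <- tabulate(idx, nbins = nbin)
  mids <- rng[1] + (seq_len(nbin) - 0.5) * binw
  if (smooth_bins > 1 && length(counts) > smooth_bins) {
    k <- rep(1 / smooth_bins, smooth_bins)
    sm <- stats::filter(counts, k, sides = 2)
    sm[is.na(sm)] <- 0
    counts <- as.numeric(sm)
  }
  pk <- pracma::findpeaks(c(0, counts, 0),
                          minpeakdistance = max(1, round(min_peak_sep * bins_per_ns)),
                          minpeakheight = prominence_frac * max(counts))
  if (is.null(pk)) {
    # monotone or single-bin histogram: fall back to the mode
    pos <- mids[which.max(counts)]
    peaks <- tibble(conductance = pos, height = max(counts))
  } else {
    peaks <- tibble(conductance = mids[pmin(length(mids), pmax(1, pk[, 2] - 1))],
                    height = pk[, 1])
    peaks <- peaks[order(peaks$conductance), ]
  }
  baseline <- max(peaks$conductance)
  ring <- if (nrow(peaks) > 1) {
    mean(peaks$conductance[peaks$conductance < baseline])
  } else NA_real_
  structure(list(baseline = baseline, ring = ring, peaks = peaks,
                 conductance = g),
            class = "level_fit")
}

#' Extract docking events from a current trace
#'
#' Full per-file pipeline: low-pass filter, split between zaps, fit the
#' conductance histogram of each segment, and locate the docked interval
#' (samples below the midpoint between baseline and ring level).
#'
#' @param trace A raw `trace_record`.
#' @param cutoff Low-pass cutoff, Hz.
#' @param guard Zap guard margin, s.
#' @param ... Passed to [detect_levels()].
#' @return A tibble of events: `segment`, `t_start`, `t_end`, `duration`
#'   (s), `baseline`, `ring` (nS), `relative` (`ring / baseline`). Segments
#'   with a single level produce no event row.
#' @export
extract_docking_events <- function(trace, cutoff = 1000, guard = 0.02, ...) {
  filt <- gaussian_lowpass(trace, cutoff)
  segs <- segment_by_zaps(filt, guard = guard)
  rate <- sample_rate(trace)
  purrr::imap_dfr(segs, function(seg, k) {
    lf <- detect_levels(seg, ...)
    if (is.na(lf$ring)) return(tibble())
    mid <- (lf$baseline + lf$ring) / 2
    docked <- which(lf$conductance < mid)
    if (length(docked) < 2) return(tibble())
    t0 <- attr(seg, "t_start")
    tibble(segment = k,
           t_start = t0 + (docked[1] - 1) / rate,
           t_end = t0 + (docked[length(docked)] - 1) / rate,
           duration = (docked[length(docked)] - docked[1] + 1) / rate,
           baseline = lf$baseline, ring = lf$ring,
           relative = lf$ring / lf$baseline)
  })
}

#' Filter docking events on baseline agreement and duration
#'
#' Keeps events whose baseline lies within `baseline_tol` of the estimated
#' average baseline (median across events unless given) and whose duration
#' is at least `min_length`.
#'
#' @param events Event tibble from [extract_docking_events()].
#' @param avg_baseline Estimated average baseline, nS; defaults to the
#'   median of the event baselines.
#' @param baseline_tol Allowed deviation from the average baseline, nS.
#' @param min_length Minimal event length, s.
#' @return The filtered event tibble.
#' @export
select_events <- function(events, avg_baseline = NULL, baseline_tol = 0.75,
                          min_length = 0.3) {
  if (nrow(events) == 0) return(events)
  if (is.null(avg_baseline)) avg_baseline <- median(events$baseline)
  events[abs(events$baseline - avg_baseline) <= baseline_tol &
           events$duration >= min_length, ]
}

#' Notched box-plot summary of relative conductances
#'
#' Quartiles use linear interpolation between closest ranks (R type 7); the
#' notch half-width is the Matlab-style 95% confidence interval of the
#' median, `1.57 * IQR / sqrt(n)`, and whiskers extend to the most extreme
#' points within 1.5 IQR of the quartiles (~ +-2.7 sigma for a normal
#' sample).
#'
#' @param x Numeric vector (e.g. relative conductances), or an event tibble
#'   with a `relative` column.
#' @return One-row tibble: `n`, `median`, `q25`, `q75`, `notch_half`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
summarize_blockades <- function(x) {
  if (is.data.frame(x)) x <- x$relative
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) abort("No values to summarize.")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  tibble(n = n, median = q[2], q25 = q[1], q75 = q[3],
         notch_half = 1.57 * iqr / sqrt(n),
         whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
         n_outliers = sum(!inside))
}

#' Fit a current-voltage (IV) curve
#'
#' Ordinary least-squares line through measured currents over an applied
#' voltage sweep; the slope is the ohmic conductance.
#'
#' @param voltage Voltages in mV (e.g. -200 to 200 mV in 2.5 mV steps).
#' @param current Currents in nA.
#' @return An `iv_fit` object wrapping the linear model; see
#'   [tidy.iv_fit()].
#' @export
fit_iv <- function(voltage, current) {
  stopifnot(length(voltage) == length(current))
  fit <- lm(current ~ voltage)
  slope_nS <- unname(coef(fit)[2]) * 1000 # nA/mV -> nS
  # noiseless synthetic sweeps trip the "essentially perfect fit" warning
  r2 <- suppressWarnings(summary(fit))$r.squared
  if (is.nan(r2)) r2 <- NA_real_
  structure(list(fit = fit, slope_nS = slope_nS,
                 intercept_nA = unname(coef(fit)[1]), r_squared = r2),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit> G = %.3f nS, intercept %.4f nA, R^2 = %s\n",
              x$slope_nS, x$intercept_nA,
              formatC(x$r_squared, digits = 6)))
  invisible(x)
}

#' Tidy methods for IV fits
#' @param x An `iv_fit`.
#' @param ... Unused.
#' @return `tidy()`: term/estimate table; `glance()`: one-row fit summary.
#' @export
tidy.iv_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope_nS, x$intercept_nA),
         unit = c("nS", "nA"))
}

#' @rdname tidy.iv_fit
#' @export
glance.iv_fit <- function(x, ...) {
  tibble(slope_nS = x$slope_nS, intercept_nA = x$intercept_nA,
         r_squared = x$r_squared)
}
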