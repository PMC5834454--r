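# Offline change-point detection by binary segmentation with an L2 cost:
# a segment is split where the split maximally reduces the sum of squared
# residuals, and the split is kept when that reduction exceeds the penalty.
.binseg <- function(y, penalty, min_size = 1L) {
  n <- length(y)
  S <- cumsum(y)
  S2 <- cumsum(y^2)
  sse <- function(i, j) {
    s <- S[j] - if (i > 1) S[i - 1] else 0
    s2 <- S2[j] - if (i > 1) S2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue) > 0) {
    seg <- queue[[1]]
    queue <- queue[-1]
    i <- seg[1]; j <- seg[2]
    if (j - i + 1 < 2 * min_size) next
    ks <- (i + min_size - 1):(j - min_size)
    nl <- ks - i + 1
    sl <- S[ks] - if (i > 1) S[i - 1] else 0
    s2l <- S2[ks] - if (i > 1) S2[i - 1] else 0
    sser_l <- s2l - sl^2 / nl
    nr <- j - ks
    sr <- S[j] - S[ks]
    s2r <- S2[j] - S2[ks]
    sser_r <- s2r - sr^2 / nr
    tot <- sser_l + sser_r
    k <- ks[which.min(tot)]
    gain <- sse(i, j) - min(tot)
    if (is.finite(gain) && gain > penalty) {
      cps <- c(cps, k)
      queue <- c(queue, list(c(i, k)), list(c(k + 1L, j)))
    }
  }
  sort(cps)
}

#' Count photobleaching steps in a TIRF intensity trace
#'
#' Fluorophores on a single particle bleach one by one, producing a
#' staircase of discrete downward intensity steps; the number of steps
#' reports the fluorophore copy number. Steps are located by offline
#' change-point detection (binary segmentation, L2 cost) with a penalty
#' calibrated on the noise standard deviation; the fitted level sequence is
#' then forced to be monotone non-increasing by merging any upward jumps,
#' and the remaining downward change-points are counted.
#'
#' @param intensity Numeric intensity trace (one value per frame), expected
#'   to end at the background level (assumed 0-mean after background
#'   subtraction).
#' @param frame_rate Frames per second (2 Hz for the recordings this
#'   emulates).
#' @param noise_sd Noise standard deviation; estimated from the median
#'   absolute successive difference when `NULL`.
#' @param penalty_factor Split penalty in units of `noise_sd^2 * log(n)`.
#' @param min_size Minimal segment length in frames.
#' @return A `bleach_counts` list: `n_steps`, `step_times` (s), `levels`
#'   (per-segment means), `changepoints` (frame indices), `noise_sd`,
#'   `reached_background` (flag; counting proceeds either way).
#' @export
#' @examples
#' y <- rep(c(3, 2, 1, 0), each = 40)
#' count_bleach_steps(y)$n_steps
count_bleach_steps <- function(intensity, frame_rate = 2, noise_sd = NULL,
                               penalty_factor = 3.5, min_size = 1L) {
  y <- as.numeric(intensity)
  n <- length(y)
  stopifnot(n >= 4)
  if (is.null(noise_sd)) {
    noise_sd <- median(abs(diff(y))) / (sqrt(2) * 0.6744898)
    if (noise_sd == 0) noise_sd <- 1e-12 # noiseless staircase
  }
  penalty <- penalty_factor * noise_sd^2 * log(n)
  cps <- .binseg(y, penalty, min_size = min_size)
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1), function(k) {
    mean(y[(bounds[k] + 1):(bounds[k + 1])])
  }, numeric(1))
  # enforce a monotone non-increasing level sequence
  repeat {
    up <- which(diff(levels) > 0)
    if (length(up) == 0) break
    k <- up[1]
    # merge segments k and k+1
    lo <- bounds[k] + 1; hi <- bounds[k + 2]
    levels[k] <- mean(y[lo:hi])
    levels <- levels[-(k + 1)]
    bounds <- bounds[-(k + 1)]
  }
  cps <- bounds[-c(1, length(bounds))]
  n_steps <- length(cps)
  reached <- abs(levels[length(levels)]) < 3 * max(noise_sd, 1e-12)
  if (!reached) {
    warn("Trace does not end at the background level; count may be partial.")
  }
  structure(list(n_steps = n_steps,
                 step_times = cps / frame_rate,
                 levels = levels, changepoints = cps,
                 noise_sd = noise_sd, reached_background = reached,
                 frame_rate = frame_rate, trace = y),
            class = "bleach_counts")
}

#' @export
print.bleach_counts <- function(x, ...) {
  cat(sprintf("<bleach_counts> %d steps%s\n", x$n_steps,
              if (x$reached_background) "" else " (background not reached)"))
  invisible(x)
}

#' @describeIn count_bleach_steps Tidy the detected steps into a tibble
#'   (`step`, `time`, `level_before`, `level_after`, `drop`).
#' @param x A `bleach_counts` object.
#' @param ... Unused.
#' @export
tidy.bleach_counts <- function(x, ...) {
  if (x$n_steps == 0) {
    return(tibble(step = integer(), time = numeric(),
                  level_before = numeric(), level_after = numeric(),
                  drop = numeric()))
  }
  tibble(step = seq_len(x$n_steps), time = x$step_times,
         level_before = x$levels[seq_len(x$n_steps)],
         level_after = x$levels[seq_len(x$n_steps) + 1],
         drop = -diff(x$levels))
}
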