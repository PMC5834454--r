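#' Generate an FG-repeat-like protein sequence
#'
#' Builds a sequence with the repeat architecture of FG-nucleoporin domains:
#' short hydrophobic motifs (FSFG by default) separated by hydrophilic
#' spacers, with a controllable fraction of charged residues (K/E in equal
#' numbers) scattered through the spacers. The construction is
#' deterministic for a fixed seed and hits the composition targets to
#' within rounding of single residues.
#'
#' @param length Sequence length in residues.
#' @param fg_motif_fraction Fraction of residues belonging to FG motifs.
#' @param charged_fraction Fraction of charged residues (split between K
#'   and E).
#' @param motif Motif string.
#' @param seed Integer seed.
#' @return Character scalar sequence.
#' @export
#' @examples
#' generate_fg_sequence(60, seed = 1)
generate_fg_sequence <- function(length = 60, fg_motif_fraction = 0.25,
                                 charged_fraction = 0.05, motif = "FSFG",
                                 seed = 1L) {
  stopifnot(length >= nchar(motif), fg_motif_fraction >= 0,
            fg_motif_fraction <= 0.8, charged_fraction >= 0,
            charged_fraction <= 0.5)
  spacer_alphabet <- c("G", "S", "T", "N", "Q", "A", "P")
  spacer_w <- c(0.24, 0.22, 0.14, 0.14, 0.1, 0.1, 0.06) # FG-domain-like bias
  withr::with_seed(seed, {
    m <- nchar(motif)
    n_motifs <- floor(fg_motif_fraction * length / m)
    n_charged <- round(charged_fraction * length)
    seq_chars <- sample(spacer_alphabet, length, replace = TRUE,
                        prob = spacer_w)
    if (n_motifs > 0) {
      # motifs evenly interspersed
      block <- length / n_motifs
      starts <- floor((seq_len(n_motifs) - 1) * block) + 1
      for (s in starts) seq_chars[s:(s + m - 1)] <- strsplit(motif, "")[[1]]
      motif_pos <- unlist(lapply(starts, function(s) s:(s + m - 1)))
    } else motif_pos <- integer(0)
    if (n_charged > 0) {
      free <- setdiff(seq_len(length), motif_pos)
      pos <- sample(free, min(n_charged, base::length(free)))
      seq_chars[pos] <- rep(c("K", "E"), length.out = base::length(pos))
    }
    paste(seq_chars, collapse = "")
  })
}

#' Replace hydrophobic F, I, L, V by hydrophilic serine
#'
#' The hydrophilic-mutant transformation: every phenylalanine, isoleucine,
#' leucine and valine becomes a serine; all other residues are untouched
#' and the length is preserved.
#'
#' @param sequence Character scalar (or vector) of residue codes.
#' @return Mutated sequence(s).
#' @export
#' @examples
#' mutate_filv_to_s("FSFG")  # "SSSG"
mutate_filv_to_s <- function(sequence) {
  chartr("FILV", "SSSS", sequence)
}

#' Generate a synthetic nanopore current trace with docking events
#'
#' Emulates a docking experiment: for each programmed event the trace holds
#' the open-pore baseline, drops to the ring conductance when a ring docks,
#' and is reset by a 10 ms voltage-reversal zap. Additive white Gaussian
#' noise is applied to the current. The programmed ground truth is returned
#' alongside the trace.
#'
#' @param baseline_nS Open-pore conductance, nS.
#' @param ring_nS Conductance with a ring docked, nS (scalar or one value
#'   per event).
#' @param n_events Number of docking events.
#' @param durations Docked durations in s (recycled); `NULL` draws them
#'   uniformly from `duration_range`.
#' @param duration_range Range for random docked durations, s.
#' @param predock_range Range of open-pore waiting time before each
#'   docking, s.
#' @param zap_duration Voltage-reversal duration, s.
#' @param voltage_mV Applied voltage, mV (reversed during zaps).
#' @param noise_sd Conductance-equivalent noise standard deviation, nS.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @return List with `trace` (a [trace_record()]) and `truth` (tibble:
#'   `event`, `t_dock`, `t_zap`, `duration`, `baseline`, `ring`,
#'   `relative`).
#' @export
generate_current_trace <- function(baseline_nS = 37.8, ring_nS = 32.9,
                                   n_events = 3, durations = NULL,
                                   duration_range = c(0.5, 1.5),
                                   predock_range = c(0.4, 0.8),
                                   zap_duration = 0.01, voltage_mV = 100,
                                   noise_sd = 0.2, sample_rate = 50000,
                                   seed = 1L) {
  withr::with_seed(seed, {
    ring_nS <- rep(ring_nS, length.out = n_events)
    if (is.null(durations)) {
      durations <- runif(n_events, duration_range[1], duration_range[2])
    } else durations <- rep(durations, length.out = n_events)
    g <- numeric(0)
    v <- numeric(0)
    truth <- vector("list", n_events)
    t_cursor <- 0
    for (k in seq_len(n_events)) {
      pre <- runif(1, predock_range[1], predock_range[2])
      n_pre <- round(pre * sample_rate)
      n_on <- round(durations[k] * sample_rate)
      n_zap <- round(zap_duration * sample_rate)
      g <- c(g, rep(baseline_nS, n_pre), rep(ring_nS[k], n_on),
             rep(baseline_nS, n_zap))
      v <- c(v, rep(voltage_mV, n_pre + n_on), rep(-voltage_mV, n_zap))
      truth[[k]] <- tibble(
        event = k, t_dock = t_cursor + n_pre / sample_rate,
        t_zap = t_cursor + (n_pre + n_on) / sample_rate,
        duration = n_on / sample_rate,
        baseline = baseline_nS, ring = ring_nS[k],
        relative = ring_nS[k] / baseline_nS)
      t_cursor <- t_cursor + (n_pre + n_on + n_zap) / sample_rate
    }
    # trailing open-pore stretch
    n_tail <- round(mean(predock_range) * sample_rate)
    g <- c(g, rep(baseline_nS, n_tail))
    v <- c(v, rep(voltage_mV, n_tail))
    current <- g * v / 1000 # nS * mV -> nA
    if (noise_sd > 0) {
      current <- current + rnorm(base::length(current),
                                 sd = noise_sd * abs(voltage_mV) / 1000)
    }
    list(trace = trace_record(current, v, sample_rate),
         truth = dplyr::bind_rows(truth))
  })
}

#' Generate a synthetic photobleaching staircase
#'
#' Per-fluorophore bleaching times are drawn from an exponential lifetime
#' distribution; the intensity starts at `n_steps * step_height` above the
#' background (0), drops by one step height at each bleaching event, and
#' carries additive white Gaussian noise.
#'
#' @param n_steps Number of fluorophores.
#' @param step_height Intensity drop per fluorophore (arbitrary units).
#' @param noise_sd Noise standard deviation (same units); step SNR is
#'   `step_height / noise_sd`.
#' @param frame_rate Frames per second.
#' @param mean_lifetime Mean bleaching lifetime per fluorophore, s.
#' @param tail Extra background-only recording after the last bleach, s.
#' @param seed Integer seed.
#' @return List with `intensity` (numeric trace), `time` (s), `truth`
#'   (tibble `fluorophore`, `t_bleach`).
#' @export
generate_bleach_trace <- function(n_steps = 8, step_height = 1,
                                  noise_sd = 0.2, frame_rate = 2,
                                  mean_lifetime = 250, tail = 60, seed = 1L) {
  withr::with_seed(seed, {
    t_bleach <- sort(rexp(n_steps, rate = 1 / mean_lifetime))
    t_end <- (if (n_steps > 0) max(t_bleach) else 0) + tail
    tt <- seq(0, t_end, by = 1 / frame_rate)
    level <- vapply(tt, function(t) sum(t_bleach > t) * step_height,
                    numeric(1))
    y <- level + rnorm(length(tt), sd = noise_sd)
    list(intensity = y, time = tt,
         truth = tibble(fluorophore = seq_len(n_steps), t_bleach = t_bleach))
  })
}

#' Generate an analytic 3D density field
#'
#' Test harness for the density reductions and the conductance model:
#' produces a [density_grid()] evaluated at cell centers from one of three
#' closed-form radial profile families, confined to `|z| <= z_half`.
#'
#' @param profile `"uniform"` (density `rho0` for `r <= r_max`),
#'   `"gaussian_radial"` (`rho0 * exp(-r^2 / (2 width^2))`) or `"annular"`
#'   (`rho0 * exp(-(r - r_peak)^2 / (2 width^2))`).
#' @param rho0 Peak density, mg/ml.
#' @param r_max Radius of the uniform disc, nm.
#' @param r_peak Annulus radius, nm.
#' @param width Gaussian width, nm.
#' @param z_half Axial half-extent of the field, nm.
#' @param cell Cell edge, nm.
#' @param box Box edge lengths, nm.
#' @return A `density_grid`; attribute `truth` stores the generating
#'   parameters and the profile function `rho_r(r)`.
#' @export
generate_density_field <- function(profile = c("uniform", "gaussian_radial",
                                               "annular"),
                                   rho0 = 50, r_max = 10, r_peak = 15,
                                   width = 8, z_half = 10, cell = 0.5,
                                   box = c(50, 50, 60)) {
  profile <- match.arg(profile)
  rho_r <- switch(profile,
    uniform = function(r) ifelse(r <= r_max, rho0, 0),
    gaussian_radial = function(r) rho0 * exp(-r^2 / (2 * width^2)),
    annular = function(r) rho0 * exp(-(r - r_peak)^2 / (2 * width^2))
  )
  dims <- as.integer(round(box / cell))
  origin <- -box / 2
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * cell
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * cell
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * cell
  rxy <- sqrt(outer(cx^2, cy^2, "+"))
  plane <- rho_r(rxy)
  rho <- array(0, dim = dims)
  zin <- abs(cz) <= z_half
  for (k in which(zin)) rho[, , k] <- plane
  g <- density_grid(rho, cell, origin = origin)
  attr(g, "truth") <- list(profile = profile, rho0 = rho0, r_max = r_max,
                           r_peak = r_peak, width = width, z_half = z_half,
                           rho_r = rho_r)
  g
}
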