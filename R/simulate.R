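#' Simulation protocol
#'
#' Bundles the Langevin-dynamics settings: timestep, temperature, friction,
#' step counts, the gradual switch-on schedule for the long-range
#' (hydrophobic-attraction and electrostatic) terms, seed and frame stride.
#' The default ramp switches the long-range terms on linearly over the
#' discarded equilibration window.
#'
#' @param timestep Integration timestep in ps. The default is stable for the
#'   stiff 0.38 nm bond at its default stiffness.
#' @param temperature Target temperature in K.
#' @param friction Langevin friction in ps-1.
#' @param n_steps Total number of steps.
#' @param n_discard Leading steps excluded from recorded frames (the
#'   equilibration window).
#' @param ramp Tibble with columns `step` and `scale` (non-decreasing, from 0
#'   to 1); `NULL` runs at full strength throughout.
#' @param seed Integer RNG seed.
#' @param stride Record every `stride`-th step after the discard window.
#' @return A `sim_protocol` list.
#' @export
sim_protocol <- function(timestep = 0.02, temperature = 300, friction = 0.5,
                         n_steps = 2e5, n_discard = 2e4,
                         ramp = tibble(step = c(0, n_discard / 2), scale = c(0, 1)),
                         seed = 1L, stride = 1000L) {
  stopifnot(timestep > 0, temperature >= 0, friction > 0,
            n_discard < n_steps, stride >= 1)
  if (!is.null(ramp)) {
    stopifnot(all(c("step", "scale") %in% names(ramp)))
    stopifnot(!is.unsorted(ramp$scale), all(ramp$scale >= 0 & ramp$scale <= 1))
    if (ramp$scale[1] > 0.1) {
      warn("Switch-on schedule does not start near zero scale.")
    }
  }
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, n_steps = as.integer(n_steps),
                 n_discard = as.integer(n_discard), ramp = ramp,
                 seed = as.integer(seed), stride = as.integer(stride)),
            class = "sim_protocol")
}

#' Desk-scale and production-scale protocol presets
#'
#' `desk_protocol()` is the default test-scale protocol (2e5 steps, first
#' 2e4 discarded). `production_scale_protocol()` encodes the production-scale run
#' of the full 32-chain system (5e7 steps, first 5e6 discarded); it is a
#' documented configuration, not something the test suite executes.
#'
#' @param seed Integer RNG seed.
#' @return A [sim_protocol()].
#' @export
desk_protocol <- function(seed = 1L) {
  sim_protocol(n_steps = 2e5, n_discard = 2e4, seed = seed)
}

#' @rdname desk_protocol
#' @export
production_scale_protocol <- function(seed = 1L) {
  sim_protocol(n_steps = 5e7, n_discard = 5e6, seed = seed, stride = 10000L)
}

#' Energy-minimize a system
#'
#' Adaptive steepest descent on the potential energy, used to remove bead
#' overlaps from freshly grown chains before dynamics. Long-range terms are
#' evaluated at `scale_hp`/`scale_el` (0 by default: minimization acts on
#' the excluded-volume and bonded landscape that the ramp later builds on).
#'
#' @param system A [cg_system()].
#' @param max_iter Iteration cap.
#' @param f_tol Convergence threshold on the maximum force component
#'   (kJ mol-1 nm-1).
#' @param scale_hp,scale_el Long-range scale factors during minimization.
#' @return The system with relaxed coordinates; attribute `minimize_info`
#'   holds `energy`, `energy_path` (non-increasing), `converged`, `f_max`,
#'   `n_iter`.
#' @export
minimize <- function(system, max_iter = 2000, f_tol = 10,
                     scale_hp = 0, scale_el = 0) {
  res <- engine_minimize(.positions(system), .sys_to_engine(system),
                         max_iter = as.integer(max_iter), f_tol = f_tol,
                         scale_hp = scale_hp, scale_el = scale_el)
  out <- .set_positions(system, res$pos)
  attr(out, "minimize_info") <- res[c("energy", "energy_path", "converged",
                                      "f_max", "n_iter")]
  out
}

#' Gradually switch on the long-range interactions
#'
#' Runs Langevin dynamics while the hydrophobic attraction and the
#' electrostatics are scaled up according to `schedule` (bonded and
#' excluded-volume terms stay at full strength). Returns the configuration
#' reached at the end of the ramp.
#'
#' @param system A minimized [cg_system()].
#' @param schedule Tibble with columns `step`, `scale`.
#' @param protocol A [sim_protocol()] supplying timestep/temperature/friction.
#' @return The system with updated coordinates.
#' @export
ramp_long_range <- function(system, schedule = tibble(step = c(0, 1e4),
                                                      scale = c(0, 1)),
                            protocol = sim_protocol()) {
  if (schedule$scale[1] > 0.1) warn("Ramp schedule does not start near zero.")
  n <- max(schedule$step)
  res <- withr::with_seed(protocol$seed, engine_langevin(
    .positions(system), .sys_to_engine(system),
    dt = protocol$timestep, temperature = protocol$temperature,
    gamma = protocol$friction, n_steps = as.integer(n), stride = as.integer(n),
    discard = 0L, sched_steps = schedule$step, sched_scales = schedule$scale
  ))
  .set_positions(system, res$pos)
}

#' Run Langevin dynamics
#'
#' BAOAB-splitting Langevin integration at the protocol temperature.
#' Scaffold beads and the anchored first bead of each chain are held fixed;
#' all randomness comes from R's RNG, so a fixed protocol seed reproduces
#' the trajectory bit for bit. Recording starts after the discard window.
#'
#' @param system A [cg_system()], typically after [minimize()].
#' @param protocol A [sim_protocol()].
#' @return A `cg_trajectory`: list with `frames` (`n_beads x 3 x n_frames`
#'   array, nm), `steps`, `ke_temp` (instantaneous kinetic temperature per
#'   frame), `system`, `protocol`.
#' @export
run_dynamics <- function(system, protocol = sim_protocol()) {
  ff <- system$ff
  if (!is.null(ff$bending)) {
    abort(paste0("The dynamics engine integrates the model without ",
                 "bending/torsion tables; disable them (forcefield(bending ",
                 "= NULL)) or evaluate them through bending_torsion_energy()."))
  }
  sched <- protocol$ramp
  if (is.null(sched)) sched <- tibble(step = 0, scale = 1)
  res <- withr::with_seed(protocol$seed, engine_langevin(
    .positions(system), .sys_to_engine(system),
    dt = protocol$timestep, temperature = protocol$temperature,
    gamma = protocol$friction, n_steps = protocol$n_steps,
    stride = protocol$stride, discard = protocol$n_discard,
    sched_steps = sched$step, sched_scales = sched$scale
  ))
  structure(list(frames = res$frames, steps = as.integer(res$steps),
                 ke_temp = res$ke_temp, final_pos = res$pos,
                 system = system, protocol = protocol),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames x %d beads (steps %s..%s of %s)\n",
              n_frames(x), dim(x$frames)[1],
              if (n_frames(x)) min(x$steps) else NA,
              if (n_frames(x)) max(x$steps) else NA,
              x$protocol$n_steps))
  invisible(x)
}

#' Number of recorded frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  dim(traj$frames)[3]
}

#' @describeIn run_dynamics Tidy a trajectory into a long tibble with one
#'   row per bead per frame (`frame`, `step`, `bead`, `type`, `chain`, `x`,
#'   `y`, `z`).
#' @param x A `cg_trajectory`.
#' @param ... Unused.
#' @export
tidy.cg_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  nb <- dim(x$frames)[1]
  b <- x$system$beads
  frames <- x$frames
  steps <- x$steps
  purrr::map_dfr(seq_len(nf), function(f) {
    tibble(frame = f, step = steps[f], bead = seq_len(nb),
           type = b$type, chain = b$chain,
           x = frames[, 1, f], y = frames[, 2, f], z = frames[, 3, f])
  })
}

#' @describeIn run_dynamics One-row summary of a trajectory.
#' @export
glance.cg_trajectory <- function(x, ...) {
  tibble(n_frames = n_frames(x), n_beads = dim(x$frames)[1],
         n_steps = x$protocol$n_steps, n_discard = x$protocol$n_discard,
         stride = x$protocol$stride,
         mean_ke_temp = mean(x$ke_temp), seed = x$protocol$seed)
}
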