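# Independent oracles shared across test files.

# quadrature oracle for the cross-section-averaged conductivity: integrate
# the piecewise-constant sigma(r) step profile with stats::integrate
oracle_region_sigma <- function(profile, model) {
  w <- profile$r[2] - profile$r[1]
  sig_at <- function(r) {
    idx <- findInterval(r, c(profile$r - w / 2, max(profile$r) + w / 2),
                        rightmost.closed = TRUE)
    rho <- ifelse(idx >= 1 & idx <= nrow(profile), profile$rho[pmax(1, idx)], 0)
    rho[idx < 1 | idx > nrow(profile)] <- 0
    pmax(0, model$sigma_bare * (1 - rho / model$rho_crit))
  }
  half <- model$diameter / 2
  int <- stats::integrate(function(r) 2 * pi * r * sig_at(r), 0, half,
                          subdivisions = 2000L, rel.tol = 1e-10,
                          stop.on.error = FALSE)$value
  4 / (pi * model$diameter^2) * int
}

# a "trajectory" holding fixed coordinates, for density-oracle tests
static_traj <- function(xyz, mass = 120, n_frames = 1, box = c(10, 10, 10)) {
  n <- nrow(xyz)
  beads <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          h = 0, charge = 0, mass = mass, diameter = 0.6,
                          mobile = TRUE, type = "protein", chain = 1L)
  sys <- cg_system(beads, tibble::tibble(i = integer(), j = integer()),
                   box = box)
  frames <- array(rep(as.vector(as.matrix(xyz)), n_frames),
                  dim = c(n, 3, n_frames))
  structure(list(frames = frames, steps = seq_len(n_frames),
                 ke_temp = rep(0, n_frames), system = sys,
                 protocol = sim_protocol(n_steps = 10, n_discard = 0,
                                         seed = 1, ramp = NULL)),
            class = "cg_trajectory")
}
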