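#' Desk-scale ring geometry
#'
#' The scaled-down study system used throughout the test suite and worked
#' examples: a ring of the same construction as the origami scaffold but
#' with a 20 nm outer diameter and 7 nm height, carrying 8 anchors, matched
#' to 60-residue chains so that grafted chains can reach and cross the ring
#' axis. The full-size geometry is available from [build_ring()] defaults.
#'
#' @param n_anchors Number of anchor sites.
#' @return A `ring_scaffold`.
#' @export
desk_ring <- function(n_anchors = 8) {
  build_ring(height = 7, outer_diameter = 20, bead_diameter = 2.6,
             n_anchors = n_anchors)
}

#' Simulate grafted chains in a ring and map their density
#'
#' End-to-end convenience wrapper: grafts `n_chains` copies of `sequence`
#' onto the ring, minimizes, runs Langevin dynamics with the gradual
#' switch-on ramp, accumulates the time-averaged protein density, and
#' reduces it to the cylindrical maps and the radial profile.
#'
#' @param sequence Residue sequence grafted at every occupied anchor.
#' @param n_chains Number of grafted chains.
#' @param seed Integer seed (chain initialization and dynamics).
#' @param ring A [build_ring()] scaffold.
#' @param protocol A [sim_protocol()]; its seed is overridden by `seed`.
#' @param ff A [forcefield()].
#' @param box Simulation box, nm.
#' @param params Residue parameter table.
#' @param zmax_profile Axial half-window for the radial profile, nm.
#' @return List: `system`, `trajectory`, `grid`, `rz`, `profile`,
#'   `sequence`.
#' @export
simulate_ring_variant <- function(sequence, n_chains = 8, seed = 1L,
                                  ring = desk_ring(), protocol = NULL,
                                  ff = forcefield(
                                    electrostatics = electrostatics_spec(
                                      screening_length = 0.48)),
                                  box = c(40, 40, 60),
                                  params = residue_params(),
                                  zmax_profile = 10) {
  if (is.null(protocol)) protocol <- desk_protocol(seed = seed)
  protocol$seed <- as.integer(seed)
  chains <- lapply(seq_len(n_chains), function(i) {
    sequence_to_chain(sequence, params = params, chain_id = i)
  })
  sys <- assemble_system(ring, chains, box = box, ff = ff, seed = seed)
  sys <- minimize(sys)
  traj <- run_dynamics(sys, protocol)
  grid <- accumulate_density(traj, cell = 0.5)
  rz <- circumferential_average(grid)
  prof <- radial_profile(rz, zmax = zmax_profile)
  list(system = sys, trajectory = traj, grid = grid, rz = rz,
       profile = prof, sequence = sequence)
}

#' Central z-averaged density
#'
#' Cell-weighted mean of the z-averaged radial density over the central
#' region `r <= r_max` — the "density at the central axis" summary used to
#' compare protein variants.
#'
#' @param profile Radial profile tibble from [radial_profile()].
#' @param r_max Central-region radius, nm.
#' @return Density in mg/ml.
#' @export
central_density <- function(profile, r_max = 5) {
  keep <- profile$r <= r_max
  counts <- attr(profile, "counts")
  if (is.null(counts)) counts <- rep(1, nrow(profile))
  sum(profile$rho[keep] * counts[keep]) / sum(counts[keep])
}

#' Hydrophobicity-dependent density and conductance experiment
#'
#' Runs the desk-scale ring system for a hydrophobic FG-like sequence and
#' its F,I,L,V -> S mutant over several seeds, recording the central
#' z-averaged density and the model conductance of each run. This is the
#' scaled-down analogue of comparing wild-type and hydrophilic-mutant
#' Nup-filled rings: the cohesive wild-type is expected to pack more mass
#' into the ring center and hence to conduct less.
#'
#' @param n_seeds Number of independent seeds.
#' @param base_seed Seed from which per-run seeds are derived.
#' @param length Chain length, residues.
#' @param n_chains Chains per ring.
#' @param pore A [pore_model()] used for the conductance readout (desk-scale
#'   pore diameter matched to the small ring).
#' @param protocol Optional [sim_protocol()] override.
#' @return Tibble: `seed`, `variant` (`"hydrophobic"`/`"mutant"`),
#'   `central_density` (mg/ml), `G` (nS), `relative` (vs the bare pore).
#' @export
run_trend_experiment <- function(n_seeds = 10, base_seed = 1L, length = 60,
                                 n_chains = 8,
                                 pore = pore_model(diameter = 14),
                                 protocol = NULL) {
  wt <- generate_fg_sequence(length, seed = base_seed)
  mut <- mutate_filv_to_s(wt)
  g_bare <- bare_pore_conductance(pore)
  ring <- desk_ring(n_anchors = n_chains)
  zh <- ring$height / 2
  r_lumen <- ring$inner_diameter / 2 - 0.4
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    seed_i <- base_seed * 1000L + i
    purrr::map_dfr(c(hydrophobic = wt, mutant = mut), function(sq) {
      run <- simulate_ring_variant(sq, n_chains = n_chains, seed = seed_i,
                                   ring = ring, protocol = protocol,
                                   zmax_profile = zh)
      prof_pore <- radial_profile(run$rz, zmax = zh)
      prof_acc <- radial_profile(run$rz, zwindow = c(zh, 20))
      G <- coated_pore_conductance(prof_pore, prof_acc, pore)$G
      tibble(central_density = central_density(run$profile,
                                               r_max = r_lumen),
             G = G, relative = G / g_bare)
    }, .id = "variant") |>
      dplyr::mutate(seed = seed_i, .before = 1)
  })
}

#' Run the standard pipeline from a configuration
#'
#' Thin orchestration over the package functions: generates (or accepts) a
#' sequence, simulates the ring system, maps densities, computes the model
#' conductance, and writes all artifacts to `out_dir`.
#'
#' @param config A [run_config()].
#' @param sequence Optional sequence; generated from the config seed when
#'   `NULL`.
#' @param out_dir Optional output directory for [write_run_outputs()].
#' @return List of results (as [simulate_ring_variant()], plus
#'   `conductance`).
#' @export
run_pipeline <- function(config = run_config(), sequence = NULL,
                         out_dir = NULL) {
  seed <- as.integer(config$seed)
  if (is.null(sequence)) sequence <- generate_fg_sequence(60, seed = seed)
  ring <- build_ring(config$ring$height, config$ring$outer_diameter,
                     config$ring$bead_diameter, config$ring$n_anchors)
  ff <- forcefield(
    hydrophobic = hydrophobic_spec(eps_max = config$forcefield$eps_max,
                                   sigma = config$forcefield$sigma,
                                   cutoff = config$forcefield$hp_cutoff),
    electrostatics = electrostatics_spec(
      screening_length = config$forcefield$screening_length),
    bond_r0 = config$forcefield$bond_r0, bond_k = config$forcefield$bond_k)
  protocol <- sim_protocol(timestep = config$protocol$timestep,
                           temperature = config$protocol$temperature,
                           friction = config$protocol$friction,
                           n_steps = config$protocol$n_steps,
                           n_discard = config$protocol$n_discard,
                           stride = config$protocol$stride, seed = seed)
  run <- simulate_ring_variant(sequence, n_chains = min(8, ring$n_anchors),
                               seed = seed, ring = ring, protocol = protocol,
                               ff = ff, box = config$grid$box)
  pm <- pore_model(config$pore$diameter, config$pore$length,
                   config$pore$sigma_bare, config$pore$rho_crit)
  prof_pore <- radial_profile(run$rz, zmax = min(10, ring$height / 2))
  prof_acc <- radial_profile(run$rz,
                             zwindow = c(min(10, ring$height / 2), 40))
  run$conductance <- coated_pore_conductance(prof_pore, prof_acc, pm)
  if (!is.null(out_dir)) {
    write_run_outputs(out_dir, config, trajectory = run$trajectory,
                      grid = run$grid, profiles = run$profile,
                      summary = glance(run$conductance))
  }
  run
}
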