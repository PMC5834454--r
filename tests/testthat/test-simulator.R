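test_that("protocol validates its invariants", {
  expect_error(sim_protocol(n_steps = 100, n_discard = 100))
  expect_error(sim_protocol(stride = 0))
  expect_warning(sim_protocol(ramp = tibble::tibble(step = c(0, 10),
                                                    scale = c(0.5, 1))),
                 "near zero")
  p <- desk_protocol(seed = 3)
  expect_equal(p$n_steps, 2e5)
  expect_equal(p$n_discard, 2e4)
  # production-scale preset is encoded but not executed here
  pp <- production_scale_protocol()
  expect_equal(pp$n_steps, 5e7)
  expect_equal(pp$n_discard, 5e6)
})

test_that("minimization removes overlaps and never increases the energy", {
  # two beads overlapping at 0.1 sigma
  beads <- tibble::tibble(x = c(0, 0.06), y = 0, z = 0, h = 0, charge = 0,
                          mass = 120, diameter = 0.6, mobile = TRUE,
                          type = "protein", chain = 1L)
  sys <- cg_system(beads, tibble::tibble(i = integer(), j = integer()))
  out <- minimize(sys)
  info <- attr(out, "minimize_info")
  sep <- abs(out$beads$x[2] - out$beads$x[1])
  expect_gt(sep, 0.8 * 0.6)
  expect_true(all(diff(info$energy_path) <= 0))

  # an isolated bead at the origin is already minimal
  one <- cg_system(beads[1, ], tibble::tibble(i = integer(), j = integer()))
  out1 <- minimize(one)
  expect_equal(out1$beads$x, one$beads$x)
})

test_that("ramp scales the long-range terms exactly", {
  sys <- toy_chain_system(n = 4, h = 1, spacing = 0.7)
  full <- total_energy_forces(sys, 1, 1)$terms
  half <- total_energy_forces(sys, 0.5, 0.5)$terms
  zero <- total_energy_forces(sys, 0, 0)$terms
  # attraction beyond the repulsive core scales linearly; bonds do not
  expect_equal(zero[["hydrophobic"]], 0) # all pair distances > rmin here
  expect_equal(half[["hydrophobic"]], full[["hydrophobic"]] / 2)
  expect_equal(half[["bond"]], full[["bond"]])

  # charged pair: electrostatics scales linearly too
  sysq <- toy_chain_system(n = 2, h = 0, charge = c(1, -1), spacing = 0.7)
  expect_equal(total_energy_forces(sysq, 0, 0.5)$terms[["electrostatic"]],
               total_energy_forces(sysq, 0, 1)$terms[["electrostatic"]] / 2)
})

test_that("dynamics is deterministic, tethered, and thermostatted", {
  ring <- desk_ring()
  chains <- list(sequence_to_chain("GSFGNSTGSF", chain_id = 1))
  sys <- minimize(assemble_system(ring, chains, box = c(40, 40, 60), seed = 2))
  prot <- sim_protocol(n_steps = 4000, n_discard = 1000, stride = 100,
                       seed = 9, ramp = tibble::tibble(step = c(0, 500),
                                                       scale = c(0, 1)))
  t1 <- run_dynamics(sys, prot)
  t2 <- run_dynamics(sys, prot)
  expect_identical(t1$frames, t2$frames) # same seed, same trajectory
  t3 <- run_dynamics(sys, sim_protocol(n_steps = 4000, n_discard = 1000,
                                       stride = 100, seed = 10))
  expect_false(identical(t1$frames, t3$frames))
  # frame count contract
  expect_equal(n_frames(t1), (4000 - 1000) / 100)
  # anchored bead 1 of the chain never moves
  i0 <- which(sys$beads$type == "protein")[1]
  a <- c(sys$beads$x[i0], sys$beads$y[i0], sys$beads$z[i0])
  for (f in seq_len(n_frames(t1))) {
    expect_equal(t1$frames[i0, , f], a)
  }
  expect_true(all(is.finite(t1$frames)))
})

test_that("too-large timesteps abort with the offending step", {
  sys <- toy_chain_system(n = 3)
  prot <- sim_protocol(timestep = 2, n_steps = 1000, n_discard = 10,
                       stride = 100, seed = 1, ramp = NULL)
  expect_error(run_dynamics(sys, prot), "timestep too large")
})

test_that("dynamics rejects enabled bending tables", {
  tab <- bending_tables(angle = tibble::tibble(theta = c(0, pi / 2, pi),
                                               energy = c(1, 0, 1)))
  sys <- toy_chain_system(n = 3, ff = forcefield(bending = tab))
  expect_error(run_dynamics(sys, sim_protocol(n_steps = 100, n_discard = 10)),
               "bending")
})

test_that("zero-temperature dynamics descends toward the minimized state", {
  # stretched bond relaxes to its rest length under damped dynamics
  beads <- tibble::tibble(x = c(0, 0.6), y = 0, z = 0, h = 0, charge = 0,
                          mass = 120, diameter = 0.6,
                          mobile = c(FALSE, TRUE), type = "protein",
                          chain = 1L)
  sys <- cg_system(beads, tibble::tibble(i = 1L, j = 2L))
  prot <- sim_protocol(temperature = 0, friction = 5, n_steps = 5000,
                       n_discard = 100, stride = 100, seed = 1, ramp = NULL)
  tr <- run_dynamics(sys, prot)
  final <- tr$frames[, , n_frames(tr)]
  expect_equal(abs(final[2, 1] - final[1, 1]), 0.38, tolerance = 1e-3)
})

test_that("trajectory tidiers expose frames as tibbles", {
  sys <- toy_chain_system(n = 3)
  tr <- run_dynamics(sys, sim_protocol(n_steps = 500, n_discard = 100,
                                       stride = 100, seed = 2, ramp = NULL))
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), n_frames(tr) * 3)
  expect_true(all(c("frame", "step", "bead", "x", "y", "z") %in% names(td)))
  gl <- glance(tr)
  expect_equal(gl$n_frames, n_frames(tr))
})
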