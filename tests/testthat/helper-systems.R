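# Small systems and fixtures built in code for the unit tests.

# a free chain of n beads along x, no scaffold
toy_chain_system <- function(n = 5, h = 0.5, charge = 0, spacing = 0.38,
                             box = c(50, 50, 50), ff = forcefield()) {
  beads <- tibble::tibble(
    x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    h = rep_len(h, n), charge = rep_len(charge, n), mass = 120,
    diameter = 0.6, mobile = TRUE, type = "protein", chain = 1L
  )
  bonds <- if (n > 1) tibble::tibble(i = seq_len(n - 1), j = seq_len(n - 1) + 1)
    else tibble::tibble(i = integer(), j = integer())
  cg_system(beads, bonds, ff = ff, box = box)
}

# a random nonbonded cluster, pairs kept away from cutoff shells
toy_random_system <- function(n = 6, seed = 1, charged = TRUE,
                              ff = forcefield(), box = c(50, 50, 50)) {
  withr::with_seed(seed, {
    repeat {
      pos <- matrix(rnorm(3 * n, sd = 0.7), n, 3)
      d <- as.matrix(dist(pos))
      diag(d) <- 1
      shells <- c(ff$hydrophobic$cutoff, ff$el_cutoff,
                  2^(1 / 6) * ff$hydrophobic$sigma)
      away <- all(d > 0.35) &&
        all(vapply(shells, function(s) all(abs(d - s) > 1e-3), logical(1)))
      if (away) break
    }
    beads <- tibble::tibble(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      h = runif(n), charge = if (charged) sample(c(-1, 0, 1), n, TRUE) else 0,
      mass = runif(n, 80, 180), diameter = 0.6, mobile = TRUE,
      type = "protein", chain = 1L
    )
    cg_system(beads, tibble::tibble(i = integer(), j = integer()),
              ff = ff, box = box)
  })
}

# finite-difference gradient of the reference energy
fd_forces <- function(system, h = 1e-6, scale_hp = 1, scale_el = 1) {
  pos <- npcmimic:::.positions(system)
  n <- nrow(pos)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      ep <- em <- system
      pp <- pos; pp[i, d] <- pp[i, d] + h
      pm <- pos; pm[i, d] <- pm[i, d] - h
      ep <- npcmimic:::.set_positions(ep, pp)
      em <- npcmimic:::.set_positions(em, pm)
      out[i, d] <- -(total_energy_forces(ep, scale_hp, scale_el,
                                         engine = "reference")$energy -
                       total_energy_forces(em, scale_hp, scale_el,
                                           engine = "reference")$energy) /
        (2 * h)
    }
  }
  out
}
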