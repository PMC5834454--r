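#' Low-level simulated-system constructor
#'
#' Bundles bead coordinates and per-bead parameters with the bond topology,
#' force field, simulation box and optional membrane into the object the
#' energy routines and the dynamics engine operate on. Most users will build
#' systems with [assemble_system()]; this constructor is exported for tests
#' and custom geometries.
#'
#' @param beads Tibble with columns `x`, `y`, `z`, `h`, `charge`, `mass`,
#'   `diameter`, `mobile` (logical), `type` (`"protein"` or `"scaffold"`)
#'   and `chain` (integer id, `NA` for scaffold).
#' @param bonds Tibble with integer columns `i`, `j` (1-based bead indices).
#' @param ff A [forcefield()].
#' @param box Numeric `c(lx, ly, lz)` box edge lengths in nm, centered on the
#'   origin; the walls are soft-reflecting.
#' @param pore Optional [build_membrane_pore()].
#' @return A `cg_system` list.
#' @export
cg_system <- function(beads, bonds, ff = forcefield(), box = c(100, 100, 140),
                      pore = NULL) {
  need <- c("x", "y", "z", "h", "charge", "mass", "diameter", "mobile", "type")
  stopifnot(all(need %in% names(beads)))
  if (!"chain" %in% names(beads)) beads$chain <- NA_integer_
  stopifnot(all(beads$mass > 0), all(beads$h >= 0 & beads$h <= 1))
  bonds <- tibble::as_tibble(bonds)
  structure(list(beads = tibble::as_tibble(beads), bonds = bonds, ff = ff,
                 box = box, pore = pore),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<cg_system> %d beads (%d mobile), %d bonds, box %s nm%s\n",
              nrow(x$beads), sum(x$beads$mobile), nrow(x$bonds),
              paste(x$box, collapse = " x "),
              if (is.null(x$pore)) "" else ", with membrane pore"))
  invisible(x)
}

.positions <- function(system) {
  as.matrix(system$beads[, c("x", "y", "z")])
}

.set_positions <- function(system, pos) {
  system$beads$x <- pos[, 1]; system$beads$y <- pos[, 2]; system$beads$z <- pos[, 3]
  system
}

# Marshal a cg_system into the plain list the C++ engine consumes.
.sys_to_engine <- function(system) {
  b <- system$beads
  ff <- system$ff
  hs <- ff$hydrophobic
  es <- ff$electrostatics
  list(
    h = b$h, q = b$charge, mass = b$mass, sigma = b$diameter,
    mobile = as.integer(b$mobile),
    bonds = cbind(as.integer(system$bonds$i) - 1L,
                  as.integer(system$bonds$j) - 1L),
    bond_r0 = ff$bond_r0, bond_k = ff$bond_k,
    eps_max = hs$eps_max, rc_hp = hs$cutoff,
    comb_rule = if (hs$combination == "arithmetic") 0L else 1L,
    kappa_inv = es$screening_length, rc_el = ff$el_cutoff,
    diel_mode = if (es$dielectric == "constant") 0L else 1L,
    diel_eps = es$eps0, diel_c = es$diel_c, diel_lambda = es$diel_lambda,
    k_wall = ff$k_wall,
    box_lo = -system$box / 2, box_hi = system$box / 2,
    has_mem = !is.null(system$pore),
    mem_zlo = if (is.null(system$pore)) 0 else system$pore$z_interval[1],
    mem_zhi = if (is.null(system$pore)) 0 else system$pore$z_interval[2],
    mem_rpore = if (is.null(system$pore)) 0 else system$pore$diameter / 2
  )
}

#' Total potential energy and per-bead forces
#'
#' Sums every interaction term of the model (bonds, hydrophobicity-scaled
#' pair attraction, screened electrostatics, box and membrane walls) and
#' returns the energy together with the exact negative-gradient forces.
#' Two implementations are available: the compiled engine (default, used by
#' the simulator) and a plain-R reference used to cross-validate it.
#'
#' @param system A [cg_system()].
#' @param scale_hp,scale_el Scale factors in `[0, 1]` applied to the
#'   hydrophobic attraction and the electrostatics (bonded and
#'   excluded-volume terms are always at full strength); used by the
#'   switch-on ramp.
#' @param engine `"compiled"` or `"reference"`.
#' @return List with `energy` (kJ/mol), `forces` (n x 3 matrix, kJ mol-1
#'   nm-1) and `terms` (named per-term energies).
#' @export
total_energy_forces <- function(system, scale_hp = 1, scale_el = 1,
                                engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  pos <- .positions(system)
  if (engine == "compiled") {
    res <- engine_energy_forces(pos, .sys_to_engine(system), scale_hp, scale_el)
    return(list(energy = res$energy, forces = res$forces,
                terms = unlist(res$terms)))
  }
  .reference_energy_forces(pos, system, scale_hp, scale_el)
}

# Plain-R reference implementation (O(n^2), small systems only).
.reference_energy_forces <- function(pos, system, scale_hp = 1, scale_el = 1) {
  b <- system$beads
  ff <- system$ff
  hs <- ff$hydrophobic
  es <- ff$electrostatics
  n <- nrow(pos)
  forces <- matrix(0, n, 3)
  e_bond <- e_hp <- e_el <- e_wall <- 0

  bonded <- rep(FALSE, n * n)
  if (nrow(system$bonds) > 0) {
    ii <- pmin(system$bonds$i, system$bonds$j)
    jj <- pmax(system$bonds$i, system$bonds$j)
    bonded[(ii - 1) * n + jj] <- TRUE
  }

  # bonds
  if (nrow(system$bonds) > 0) {
    for (k in seq_len(nrow(system$bonds))) {
      i <- system$bonds$i[k]; j <- system$bonds$j[k]
      d <- pos[i, ] - pos[j, ]
      r <- sqrt(sum(d^2))
      if (r < 1e-6) abort(sprintf("Overlapping bonded beads %d and %d.", i, j))
      e_bond <- e_bond + 0.5 * ff$bond_k * (r - ff$bond_r0)^2
      dU <- ff$bond_k * (r - ff$bond_r0)
      f <- -dU * d / r
      forces[i, ] <- forces[i, ] + f
      forces[j, ] <- forces[j, ] - f
    }
  }

  # nonbonded pairs
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!b$mobile[i] && !b$mobile[j]) next
        if (bonded[(i - 1) * n + j]) next
        d <- pos[i, ] - pos[j, ]
        r2 <- sum(d^2)
        if (r2 < 1e-12) abort(sprintf("Overlapping beads %d and %d at r = 0.", i, j))
        r <- sqrt(r2)
        sij <- (b$diameter[i] + b$diameter[j]) / 2
        lam <- scale_hp * .lambda_pair(b$h[i], b$h[j], hs$combination)
        rcp <- max(hs$cutoff, 2^(1 / 6) * sij)
        if (r < rcp) {
          ah <- .ah_energy(r, lam, hs$eps_max, sij, hs$cutoff, deriv = TRUE)
          e_hp <- e_hp + ah$energy
          f <- -ah$dUdr * d / r
          forces[i, ] <- forces[i, ] + f
          forces[j, ] <- forces[j, ] - f
        }
        qq <- b$charge[i] * b$charge[j]
        if (qq != 0 && r < ff$el_cutoff && scale_el > 0) {
          g <- function(rr) exp(-rr / es$screening_length) /
            (dielectric_at(rr, es) * rr)
          U <- scale_el * .ke_coulomb * qq * (g(r) - g(ff$el_cutoff))
          eps_r <- dielectric_at(r, es)
          deps <- if (es$dielectric == "constant") 0 else
            es$eps0 * es$diel_c / es$diel_lambda * exp(-r / es$diel_lambda)
          dg <- exp(-r / es$screening_length) *
            (-1 / (es$screening_length * eps_r * r) - 1 / (eps_r * r2) -
               deps / (eps_r^2 * r))
          dU <- scale_el * .ke_coulomb * qq * dg
          e_el <- e_el + U
          f <- -dU * d / r
          forces[i, ] <- forces[i, ] + f
          forces[j, ] <- forces[j, ] - f
        }
      }
    }
  }

  # box walls
  lo <- -system$box / 2; hi <- system$box / 2
  for (i in seq_len(n)) {
    for (dm in 1:3) {
      if (pos[i, dm] < lo[dm]) {
        dlt <- lo[dm] - pos[i, dm]
        e_wall <- e_wall + 0.5 * ff$k_wall * dlt^2
        forces[i, dm] <- forces[i, dm] + ff$k_wall * dlt
      } else if (pos[i, dm] > hi[dm]) {
        dlt <- pos[i, dm] - hi[dm]
        e_wall <- e_wall + 0.5 * ff$k_wall * dlt^2
        forces[i, dm] <- forces[i, dm] - ff$k_wall * dlt
      }
    }
  }

  # membrane slab with pore
  if (!is.null(system$pore)) {
    zlo <- system$pore$z_interval[1]; zhi <- system$pore$z_interval[2]
    rp <- system$pore$diameter / 2
    for (i in seq_len(n)) {
      z <- pos[i, 3]
      rxy <- sqrt(pos[i, 1]^2 + pos[i, 2]^2)
      if (z > zlo && z < zhi && rxy > rp) {
        d_top <- zhi - z; d_bot <- z - zlo; d_in <- rxy - rp
        dlt <- min(d_top, d_bot, d_in)
        e_wall <- e_wall + 0.5 * ff$k_wall * dlt^2
        if (dlt == d_top) {
          forces[i, 3] <- forces[i, 3] + ff$k_wall * dlt
        } else if (dlt == d_bot) {
          forces[i, 3] <- forces[i, 3] - ff$k_wall * dlt
        } else {
          forces[i, 1:2] <- forces[i, 1:2] - ff$k_wall * dlt * pos[i, 1:2] / rxy
        }
      }
    }
  }

  list(energy = e_bond + e_hp + e_el + e_wall, forces = forces,
       terms = c(bond = e_bond, hydrophobic = e_hp, electrostatic = e_el,
                 wall = e_wall))
}

# Self-avoiding random walk growing a chain inward from its anchor.
.grow_chain <- function(chain, anchor_xyz, inward, placed, placed_sigma,
                        r0, box, pore, max_retry = 200) {
  n <- nrow(chain)
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- anchor_xyz
  dirprev <- inward
  for (k in 2:n) {
    sig_new <- chain$diameter[k]
    ok <- FALSE
    for (t in seq_len(max_retry)) {
      prop <- dirprev + 0.8 * rnorm(3) + 0.15 * inward
      prop <- prop / sqrt(sum(prop^2))
      cand <- coords[k - 1, ] + r0 * prop
      if (any(abs(cand) > box / 2 - 0.5)) next
      if (!is.null(pore) &&
          in_membrane_wall(cand[1], cand[2], cand[3], pore)) next
      prev <- rbind(placed, coords[seq_len(k - 2), , drop = FALSE])
      prev_sigma <- c(placed_sigma, chain$diameter[seq_len(k - 2)])
      if (nrow(prev) > 0) {
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (any(d2 < (0.8 * (prev_sigma + sig_new) / 2)^2)) next
      }
      coords[k, ] <- cand
      dirprev <- prop
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  coords
}

#' Assemble a ring scaffold with grafted chains into a simulated system
#'
#' Chains are assigned to anchors with even index striding (8 chains on a
#' 32-anchor ring occupy anchors 1, 5, 9, ...), their first bead fixed at the
#' anchor coordinate, and the remaining beads initialized as self-avoiding
#' random walks growing inward. Initialization is deterministic for a given
#' seed.
#'
#' @param ring A [build_ring()] scaffold.
#' @param chains List of [sequence_to_chain()] objects (may be empty).
#' @param pore Optional [build_membrane_pore()].
#' @param box Box edge lengths `c(lx, ly, lz)` in nm.
#' @param ff A [forcefield()].
#' @param seed Integer seed for chain initialization.
#' @return A [cg_system()] whose beads hold the scaffold plus chain beads;
#'   anchored bead 1 of each chain (and every scaffold bead) is immobile.
#' @export
assemble_system <- function(ring, chains = list(), pore = NULL,
                            box = c(100, 100, 140), ff = forcefield(),
                            seed = 1L) {
  n_chain <- length(chains)
  if (n_chain > ring$n_anchors) {
    abort("More chains than anchor sites on the ring.")
  }
  scaffold <- tibble(
    x = ring$beads$x, y = ring$beads$y, z = ring$beads$z,
    h = 0, charge = 0, mass = 650, # inert DNA-scaffold beads
    diameter = ring$bead_diameter, mobile = FALSE, type = "scaffold",
    chain = NA_integer_, code = "X"
  )
  beads <- scaffold
  bonds <- tibble(i = integer(), j = integer())
  if (n_chain > 0) {
    anchor_idx <- (seq_len(n_chain) - 1) * (ring$n_anchors %/% n_chain) + 1
    withr::with_seed(seed, {
      placed <- .positions_of(beads)
      sig <- beads$diameter
      for (c_i in seq_len(n_chain)) {
        ch <- chains[[c_i]]
        a <- ring$anchors[anchor_idx[c_i], ]
        anchor_xyz <- c(a$x, a$y, a$z)
        inward <- -c(cos(a$theta), sin(a$theta), 0)
        coords <- NULL
        for (attempt in 1:20) {
          coords <- .grow_chain(ch, anchor_xyz, inward, placed, sig,
                                attr(ch, "r0"), box, pore)
          if (!is.null(coords)) break
        }
        if (is.null(coords)) {
          abort(sprintf(
            "Chain %d could not be initialized without collisions (seed %d).",
            c_i, seed))
        }
        offset <- nrow(beads)
        beads <- dplyr::bind_rows(beads, tibble(
          x = coords[, 1], y = coords[, 2], z = coords[, 3],
          h = ch$h, charge = ch$charge, mass = ch$mass,
          diameter = ch$diameter,
          mobile = c(FALSE, rep(TRUE, nrow(ch) - 1)), # bead 1 held at anchor
          type = "protein", chain = c_i, code = ch$code
        ))
        bonds <- dplyr::bind_rows(bonds, tibble(
          i = offset + seq_len(nrow(ch) - 1),
          j = offset + 1 + seq_len(nrow(ch) - 1)
        ))
        placed <- rbind(placed, coords)
        sig <- c(sig, ch$diameter)
      }
    })
  }
  sys <- cg_system(beads, bonds, ff = ff, box = box, pore = pore)
  sys$ring <- ring
  attr(sys, "anchor_indices") <- if (n_chain > 0) anchor_idx else integer()
  attr(sys, "seed") <- seed
  sys
}

.positions_of <- function(beads) {
  cbind(beads$x, beads$y, beads$z)
}
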