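#' Hydrophobic pair-interaction specification
#'
#' The hydrophobic attraction between beads is a hydrophobicity-scaled
#' (Ashbaugh-Hatch style) 12-6 Lennard-Jones potential: the repulsive core is
#' always present, while the well depth equals `eps_max` times the combined
#' hydrophobicity of the pair (arithmetic mean `(h_i + h_j)/2` by default).
#' The potential is truncated at `cutoff` with a force-shift so that both the
#' energy and the force go continuously to zero there. A fully hydrophilic
#' pair (`h_i = h_j = 0`) therefore interacts through a purely repulsive
#' (WCA) core.
#'
#' @param eps_max Well-depth scale in kJ/mol reached by a maximally
#'   hydrophobic pair (`h_i = h_j = 1`). The default (3 kJ/mol, ~1.2 kT at
#'   300 K) puts phenylalanine contacts at about 1 kT and the
#'   sequence-average FG-domain contact near the coil-globule transition,
#'   the regime in which FG domains form dilute cohesive networks of tens
#'   of mg/ml rather than collapsed globules.
#' @param sigma Lennard-Jones length scale in nm (bead diameter).
#' @param cutoff Truncation radius in nm.
#' @param combination `"arithmetic"` (`(h_i+h_j)/2`) or `"geometric"`
#'   (`sqrt(h_i h_j)`) combination rule.
#' @return A `hydrophobic_spec` list.
#' @export
hydrophobic_spec <- function(eps_max = 3, sigma = 0.6, cutoff = 1.5,
                             combination = c("arithmetic", "geometric")) {
  combination <- match.arg(combination)
  stopifnot(eps_max >= 0, sigma > 0, cutoff > 0)
  structure(list(eps_max = eps_max, sigma = sigma, cutoff = cutoff,
                 combination = combination),
            class = "hydrophobic_spec")
}

#' Screened-electrostatics specification
#'
#' Charged beads interact through a Yukawa (Debye-screened Coulomb)
#' potential. Solvent polarity enters either through a constant dielectric
#' or a distance-dependent saturating dielectric
#' `eps(r) = eps0 * (1 - c * exp(-r / lambda))`, which reduces the effective
#' permittivity at short range where the bulk water response is suppressed.
#'
#' @param screening_length Debye length in nm (`> 0`).
#' @param dielectric `"saturating"` (default) or `"constant"`.
#' @param eps0 Bulk relative permittivity.
#' @param diel_c,diel_lambda Saturation amplitude (in `(0, 1)`) and decay
#'   length (nm) of the distance-dependent dielectric.
#' @param temperature Temperature in K.
#' @return An `electrostatics_spec` list.
#' @export
electrostatics_spec <- function(screening_length = 0.8,
                                dielectric = c("saturating", "constant"),
                                eps0 = 80, diel_c = 0.85, diel_lambda = 0.5,
                                temperature = 300) {
  dielectric <- match.arg(dielectric)
  stopifnot(screening_length > 0, eps0 > 1, eps0 <= 80.5)
  if (dielectric == "saturating") stopifnot(diel_c > 0, diel_c < 1, diel_lambda > 0)
  structure(list(screening_length = screening_length, dielectric = dielectric,
                 eps0 = eps0, diel_c = diel_c, diel_lambda = diel_lambda,
                 temperature = temperature),
            class = "electrostatics_spec")
}

#' Relative permittivity at separation r
#' @param r Separation(s) in nm.
#' @param spec An [electrostatics_spec()].
#' @return Dielectric value(s), always in `(1, eps0]`.
#' @export
dielectric_at <- function(r, spec = electrostatics_spec()) {
  if (spec$dielectric == "constant") rep(spec$eps0, length(r))
  else spec$eps0 * (1 - spec$diel_c * exp(-r / spec$diel_lambda))
}

.lambda_pair <- function(h_i, h_j, combination) {
  switch(combination,
    arithmetic = (h_i + h_j) / 2,
    geometric = sqrt(h_i * h_j)
  )
}

# Ashbaugh-Hatch 12-6 with force-shift truncation; returns energy (and
# optionally dU/dr) for scalar lambda/sigma, vectorized over r.
.ah_energy <- function(r, lambda, eps, sij, rc, deriv = FALSE) {
  rmin <- 2^(1 / 6) * sij
  rcp <- max(rc, rmin)
  ulj <- function(rr) 4 * eps * ((sij / rr)^12 - (sij / rr)^6)
  dulj <- function(rr) 4 * eps * (-12 * (sij / rr)^12 + 6 * (sij / rr)^6) / rr
  A <- lambda * ulj(rcp)
  B <- lambda * dulj(rcp)
  inside <- r < rcp
  core <- r < rmin
  U <- numeric(length(r))
  dU <- numeric(length(r))
  i1 <- inside & core
  i2 <- inside & !core
  if (any(i1)) {
    U[i1] <- ulj(r[i1]) + (1 - lambda) * eps - A - B * (r[i1] - rcp)
    dU[i1] <- dulj(r[i1]) - B
  }
  if (any(i2)) {
    U[i2] <- lambda * ulj(r[i2]) - A - B * (r[i2] - rcp)
    dU[i2] <- lambda * dulj(r[i2]) - B
  }
  if (deriv) list(energy = U, dUdr = dU) else U
}

#' Hydrophobic pair energy
#'
#' @param h_i,h_j Hydrophobicities of the two beads, in `[0, 1]`.
#' @param r Separation(s) in nm, `> 0`.
#' @param spec A [hydrophobic_spec()].
#' @return Energy in kJ/mol, vectorized over `r`.
#' @export
#' @examples
#' hydrophobic_pair_energy(1, 1, seq(0.6, 1.4, by = 0.2))
hydrophobic_pair_energy <- function(h_i, h_j, r, spec = hydrophobic_spec()) {
  stopifnot(all(r > 0), h_i >= 0, h_i <= 1, h_j >= 0, h_j <= 1)
  lambda <- .lambda_pair(h_i, h_j, spec$combination)
  .ah_energy(r, lambda, spec$eps_max, spec$sigma, spec$cutoff)
}

#' Screened (Yukawa) electrostatic pair energy
#'
#' `ke * q_i * q_j * exp(-r / lambda_D) / (eps(r) * r)` with the Coulomb
#' constant `ke = 138.935` kJ mol-1 nm e-2. Zero whenever either charge is
#' zero; the sign follows the product of the charges.
#'
#' @param q_i,q_j Bead charges in elementary charges.
#' @param r Separation(s) in nm, `> 0`.
#' @param spec An [electrostatics_spec()].
#' @return Energy in kJ/mol, vectorized over `r`.
#' @export
electrostatic_pair_energy <- function(q_i, q_j, r, spec = electrostatics_spec()) {
  stopifnot(all(r > 0))
  if (q_i == 0 || q_j == 0) return(numeric(length(r)) )
  .ke_coulomb * q_i * q_j * exp(-r / spec$screening_length) /
    (dielectric_at(r, spec) * r)
}

.salt_ions <- list(
  # moles of each ion per mole of salt, with valences
  NaCl  = list(z = c(1, -1), n = c(1, 1)),
  KCl   = list(z = c(1, -1), n = c(1, 1)),
  LiCl  = list(z = c(1, -1), n = c(1, 1)),
  CsCl  = list(z = c(1, -1), n = c(1, 1)),
  MgCl2 = list(z = c(2, -1), n = c(1, 2)),
  CaCl2 = list(z = c(2, -1), n = c(1, 2))
)

#' Debye screening length of an electrolyte
#'
#' Computes the Debye length in water from the ionic strength
#' `I = 1/2 * sum(c_i * z_i^2)`. Input is either a table of ion species or a
#' named vector of salt concentrations (counter-ions are added automatically
#' for salts, guaranteeing electroneutrality).
#'
#' @param ions Optional tibble/data frame with columns `concentration`
#'   (mol/l) and `valence`. The composition must be electroneutral.
#' @param salts Optional named numeric vector of salt concentrations in
#'   mol/l; supported salts: NaCl, KCl, LiCl, CsCl, MgCl2, CaCl2.
#' @param temperature Temperature in K.
#' @param epsilon_r Relative permittivity of the solvent (78.4 for water at
#'   25 C).
#' @return Debye length in nm.
#' @export
#' @examples
#' screening_length(salts = c(KCl = 0.15))                  # ~0.8 nm
#' screening_length(salts = c(KCl = 0.25, MgCl2 = 0.05))    # ~0.5 nm
screening_length <- function(ions = NULL, salts = NULL, temperature = 298.15,
                             epsilon_r = 78.4) {
  if (is.null(ions) && is.null(salts)) abort("Supply `ions` or `salts`.")
  conc <- numeric(0)
  z <- numeric(0)
  if (!is.null(salts)) {
    if (is.null(names(salts)) || any(!names(salts) %in% names(.salt_ions))) {
      abort(sprintf("Unknown salt; supported: %s.",
                    paste(names(.salt_ions), collapse = ", ")))
    }
    for (s in names(salts)) {
      def <- .salt_ions[[s]]
      conc <- c(conc, salts[[s]] * def$n)
      z <- c(z, def$z)
    }
  }
  if (!is.null(ions)) {
    stopifnot(all(c("concentration", "valence") %in% names(ions)))
    conc <- c(conc, ions$concentration)
    z <- c(z, ions$valence)
    net <- sum(ions$concentration * ions$valence)
    if (abs(net) > 1e-9 * sum(abs(ions$concentration * ions$valence))) {
      abort("Ion composition is not electroneutral; add counter-ions.")
    }
  }
  I <- 0.5 * sum(conc * z^2) # mol/l
  if (I <= 0) abort("Zero ionic strength: the screening length is infinite.")
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23; NA_ <- 6.02214076e23
  lam_m <- sqrt(eps0 * epsilon_r * kB * temperature / (2 * NA_ * e^2 * I * 1000))
  lam_m * 1e9
}

#' Tabulated bending/torsion potential
#'
#' Holds virtual-bond angle and dihedral energy tables (interpolated by
#' cubic splines) for consecutive bead triplets/quadruplets. The tables are
#' disabled by default: the chain-stiffness term is optional in this model
#' and contributes exactly zero when switched off.
#'
#' @param angle Optional tibble with columns `theta` (radians, ascending over
#'   `[0, pi]`) and `energy` (kJ/mol).
#' @param dihedral Optional tibble with columns `phi` (radians over
#'   `[-pi, pi]`, periodic: first and last energy equal) and `energy`.
#' @return A `bending_tables` object, or `NULL` if both tables are absent.
#' @export
bending_tables <- function(angle = NULL, dihedral = NULL) {
  if (is.null(angle) && is.null(dihedral)) return(NULL)
  fa <- fd <- NULL
  if (!is.null(angle)) {
    stopifnot(all(c("theta", "energy") %in% names(angle)))
    fa <- splinefun(angle$theta, angle$energy, method = "natural")
  }
  if (!is.null(dihedral)) {
    stopifnot(all(c("phi", "energy") %in% names(dihedral)))
    if (abs(dihedral$energy[1] - dihedral$energy[nrow(dihedral)]) > 1e-12) {
      abort("Dihedral table must be periodic (equal first/last energy).")
    }
    fd <- splinefun(dihedral$phi, dihedral$energy, method = "periodic")
  }
  structure(list(angle = fa, dihedral = fd, angle_table = angle,
                 dihedral_table = dihedral),
            class = "bending_tables")
}

.bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang)))
}

# dihedral angle (praxeolitic formulation)
.dihedral <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1; b1 <- p2 - p1; b2 <- p3 - p2
  b1n <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1n) * b1n
  w <- b2 - sum(b2 * b1n) * b1n
  x <- sum(v * w)
  cr <- c(b1n[2] * v[3] - b1n[3] * v[2], b1n[3] * v[1] - b1n[1] * v[3],
          b1n[1] * v[2] - b1n[2] * v[1])
  y <- sum(cr * w)
  atan2(y, x)
}

#' Bending/torsion energy of four consecutive beads
#'
#' Evaluates the tabulated virtual-bond-angle energy for the two triplets
#' `(1,2,3)` and `(2,3,4)` plus the dihedral energy of the quadruplet. The
#' energy depends only on internal coordinates, so it is invariant under
#' rigid rotations and translations. A collinear triplet has a well-defined
#' angle energy and, by convention, zero bending force.
#'
#' @param coords 4 x 3 numeric matrix of bead coordinates (nm), consecutive
#'   along one chain.
#' @param tables A [bending_tables()] object, or `NULL`/disabled for zero.
#' @return Energy in kJ/mol (0 when the feature is disabled).
#' @export
bending_torsion_energy <- function(coords, tables = NULL) {
  if (is.null(tables)) return(0)
  stopifnot(is.matrix(coords), nrow(coords) == 4L, ncol(coords) == 3L)
  e <- 0
  if (!is.null(tables$angle)) {
    e <- e + tables$angle(.bead_angle(coords[1, ], coords[2, ], coords[3, ])) +
      tables$angle(.bead_angle(coords[2, ], coords[3, ], coords[4, ]))
  }
  if (!is.null(tables$dihedral)) {
    e <- e + tables$dihedral(.dihedral(coords[1, ], coords[2, ], coords[3, ],
                                       coords[4, ]))
  }
  e
}

#' Force-field bundle
#'
#' Collects all interaction parameters of the one-bead-per-residue model:
#' bonded terms, hydrophobic pair attraction, screened electrostatics,
#' optional bending/torsion tables, and the wall stiffness used for the
#' reflecting box and the membrane.
#'
#' @param hydrophobic A [hydrophobic_spec()].
#' @param electrostatics An [electrostatics_spec()].
#' @param bond_r0,bond_k Bond rest length (nm) and stiffness (kJ mol-1 nm-2).
#' @param bending Optional [bending_tables()]; `NULL` disables the term.
#' @param k_wall Harmonic wall stiffness (kJ mol-1 nm-2).
#' @param el_cutoff_factor Electrostatic truncation radius in units of the
#'   screening length (the Yukawa energy is shifted to zero at the cutoff).
#' @return A `forcefield` list.
#' @export
forcefield <- function(hydrophobic = hydrophobic_spec(),
                       electrostatics = electrostatics_spec(),
                       bond_r0 = 0.38, bond_k = 8000,
                       bending = NULL, k_wall = 100,
                       el_cutoff_factor = 6) {
  structure(list(hydrophobic = hydrophobic, electrostatics = electrostatics,
                 bond_r0 = bond_r0, bond_k = bond_k, bending = bending,
                 k_wall = k_wall,
                 el_cutoff = el_cutoff_factor * electrostatics$screening_length),
            class = "forcefield")
}
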