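test_that("residue parameter table is complete and normalized", {
  p <- residue_params()
  expect_equal(nrow(p), 20)
  expect_setequal(p$code, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_true(all(p$h >= 0 & p$h <= 1))
  expect_equal(min(p$h), 0)
  expect_equal(max(p$h), 1)
  expect_true(all(p$mass > 0))
  # charge convention: K,R positive, D,E negative, H neutral
  expect_equal(p$charge[p$code %in% c("K", "R")], c(1, 1))
  expect_equal(p$charge[p$code %in% c("D", "E")], c(-1, -1))
  expect_equal(p$charge[p$code == "H"], 0)
  # uniform-mass mode
  pu <- residue_params(mass_mode = "uniform")
  expect_true(all(pu$mass == 120))
})

test_that("hydrophobicity normalization is the affine min-max map", {
  raw <- c(A = -2, B = 0, C = 2)
  h <- normalize_hydrophobicity(raw)
  expect_equal(unname(h), c(0, 0.5, 1))
  expect_equal(order(raw), order(h)) # order preserved
  expect_error(normalize_hydrophobicity(rep(1, 20)), "degenerate")
  expect_error(normalize_hydrophobicity(c(1, NA, 3)), "finite")
})

test_that("sequence_to_chain populates beads, bonds and charges", {
  gg <- sequence_to_chain("GG")
  expect_equal(nrow(gg), 2)
  expect_equal(sum(gg$charge), 0)

  ke <- sequence_to_chain("KE")
  expect_equal(sum(ke$charge), 0)
  expect_equal(ke$charge, c(1, -1))

  fsfg <- sequence_to_chain("FSFG")
  expect_gt(fsfg$h[1], fsfg$h[2]) # F more hydrophobic than S
  expect_gt(fsfg$h[1], fsfg$h[4]) # and than G

  expect_error(sequence_to_chain("GGXG"), "position 3")
})

test_that("bond energy is harmonic around 0.38 nm", {
  expect_equal(bond_energy(0.38), 0)
  d <- 0.013
  expect_equal(bond_energy(0.38 + d), bond_energy(0.38 - d))
  expect_equal(bond_energy(0.40, k_bond = 1), 0.0002)
  expect_error(bond_energy(-0.1))
})

test_that("hydrophobic pair interaction follows the scaled 12-6 contract", {
  spec <- hydrophobic_spec()
  r <- seq(0.6, spec$cutoff - 0.01, by = 0.01)
  # purely repulsive at h = 0
  expect_true(all(hydrophobic_pair_energy(0, 0, r, spec) >= 0))
  expect_true(all(hydrophobic_pair_energy(0, 0,
    seq(2^(1 / 6) * spec$sigma, 2, by = 0.05), spec) == 0))
  # well depth at the endpoint of the combination rule; the force-shift
  # truncation makes the realized depth ~7% shallower than eps_max at the
  # default 2.5-sigma cutoff
  rmin <- 2^(1 / 6) * spec$sigma
  expect_equal(-hydrophobic_pair_energy(1, 1, rmin, spec), spec$eps_max,
               tolerance = 0.08)
  # and the depth approaches eps_max as the cutoff grows
  far <- hydrophobic_spec(cutoff = 6)
  expect_equal(-hydrophobic_pair_energy(1, 1, rmin, far), far$eps_max,
               tolerance = 0.005)
  # zero at and beyond the cutoff; continuous up to it
  expect_equal(hydrophobic_pair_energy(1, 1, c(spec$cutoff, 2, 5), spec),
               c(0, 0, 0))
  eps <- 1e-7
  expect_lt(abs(hydrophobic_pair_energy(1, 1, spec$cutoff - eps, spec)), 1e-5)
  # monotone deepening with combined hydrophobicity over an r grid
  e_half <- hydrophobic_pair_energy(0.5, 0.5, r, spec)
  e_full <- hydrophobic_pair_energy(1, 1, r, spec)
  expect_true(all(e_full <= e_half + 1e-12))
  expect_lt(min(e_full), min(e_half))
})

test_that("hydrophobic well depth is non-decreasing in each h", {
  spec <- hydrophobic_spec()
  rmin <- 2^(1 / 6) * spec$sigma
  hs <- seq(0, 1, by = 0.1)
  for (hj in c(0, 0.4, 1)) {
    depth <- -vapply(hs, function(hi)
      hydrophobic_pair_energy(hi, hj, rmin, spec), numeric(1))
    expect_true(all(diff(depth) >= -1e-12))
  }
})

test_that("screened electrostatics has the Yukawa closed form", {
  spec <- electrostatics_spec(screening_length = 0.8, dielectric = "constant")
  expect_equal(electrostatic_pair_energy(0, 1, c(0.5, 1, 2), spec), rep(0, 3))
  expect_gt(electrostatic_pair_energy(1, 1, 0.5, spec), 0)
  expect_lt(electrostatic_pair_energy(1, -1, 0.5, spec), 0)
  # ratio E(2r)/E(r) = (1/2) exp(-r/kappa^-1) at constant dielectric
  r <- 0.7
  rat <- electrostatic_pair_energy(1, 1, 2 * r, spec) /
    electrostatic_pair_energy(1, 1, r, spec)
  expect_equal(rat, 0.5 * exp(-r / 0.8), tolerance = 1e-12)
})

test_that("distance-dependent dielectric stays within physical bounds", {
  spec <- electrostatics_spec()
  r <- seq(0.05, 10, by = 0.05)
  eps <- dielectric_at(r, spec)
  expect_true(all(eps > 1 & eps <= 80.5))
  expect_true(all(diff(eps) > 0)) # saturates upward toward the bulk value
})

test_that("Debye screening length matches the buffers and the closed form", {
  expect_equal(round(screening_length(salts = c(KCl = 0.15)), 1), 0.8)
  expect_equal(round(screening_length(salts = c(KCl = 0.25, MgCl2 = 0.05)), 1),
               0.5)
  # quadrupling the ionic strength halves the screening length
  expect_equal(screening_length(salts = c(NaCl = 0.1)) /
                 screening_length(salts = c(NaCl = 0.4)), 2,
               tolerance = 1e-12)
  # closed form 0.304 nm / sqrt(I) over 1 mM - 1 M to 3 significant figures
  for (I in c(0.001, 0.01, 0.1, 0.5, 1)) {
    lam <- screening_length(ions = tibble::tibble(concentration = c(I, I),
                                                  valence = c(1, -1)))
    expect_equal(lam, 0.30414 / sqrt(I), tolerance = 2e-3)
  }
  expect_error(screening_length(ions = tibble::tibble(concentration = c(1, 1),
                                                      valence = c(1, 1))),
               "electroneutral")
  expect_error(
    screening_length(ions = tibble::tibble(concentration = 0, valence = 1)),
    "ionic strength")
})

test_that("bending/torsion tables evaluate and toggle off", {
  sq <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.38, 0.38, 0), c(0, 0.38, 0))
  # disabled -> exactly zero
  expect_identical(bending_torsion_energy(sq, NULL), 0)
  ang <- tibble::tibble(theta = seq(0, pi, length.out = 19),
                        energy = 5 * (seq(0, pi, length.out = 19) - 2)^2)
  tab <- bending_tables(angle = ang)
  # configured minimum read back: both angles at the table knot closest to
  # the quadratic's minimum (spline equals the table exactly at knots)
  th0 <- pi * 11 / 18
  p1 <- c(0, 0, 0); p2 <- c(0.38, 0, 0)
  p3 <- p2 + 0.38 * c(cos(pi - th0), sin(pi - th0), 0)
  v23 <- p3 - p2
  # place bead 4 so that angle(2,3,4) is also th0, within the same plane
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2], 0)
  p4 <- p3 + 0.38 * rot(-v23 / sqrt(sum(v23^2)), th0)
  coords <- rbind(p1, p2, p3, p4)
  e_min <- bending_torsion_energy(coords, tab)
  expect_equal(e_min, 2 * min(ang$energy), tolerance = 1e-6)
  # rigid rotation invariance
  a <- 0.7
  R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  expect_equal(bending_torsion_energy(coords %*% t(R), tab), e_min,
               tolerance = 1e-10)
  # collinear triplet: finite energy, no crash
  col <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0), c(1.14, 0.1, 0))
  expect_true(is.finite(bending_torsion_energy(col, tab)))
})
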