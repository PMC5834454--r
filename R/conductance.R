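#' Nanopore conductance model parameters
#'
#' Geometry and material constants of the density-based conductance model:
#' pore diameter `d` and length `l`, the bulk ionic conductivity
#' `sigma_bare` of the electrolyte, and the critical protein density
#' `rho_crit` at and above which the local ion conductivity is taken to be
#' zero.
#'
#' @param diameter Pore diameter d, nm.
#' @param length Pore length l (membrane thickness), nm.
#' @param sigma_bare Bulk conductivity, nS/nm (4.30 for 250 mM KCl + 50 mM
#'   MgCl2).
#' @param rho_crit Critical protein density, mg/ml.
#' @return A `pore_model` list.
#' @export
pore_model <- function(diameter = 20, length = 20, sigma_bare = 4.30,
                       rho_crit = 85) {
  stopifnot(diameter > 0, length >= 0, sigma_bare >= 0, rho_crit > 0)
  structure(list(diameter = diameter, length = length,
                 sigma_bare = sigma_bare, rho_crit = rho_crit),
            class = "pore_model")
}

#' Conductance of a bare cylindrical nanopore
#'
#' `G = sigma_bare * (4 l / (pi d^2) + 1 / d)^-1`: the two denominator terms
#' are the pore (channel) resistance and the access resistance of the
#' converging field lines on both sides.
#'
#' @param model A [pore_model()].
#' @return Conductance in nS.
#' @export
#' @examples
#' bare_pore_conductance(pore_model())  # ~37.8 nS for d = l = 20 nm
bare_pore_conductance <- function(model = pore_model()) {
  d <- model$diameter; l <- model$length
  model$sigma_bare / (4 * l / (pi * d^2) + 1 / d)
}

#' Local ion conductivity at a given protein density
#'
#' The conductivity decreases linearly with the local protein density,
#' `sigma = sigma_bare * (1 - rho / rho_crit)`, clamped to zero at and
#' beyond the critical density.
#'
#' @param rho Protein density (mg/ml), vectorized.
#' @param model A [pore_model()].
#' @return Conductivity in nS/nm.
#' @export
local_conductivity <- function(rho, model = pore_model()) {
  stopifnot(all(rho >= 0))
  pmax(0, model$sigma_bare * (1 - rho / model$rho_crit))
}

#' Cross-section-averaged conductivity from a radial density profile
#'
#' Radially integrates the local conductivity over the pore cross section:
#' `sigma_region = (4 / (pi d^2)) * integral_0^{d/2} 2 pi r sigma(r) dr`.
#' The profile is treated as piecewise constant on its native bins (the
#' integral over each bin is then exact) and as zero beyond the last bin.
#'
#' @param profile Tibble with columns `r` (ascending, equally spaced bin
#'   centers, nm) and `rho` (mg/ml, non-negative).
#' @param model A [pore_model()].
#' @return Conductivity in nS/nm.
#' @export
region_conductivity <- function(profile, model = pore_model()) {
  stopifnot(all(c("r", "rho") %in% names(profile)))
  if (any(profile$rho < 0)) abort("Negative density in the radial profile.")
  d <- model$diameter
  half <- d / 2
  r <- profile$r
  w <- if (length(r) > 1) r[2] - r[1] else 2 * r[1]
  lo <- r - w / 2
  hi <- pmin(r + w / 2, half)
  keep <- lo < half
  lo <- lo[keep]; hi <- hi[keep]
  sig <- local_conductivity(profile$rho[keep], model)
  # exact integral of the step profile: sum sigma_i * (hi^2 - lo^2) / 2
  int_covered <- sum(sig * (hi^2 - lo^2) / 2)
  top <- if (length(hi) > 0) max(hi) else 0
  int_bare <- model$sigma_bare * (half^2 - top^2) / 2 # zero density beyond bins
  (4 / d^2) * 2 * (int_covered + int_bare)
}

.conductance_result <- function(G, model, sigma_pore, sigma_access_top,
                                sigma_access_bottom, windows, equation) {
  structure(list(G = G, model = model, sigma_pore = sigma_pore,
                 sigma_access_top = sigma_access_top,
                 sigma_access_bottom = sigma_access_bottom,
                 windows = windows, equation = equation),
            class = "conductance_result")
}

#' @export
print.conductance_result <- function(x, ...) {
  cat(sprintf("<conductance_result> G = %.3f nS (%s; sigma_pore = %.3f nS/nm)\n",
              x$G, x$equation, x$sigma_pore))
  invisible(x)
}

#' Conductance of a protein-coated nanopore
#'
#' Protein reduces the conductivity in the pore and in the access region by
#' volume exclusion:
#' `G = (4 l / (pi d^2 sigma_pore) + 1 / (d sigma_access))^-1`,
#' with `sigma_pore` computed from the radial density profile averaged over
#' the pore window (|z| <= 10 nm by convention) and `sigma_access` from the
#' access-region window (10 < |z| < 40 nm).
#'
#' @param profile_pore Radial density profile (tibble `r`, `rho`) of the
#'   pore region.
#' @param profile_access Radial density profile of the access region.
#' @param model A [pore_model()].
#' @return A `conductance_result`.
#' @export
coated_pore_conductance <- function(profile_pore, profile_access,
                                    model = pore_model()) {
  sp <- region_conductivity(profile_pore, model)
  sa <- region_conductivity(profile_access, model)
  d <- model$diameter; l <- model$length
  G <- 1 / (4 * l / (pi * d^2 * sp) + 1 / (d * sa))
  .conductance_result(G, model, sp, sa, sa,
                      windows = list(pore = attr(profile_pore, "zwindow"),
                                     access = attr(profile_access, "zwindow")),
                      equation = "coated pore")
}

#' Conductance of a Nup-carrying ring docked on a nanopore
#'
#' For a DNA ring resting on top of the membrane the two access resistances
#' differ: the top side carries protein density while the bottom side is
#' protein-free, giving
#' `G = (4 l / (pi d^2 sigma_pore) + 1 / (2 d sigma_access) +
#' 1 / (2 d sigma_bare))^-1`.
#' By the convention of the ring-on-pore frame (ring center at z = 0) the
#' pore-region density window is -27 < z < 7 nm and the top access window
#' -7 < z < 33 nm; the bottom access region (z < -27 nm) has zero protein
#' density by construction.
#'
#' @param profile_pore Radial density profile of the pore-region window.
#' @param profile_access_top Radial density profile of the top access
#'   window.
#' @param model A [pore_model()].
#' @param check_windows When both profiles carry `zwindow` attributes,
#'   require the access window to start inside/above the pore window top
#'   region rather than below it.
#' @return A `conductance_result`.
#' @export
ring_on_pore_conductance <- function(profile_pore, profile_access_top,
                                     model = pore_model(),
                                     check_windows = TRUE) {
  wp <- attr(profile_pore, "zwindow")
  wa <- attr(profile_access_top, "zwindow")
  if (check_windows && !is.null(wp) && !is.null(wa)) {
    if (wa[2] <= wp[1] || wa[1] < wp[1]) {
      abort(sprintf(
        "Access window [%g, %g] lies below the pore window [%g, %g].",
        wa[1], wa[2], wp[1], wp[2]))
    }
  }
  sp <- region_conductivity(profile_pore, model)
  sa <- region_conductivity(profile_access_top, model)
  d <- model$diameter; l <- model$length
  G <- 1 / (4 * l / (pi * d^2 * sp) + 1 / (2 * d * sa) +
              1 / (2 * d * model$sigma_bare))
  .conductance_result(G, model, sp, sa, model$sigma_bare,
                      windows = list(pore = wp, access_top = wa),
                      equation = "ring on pore")
}

#' Relative conductance and percent blockade
#'
#' @param g_ring Conductance with the ring docked, nS (or a
#'   `conductance_result`).
#' @param g_pore Bare-pore conductance, nS (or a `conductance_result`).
#' @return Tibble with `fraction` (`G_ring / G_pore`) and `reduction_pct`
#'   (percent conductance blockade).
#' @export
#' @examples
#' relative_conductance(32.9, 37.8)
relative_conductance <- function(g_ring, g_pore) {
  if (inherits(g_ring, "conductance_result")) g_ring <- g_ring$G
  if (inherits(g_pore, "conductance_result")) g_pore <- g_pore$G
  stopifnot(g_pore > 0, g_ring >= 0)
  frac <- g_ring / g_pore
  tibble(fraction = frac, reduction_pct = 100 * (1 - frac))
}

#' @describeIn coated_pore_conductance Tidy a conductance result.
#' @param x A `conductance_result`.
#' @param ... Unused.
#' @export
tidy.conductance_result <- function(x, ...) {
  tibble(term = c("G", "sigma_pore", "sigma_access_top", "sigma_access_bottom"),
         estimate = c(x$G, x$sigma_pore, x$sigma_access_top,
                      x$sigma_access_bottom),
         unit = c("nS", rep("nS/nm", 3)))
}

#' @describeIn coated_pore_conductance One-row summary with the relative
#'   conductance against the bare pore.
#' @export
glance.conductance_result <- function(x, ...) {
  g0 <- bare_pore_conductance(x$model)
  rel <- relative_conductance(x$G, g0)
  tibble(G = x$G, G_bare = g0, fraction = rel$fraction,
         reduction_pct = rel$reduction_pct, equation = x$equation)
}
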