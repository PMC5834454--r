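#' Build a DNA-origami ring scaffold from inert beads
#'
#' The ring is modelled as a cylindrical shell of inert beads: rows of beads
#' are stacked along z at one bead-diameter spacing, each row holding enough
#' beads that neighbouring bead centers are at most one bead diameter apart
#' (alternate rows are staggered by half a spacing). Protein attachment
#' anchors sit on the inner surface at mid-height, equally spaced in angle
#' and pointing radially inward.
#'
#' @param height Ring height in nm.
#' @param outer_diameter Outer ring diameter in nm.
#' @param bead_diameter Scaffold bead diameter in nm.
#' @param n_anchors Number of anchor sites (8 or 32 in the origami designs;
#'   other counts are allowed with a warning).
#' @param anchor_offset Radial stand-off of the anchor points from the inner
#'   surface, nm (mimics the short double-helical separator that orients the
#'   anchors inward).
#' @param shell `"full"` for the complete bead tiling or `"coarse"` for a
#'   single mid-height bead row (faster for desk-scale tests).
#' @return A `ring_scaffold` list with `beads` (tibble `x`, `y`, `z`),
#'   `anchors` (tibble `anchor`, `x`, `y`, `z`, `theta`), and the geometry
#'   fields. The ring center is the origin; z runs along the ring axis.
#' @export
#' @examples
#' ring <- build_ring()
#' nrow(ring$beads)
build_ring <- function(height = 13.85, outer_diameter = 36, bead_diameter = 2.6,
                       n_anchors = 32, anchor_offset = 0.5,
                       shell = c("full", "coarse")) {
  shell <- match.arg(shell)
  stopifnot(height > 0, outer_diameter > 0, bead_diameter > 0, n_anchors >= 1)
  if (bead_diameter > height) {
    abort("Scaffold bead diameter exceeds the ring height.")
  }
  if (!n_anchors %in% c(8L, 32L)) {
    warn(sprintf("n_anchors = %d is outside the origami designs (8 or 32).",
                 n_anchors))
  }
  r_shell <- (outer_diameter - bead_diameter) / 2
  inner_diameter <- outer_diameter - 2 * bead_diameter

  n_rows <- if (shell == "coarse") 1L else max(1L, round(height / bead_diameter))
  zs <- if (n_rows == 1L) 0 else
    seq(-height / 2 + bead_diameter / 2, height / 2 - bead_diameter / 2,
        length.out = n_rows)
  n_per_row <- max(3L, ceiling(2 * pi * r_shell / bead_diameter))
  beads <- purrr::map_dfr(seq_len(n_rows), function(i) {
    th <- 2 * pi * (seq_len(n_per_row) - 1) / n_per_row +
      (i %% 2) * pi / n_per_row # stagger alternate rows
    tibble(x = r_shell * cos(th), y = r_shell * sin(th), z = zs[i])
  })

  r_anchor <- inner_diameter / 2 - anchor_offset
  th_a <- 2 * pi * (seq_len(n_anchors) - 1) / n_anchors
  anchors <- tibble(anchor = seq_len(n_anchors),
                    x = r_anchor * cos(th_a), y = r_anchor * sin(th_a),
                    z = 0, theta = th_a)

  structure(list(beads = beads, anchors = anchors, height = height,
                 outer_diameter = outer_diameter,
                 inner_diameter = inner_diameter,
                 bead_diameter = bead_diameter, n_anchors = n_anchors,
                 anchor_radius = r_anchor, shell = shell),
            class = "ring_scaffold")
}

#' @export
print.ring_scaffold <- function(x, ...) {
  cat(sprintf(
    "<ring_scaffold> height %.2f nm, outer diameter %.1f nm, %d beads, %d anchors at r = %.2f nm\n",
    x$height, x$outer_diameter, nrow(x$beads), x$n_anchors, x$anchor_radius))
  invisible(x)
}

#' Build a solid-state membrane with a cylindrical nanopore
#'
#' The SiN membrane is represented by analytic repulsive walls: a slab of
#' thickness `thickness` perforated by a coaxial cylindrical pore of diameter
#' `diameter`. In the ring-on-pore frame (ring center at z = 0) the ring
#' rests on top of the membrane, so the slab occupies
#' `[-ring_half_height - thickness, -ring_half_height]`; with the default
#' ring half-height of ~7 nm and a 20 nm membrane this is approximately
#' `[-27, -7]` nm.
#'
#' @param diameter Pore diameter d in nm.
#' @param thickness Membrane thickness (pore length l) in nm.
#' @param ring_half_height Half-height of the ring the membrane is paired
#'   with, nm; sets the z placement of the slab.
#' @return A `membrane_pore` list with fields `diameter`, `thickness`,
#'   `z_interval`.
#' @export
build_membrane_pore <- function(diameter = 20, thickness = 20,
                                ring_half_height = 7) {
  stopifnot(diameter > 0, thickness > 0)
  z_interval <- c(-ring_half_height - thickness, -ring_half_height)
  structure(list(diameter = diameter, thickness = thickness,
                 z_interval = z_interval),
            class = "membrane_pore")
}

#' Is a point inside the membrane wall material?
#' @param x,y,z Coordinates in nm (vectorized).
#' @param pore A [build_membrane_pore()] object.
#' @return Logical vector: `TRUE` where the point lies inside the solid slab
#'   (i.e. outside the pore lumen at slab height).
#' @export
in_membrane_wall <- function(x, y, z, pore) {
  r <- sqrt(x^2 + y^2)
  z > pore$z_interval[1] & z < pore$z_interval[2] & r > pore$diameter / 2
}

#' Convert Cartesian coordinates to cylindrical
#'
#' @param coords Data frame/tibble with columns `x`, `y`, `z`, or an n x 3
#'   matrix. The frame origin must be the ring center, z along the axis.
#' @return Tibble with columns `r` (`>= 0`), `theta` (in `[0, 2*pi)`; 0 on
#'   the axis by convention) and `z`.
#' @export
#' @examples
#' to_cylindrical(data.frame(x = 3, y = 4, z = 0))
to_cylindrical <- function(coords) {
  if (is.matrix(coords)) coords <- tibble(x = coords[, 1], y = coords[, 2],
                                          z = coords[, 3])
  r <- sqrt(coords$x^2 + coords$y^2)
  theta <- atan2(coords$y, coords$x)
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  theta[r == 0] <- 0
  tibble(r = r, theta = theta, z = coords$z)
}

#' Convert cylindrical coordinates back to Cartesian
#' @param cyl Tibble with columns `r`, `theta`, `z`.
#' @return Tibble with columns `x`, `y`, `z`.
#' @export
from_cylindrical <- function(cyl) {
  tibble(x = cyl$r * cos(cyl$theta), y = cyl$r * sin(cyl$theta), z = cyl$z)
}
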