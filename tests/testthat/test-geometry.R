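test_that("ring scaffold geometry follows the origami design", {
  ring <- build_ring() # 13.85 x 36 nm, 32 anchors
  # anchors equally spaced: 360/32 = 11.25 degrees
  dtheta <- diff(ring$anchors$theta)
  expect_equal(unique(round(dtheta, 10)), 2 * pi / 32)
  expect_equal(dtheta[1] * 180 / pi, 11.25)
  # all scaffold beads on the cylindrical shell
  r_bead <- sqrt(ring$beads$x^2 + ring$beads$y^2)
  expect_equal(max(abs(r_bead - r_bead[1])), 0)
  expect_true(all(abs(ring$beads$z) <= ring$height / 2))
  # deterministic tiling count for the default geometry (pinned regression:
  # round(2*pi*16.7/2.6) beads per row x round(13.85/2.6) rows)
  expect_equal(nrow(ring$beads), 41 * 5)

  ring8 <- build_ring(n_anchors = 8)
  expect_equal(nrow(ring8$anchors), 8)
  r_anchor <- sqrt(ring8$anchors$x^2 + ring8$anchors$y^2)
  expect_true(all(r_anchor <= 17)) # inside the inner radius
  # anchors point radially inward: anchor radius below the shell radius
  expect_true(all(r_anchor < min(r_bead)))

  expect_error(build_ring(height = 2, bead_diameter = 2.6), "height")
  expect_warning(build_ring(n_anchors = 12), "origami")
})

test_that("anchor set is invariant under the ring rotation symmetry", {
  ring <- build_ring(n_anchors = 8)
  th <- sort(ring$anchors$theta)
  rot <- sort((th + 2 * pi / 8) %% (2 * pi))
  expect_equal(rot, th, tolerance = 1e-12)
})

test_that("membrane pore geometry and wall classification", {
  pore <- build_membrane_pore(diameter = 20, thickness = 20)
  # ring resting on top: slab at [-27, -7] for a ~14 nm ring
  expect_equal(pore$z_interval, c(-27, -7))
  expect_equal(diff(pore$z_interval), pore$thickness)
  # pore lumen point vs wall point at slab height
  expect_false(in_membrane_wall(0, 0, -10, pore))
  expect_true(in_membrane_wall(15, 0, -10, pore))
  # outside the slab entirely
  expect_false(in_membrane_wall(15, 0, 5, pore))
})

test_that("system assembly grafts chains deterministically at strided anchors", {
  ring <- build_ring(n_anchors = 32)
  # empty ring is a valid system
  empty <- assemble_system(ring, list(), seed = 3)
  expect_s3_class(empty, "cg_system")
  expect_equal(sum(empty$beads$type == "protein"), 0)

  chains <- lapply(1:8, function(i)
    sequence_to_chain("GSGSGSGSGS", chain_id = i))
  sys <- assemble_system(ring, chains, seed = 11)
  idx <- attr(sys, "anchor_indices")
  expect_equal(idx, seq(1, 29, by = 4)) # every 4th anchor
  # bead 1 of each chain sits exactly at its anchor
  for (k in seq_along(idx)) {
    b0 <- sys$beads[sys$beads$type == "protein" & sys$beads$chain == k, ][1, ]
    a <- ring$anchors[idx[k], ]
    expect_equal(c(b0$x, b0$y, b0$z), c(a$x, a$y, a$z))
    expect_false(b0$mobile)
  }
  # all beads inside the box
  expect_true(all(abs(sys$beads$x) < sys$box[1] / 2))
  # same seed -> bit-identical coordinates
  sys2 <- assemble_system(ring, chains, seed = 11)
  expect_identical(sys$beads, sys2$beads)
  sys3 <- assemble_system(ring, chains, seed = 12)
  expect_false(identical(sys$beads, sys3$beads))

  expect_error(assemble_system(build_ring(n_anchors = 8), c(chains, chains)),
               "More chains")
})

test_that("scaffold beads are inert (no attraction, no charge)", {
  sys <- assemble_system(desk_ring(), list(sequence_to_chain("GSG")), seed = 1)
  sc <- sys$beads[sys$beads$type == "scaffold", ]
  expect_true(all(sc$h == 0))
  expect_true(all(sc$charge == 0))
  expect_true(all(!sc$mobile))
})

test_that("cylindrical coordinates round-trip and follow conventions", {
  expect_equal(to_cylindrical(data.frame(x = 0, y = 0, z = 5)),
               tibble::tibble(r = 0, theta = 0, z = 5))
  expect_equal(to_cylindrical(data.frame(x = 3, y = 4, z = 0))$r, 5)
  withr::with_seed(8, {
    pts <- tibble::tibble(x = rnorm(200), y = rnorm(200), z = rnorm(200))
    cyl <- to_cylindrical(pts)
    expect_true(all(cyl$r >= 0))
    expect_true(all(cyl$theta >= 0 & cyl$theta < 2 * pi))
    back <- from_cylindrical(cyl)
    expect_equal(as.matrix(back), as.matrix(pts), tolerance = 1e-12)
  })
})
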