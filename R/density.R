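#' Time-averaged 3D protein mass-density grid
#'
#' Bins protein-bead centers of every recorded frame into cubic cells
#' (half-open intervals `[x, x + cell)`), averages the per-cell counts over
#' frames, and multiplies by the bead masses to obtain a mass density in
#' mg/ml. Scaffold beads are excluded: the grid maps the protein mass only.
#'
#' @param traj A `cg_trajectory` from [run_dynamics()].
#' @param cell Cell edge in nm.
#' @param box Box edge lengths; defaults to the simulated system's box.
#' @return A `density_grid`: list with `rho` (3D array, mg/ml), `cell`,
#'   `origin` (corner of cell `[1,1,1]`), `dims`, `n_frames`, `mass_mode`.
#' @export
accumulate_density <- function(traj, cell = 0.5, box = traj$system$box) {
  nf <- n_frames(traj)
  if (is.null(nf) || nf == 0) abort("No frames in the trajectory window.")
  sel <- traj$system$beads$type == "protein"
  if (!any(sel)) abort("No protein beads in the system.")
  mass <- traj$system$beads$mass[sel]
  dims <- as.integer(round(box / cell))
  origin <- -box / 2
  rho <- array(0, dim = dims)
  nxy <- dims[1] * dims[2]
  for (f in seq_len(nf)) {
    fr <- traj$frames[, , f, drop = FALSE]
    dim(fr) <- dim(fr)[1:2]
    xyz <- fr[sel, , drop = FALSE]
    ix <- floor((xyz[, 1] - origin[1]) / cell)
    iy <- floor((xyz[, 2] - origin[2]) / cell)
    iz <- floor((xyz[, 3] - origin[3]) / cell)
    bad <- which(ix < 0 | ix >= dims[1] | iy < 0 | iy >= dims[2] |
                   iz < 0 | iz >= dims[3])
    if (length(bad) > 0) {
      abort(sprintf("Frame %d has coordinates outside the box (bead %d).",
                    f, which(sel)[bad[1]]))
    }
    lin <- 1 + ix + dims[1] * iy + nxy * iz
    acc <- rowsum(mass, lin)
    rho[as.integer(rownames(acc))] <- rho[as.integer(rownames(acc))] + acc[, 1]
  }
  rho <- rho / (nf * cell^3) * DA_PER_NM3_TO_MG_PER_ML
  structure(list(rho = rho, cell = cell, origin = origin, dims = dims,
                 n_frames = nf,
                 mass_mode = attr(traj$system$beads, "mass_mode") %||% "natural"),
            class = "density_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a density grid from an array (internal/synthetic use)
#' @param rho 3D array of densities in mg/ml.
#' @param cell Cell edge in nm.
#' @param origin Corner coordinate of the first cell, nm.
#' @param n_frames Frames-averaged count recorded in the metadata.
#' @return A `density_grid`.
#' @export
density_grid <- function(rho, cell, origin = -dim(rho) * cell / 2,
                         n_frames = 1L) {
  stopifnot(length(dim(rho)) == 3, all(rho >= 0))
  structure(list(rho = rho, cell = cell, origin = origin, dims = dim(rho),
                 n_frames = n_frames, mass_mode = "synthetic"),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s cells of (%g nm)^3, %d frame(s), max %.1f mg/ml\n",
              paste(x$dims, collapse = " x "), x$cell, x$n_frames, max(x$rho)))
  invisible(x)
}

#' Total protein mass held in a 3D density grid
#' @param grid A `density_grid`.
#' @return Mass in Da.
#' @export
grid_mass <- function(grid) {
  sum(grid$rho) * grid$cell^3 / DA_PER_NM3_TO_MG_PER_ML
}

# cell-center coordinates along one axis
.cell_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$cell
}

# radial bin index (1-based, width = cell edge) of each (x,y) column
.radial_index <- function(grid) {
  cx <- .cell_centers(grid, 1)
  cy <- .cell_centers(grid, 2)
  r <- sqrt(outer(cx^2, cy^2, "+"))
  pmax(1L, as.integer(ceiling(r / grid$cell)))
}

#' Circumferential average: rho(r, z)
#'
#' Averages the 3D grid over the azimuthal direction: cells are grouped into
#' radial bins of width equal to the cell edge by the radius of their
#' centers, and each (r, z) value is the plain mean over contributing cells.
#' The per-bin cell counts are retained so that mass integrals over the
#' reduced map reproduce the parent grid exactly.
#'
#' @param grid A `density_grid` centered on the symmetry axis.
#' @return A `cyl_rz` object: `rho` (nr x nz matrix, mg/ml), `counts`
#'   (cells per radial bin), `r` and `z` bin centers, `cell`.
#' @export
circumferential_average <- function(grid) {
  ri <- .radial_index(grid)
  nr <- max(ri)
  nz <- grid$dims[3]
  mat <- matrix(grid$rho, nrow = grid$dims[1] * grid$dims[2], ncol = nz)
  sums <- rowsum(mat, as.vector(ri))
  counts <- tabulate(as.vector(ri), nbins = nr)
  rho_rz <- sums / counts
  structure(list(rho = rho_rz, counts = counts,
                 r = (seq_len(nr) - 0.5) * grid$cell,
                 z = .cell_centers(grid, 3), cell = grid$cell),
            class = "cyl_rz")
}

#' @export
print.cyl_rz <- function(x, ...) {
  cat(sprintf("<cyl_rz> %d radial x %d axial bins of %g nm, max %.1f mg/ml\n",
              length(x$r), length(x$z), x$cell, max(x$rho)))
  invisible(x)
}

#' Axial average: rho(r, theta)
#'
#' Averages the 3D grid along z over the window `|z| <= zmax` and reduces
#' the in-plane map to polar bins.
#'
#' @param grid A `density_grid`.
#' @param zmax Half-width of the axial averaging window, nm.
#' @param n_theta Number of azimuthal bins.
#' @return A `cyl_rtheta` object: `rho` (nr x n_theta), `r`, `theta` bin
#'   centers, plus the in-plane map `xy` (matrix) used to build it.
#' @export
z_average <- function(grid, zmax = 25, n_theta = 72L) {
  cz <- .cell_centers(grid, 3)
  keep <- abs(cz) <= zmax
  if (!any(keep)) {
    xy <- matrix(0, grid$dims[1], grid$dims[2])
  } else {
    nxy <- grid$dims[1] * grid$dims[2]
    mat <- matrix(grid$rho, nrow = nxy, ncol = grid$dims[3])
    xy <- matrix(rowMeans(mat[, keep, drop = FALSE]),
                 grid$dims[1], grid$dims[2])
  }
  cx <- .cell_centers(grid, 1)
  cy <- .cell_centers(grid, 2)
  r <- sqrt(outer(cx^2, cy^2, "+"))
  th <- atan2(matrix(cy, grid$dims[1], grid$dims[2], byrow = TRUE),
              matrix(cx, grid$dims[1], grid$dims[2]))
  th[th < 0] <- th[th < 0] + 2 * pi
  ri <- pmax(1L, as.integer(ceiling(r / grid$cell)))
  ti <- pmin(n_theta, 1L + as.integer(floor(th / (2 * pi) * n_theta)))
  nr <- max(ri)
  key <- (ti - 1L) * nr + ri
  sums <- rowsum(as.vector(xy), as.vector(key))
  counts <- tabulate(as.vector(key), nbins = nr * n_theta)
  rho_rt <- matrix(NA_real_, nr, n_theta)
  idx <- as.integer(rownames(sums))
  rho_rt[idx] <- sums[, 1] / counts[idx]
  structure(list(rho = rho_rt, xy = xy,
                 r = (seq_len(nr) - 0.5) * grid$cell,
                 theta = (seq_len(n_theta) - 0.5) * 2 * pi / n_theta,
                 zmax = zmax, cell = grid$cell),
            class = "cyl_rtheta")
}

#' Radial density profile rho(r)
#'
#' Averages a `cyl_rz` map along z over `|z| <= zmax` (or an explicit
#' `zwindow = c(zlo, zhi)`), yielding the 1D radial profile used by the
#' conductance model.
#'
#' @param rz A `cyl_rz` from [circumferential_average()].
#' @param zmax Half-width of the symmetric window, nm (ignored when
#'   `zwindow` is given).
#' @param zwindow Optional explicit `c(zlo, zhi)` window in nm.
#' @return Tibble with columns `r` (bin centers, nm) and `rho` (mg/ml);
#'   attributes `zwindow`, `cell`, `counts`.
#' @export
radial_profile <- function(rz, zmax = 25, zwindow = NULL) {
  if (is.null(zwindow)) zwindow <- c(-zmax, zmax)
  keep <- rz$z >= zwindow[1] & rz$z <= zwindow[2]
  rho <- if (any(keep)) rowMeans(rz$rho[, keep, drop = FALSE]) else
    rep(0, length(rz$r))
  out <- tibble(r = rz$r, rho = rho)
  attr(out, "zwindow") <- zwindow
  attr(out, "cell") <- rz$cell
  attr(out, "counts") <- rz$counts
  out
}

#' Integrated protein mass inside the ring
#'
#' Integrates a `cyl_rz` map over radii `r <= r_max` and `|z| <= z_max`.
#' Because each (r, z) bin remembers how many 3D cells contribute to it,
#' the integral is the exact sum over those cells.
#'
#' @param rz A `cyl_rz`.
#' @param r_max Radial cut in nm (the ring interior).
#' @param z_max Axial half-window in nm.
#' @return Mass in Da.
#' @export
integrated_mass <- function(rz, r_max = 18, z_max = 25) {
  rk <- rz$r <= r_max
  zk <- abs(rz$z) <= z_max
  if (!any(rk) || !any(zk)) return(0)
  sub <- rz$rho[rk, zk, drop = FALSE] * rz$counts[rk]
  sum(sub) * rz$cell^3 / DA_PER_NM3_TO_MG_PER_ML
}

#' Circularly averaged intensity profile of a 2D image
#'
#' Averages pixel intensities in 1-pixel annuli around `center` and
#' subtracts the background, estimated as the mean over the outermost 10%
#' of sampled radii, so the background level is normalized to 0. This is the
#' machinery for comparing ring-interior protein intensities between
#' micrograph class averages.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param center `c(row, col)` center in pixel units; must lie inside the
#'   image.
#' @return Tibble with columns `r` (pixels) and `intensity`
#'   (background-subtracted).
#' @export
radial_intensity_profile <- function(image,
                                     center = (dim(image) + 1) / 2) {
  stopifnot(is.matrix(image))
  if (center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image)) {
    abort("Profile center lies outside the image.")
  }
  rr <- sqrt(outer((seq_len(nrow(image)) - center[1])^2,
                   (seq_len(ncol(image)) - center[2])^2, "+"))
  ri <- pmax(1L, as.integer(ceiling(rr)))
  sums <- rowsum(as.vector(image), as.vector(ri))
  counts <- tabulate(as.vector(ri), nbins = max(ri))
  idx <- as.integer(rownames(sums))
  prof <- rep(NA_real_, max(ri))
  prof[idx] <- sums[, 1] / counts[idx]
  keep <- which(!is.na(prof))
  prof <- prof[keep]
  nr <- length(prof)
  bg <- mean(prof[keep >= stats::quantile(keep, 0.9)])
  tibble(r = keep - 0.5, intensity = prof - bg)
}
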