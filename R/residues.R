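.residue_cache <- new.env(parent = emptyenv())

.residue_table <- function() {
  if (!is.null(.residue_cache$tab)) return(.residue_cache$tab)
  path <- system.file("extdata", "residue_params.tsv", package = "npcmimic")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .residue_cache$tab <- tibble::as_tibble(tab)
  .residue_cache$tab
}

#' Renormalize raw partition energies to a 0-1 hydrophobicity scale
#'
#' Applies the affine map that sends the least hydrophobic residue to 0 and
#' the most hydrophobic one to 1, preserving the order of the raw
#' experimental partition energies.
#'
#' @param raw Named (or plain) numeric vector of raw partition energies, one
#'   per residue. All values must be finite and not all equal.
#' @return Numeric vector of the same length and names, with values in
#'   `[0, 1]`.
#' @export
#' @examples
#' normalize_hydrophobicity(c(G = 0, F = 1.79, W = 2.25, R = -1.01))
normalize_hydrophobicity <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 2L) {
    abort("`raw` must be a numeric vector with at least two values.")
  }
  if (any(!is.finite(raw))) abort("All raw partition energies must be finite.")
  rng <- range(raw)
  if (diff(rng) == 0) {
    abort("All raw partition energies are equal; the hydrophobicity scale is degenerate.")
  }
  (raw - rng[1]) / diff(rng)
}

#' Residue parameter table for the one-bead-per-amino-acid model
#'
#' Per-residue bead parameters: hydrophobicity `h` (raw octanol/water
#' partition energies renormalized to `[0, 1]`), net charge at neutral pH
#' (K, R = +1; D, E = -1; H = 0), bead mass and bead diameter. Masses default
#' to the natural per-residue monomer masses; `mass_mode = "uniform"` uses a
#' single 120 Da bead mass (the sequence-average value for typical FG
#' domains) for all residues.
#'
#' @param mass_mode `"natural"` (default) for per-residue masses or
#'   `"uniform"` for 120 Da beads.
#' @param uniform_mass Bead mass used when `mass_mode = "uniform"`, in Da.
#' @return A tibble with columns `code`, `raw_energy`, `h`, `charge`,
#'   `mass`, `diameter` and one row per standard residue.
#' @export
#' @examples
#' params <- residue_params()
#' params[params$code %in% c("F", "S", "G"), ]
residue_params <- function(mass_mode = c("natural", "uniform"), uniform_mass = 120) {
  mass_mode <- match.arg(mass_mode)
  tab <- .residue_table()
  tab$h <- normalize_hydrophobicity(tab$raw_energy)
  if (mass_mode == "uniform") tab$mass <- rep(uniform_mass, nrow(tab))
  attr(tab, "mass_mode") <- mass_mode
  tab[, c("code", "raw_energy", "h", "charge", "mass", "diameter")]
}

#' Convert a residue sequence into a bead chain
#'
#' Maps each residue of `sequence` to one bead, populating hydrophobicity,
#' charge, mass and diameter from the parameter table, with consecutive
#' beads bonded by a stiff harmonic spring of rest length `r0`.
#'
#' @param sequence Character scalar of 1-letter residue codes.
#' @param params Residue parameter table from [residue_params()].
#' @param r0 Bond rest length in nm.
#' @param k_bond Bond stiffness in kJ mol-1 nm-2. The default keeps
#'   root-mean-square bond-length fluctuations below 5% of `r0` at 300 K.
#' @param chain_id Integer chain identifier.
#' @param anchor Optional numeric `c(x, y, z)` anchor coordinate (nm); when
#'   set, bead 1 is constrained to this point during simulation.
#' @return A `bead_chain`: a tibble with one row per bead (columns `bead`,
#'   `code`, `h`, `charge`, `mass`, `diameter`) and attributes `r0`,
#'   `k_bond`, `chain_id`, `anchor`.
#' @export
#' @examples
#' ch <- sequence_to_chain("FSFG")
#' ch$h
sequence_to_chain <- function(sequence, params = residue_params(), r0 = 0.38,
                              k_bond = 8000, chain_id = 1L, anchor = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  codes <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!codes %in% params$code)
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue code '%s' at position %d.", codes[bad[1]], bad[1]))
  }
  idx <- match(codes, params$code)
  beads <- tibble(
    bead = seq_along(codes),
    code = codes,
    h = params$h[idx],
    charge = params$charge[idx],
    mass = params$mass[idx],
    diameter = params$diameter[idx]
  )
  if (!is.null(anchor)) {
    stopifnot(is.numeric(anchor), length(anchor) == 3L)
    anchor <- as.numeric(anchor)
  }
  structure(beads,
    class = c("bead_chain", class(beads)),
    r0 = r0, k_bond = k_bond, chain_id = as.integer(chain_id), anchor = anchor
  )
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf(
    "<bead_chain> %d beads, total charge %+g e, mass %.0f Da (r0 = %g nm)\n",
    nrow(x), sum(x$charge), sum(x$mass), attr(x, "r0")
  ))
  NextMethod()
}

#' Harmonic bond energy
#'
#' `0.5 * k_bond * (r - r0)^2`, minimized exactly at the rest length.
#'
#' @param r Bead-bead separation(s) in nm, `> 0`.
#' @param chain Optional `bead_chain` supplying `r0` and `k_bond`.
#' @param r0,k_bond Rest length (nm) and stiffness (kJ mol-1 nm-2), used when
#'   no chain is given.
#' @return Energy in kJ/mol, vectorized over `r`.
#' @export
bond_energy <- function(r, chain = NULL, r0 = 0.38, k_bond = 8000) {
  stopifnot(all(r > 0))
  if (!is.null(chain)) {
    r0 <- attr(chain, "r0")
    k_bond <- attr(chain, "k_bond")
  }
  0.5 * k_bond * (r - r0)^2
}
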