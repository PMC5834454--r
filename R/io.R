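#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` and `sequence` (uppercase; lowercase
#'   input is uppercased with a warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf(
                    "Failed to parse FASTA file %s: %s", path,
                    conditionMessage(e))))
  if (length(set) == 0) abort(sprintf("FASTA file %s contains no records.", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warn("Lowercase residues found; sequences were uppercased.")
    seqs <- toupper(seqs)
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#' @param sequences Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  lines <- as.vector(rbind(paste0(">", sequences$id), sequences$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Plain-text XYZ: per frame a bead count line, a comment line with the
#' step index, then one `code x y z` line per bead (nm).
#'
#' @param traj A `cg_trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(traj, path) {
  nb <- dim(traj$frames)[1]
  codes <- traj$system$beads[["code"]] %||% rep("C", nb)
  codes[traj$system$beads$type == "scaffold"] <- "X"
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(nb), sprintf("step %d", traj$steps[f])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", codes,
                       traj$frames[, 1, f], traj$frames[, 2, f],
                       traj$frames[, 3, f]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#' @param path Path to an XYZ file written by [write_xyz()].
#' @return Tibble with columns `frame`, `code`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1; f <- 0
  while (i <= length(lines)) {
    nb <- as.integer(lines[i])
    f <- f + 1
    block <- lines[(i + 2):(i + 1 + nb)]
    parts <- strsplit(block, "\\s+")
    out[[f]] <- tibble(frame = f,
                       code = vapply(parts, `[`, "", 1),
                       x = as.numeric(vapply(parts, `[`, "", 2)),
                       y = as.numeric(vapply(parts, `[`, "", 3)),
                       z = as.numeric(vapply(parts, `[`, "", 4)))
    i <- i + 2 + nb
  }
  dplyr::bind_rows(out)
}

#' Write a density grid as plain text with a JSON metadata header
#'
#' @param grid A `density_grid`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  meta <- jsonlite::toJSON(list(cell = grid$cell, origin = grid$origin,
                                dims = grid$dims, n_frames = grid$n_frames,
                                mass_mode = grid$mass_mode),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# npcmimic density grid v1", as.character(meta)), con)
  writeLines(sprintf("%.17g", as.vector(grid$rho)), con)
  invisible(path)
}

#' Read a density grid written by [write_density_grid()]
#' @param path Path to the grid file.
#' @return A `density_grid`.
#' @export
read_density_grid <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# npcmimic density grid")) {
    abort("Not a density grid file.")
  }
  meta <- jsonlite::fromJSON(lines[2])
  vals <- as.numeric(lines[-(1:2)])
  g <- density_grid(array(vals, dim = meta$dims), cell = meta$cell,
                    origin = meta$origin, n_frames = meta$n_frames)
  g$mass_mode <- meta$mass_mode
  g
}

#' Run configuration
#'
#' A serializable bundle of every pipeline parameter: geometry, force
#' field scalars, protocol, grid, pore model, signal thresholds and seeds.
#' Round-trips losslessly through YAML.
#'
#' @param ... Named configuration entries; defaults cover the standard
#'   ring-on-pore study.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    ring = list(height = 13.85, outer_diameter = 36, bead_diameter = 2.6,
                n_anchors = 32),
    pore = list(diameter = 20, length = 20, sigma_bare = 4.30, rho_crit = 85),
    forcefield = list(eps_max = 3, sigma = 0.6, hp_cutoff = 1.5,
                      screening_length = 0.48, bond_r0 = 0.38, bond_k = 8000),
    protocol = list(timestep = 0.02, temperature = 300, friction = 0.5,
                    n_steps = 2e5, n_discard = 2e4, stride = 1000),
    grid = list(cell = 0.5, box = c(100, 100, 140)),
    signal = list(cutoff_hz = 1000, bins_per_ns = 1000, smooth_bins = 25,
                  min_peak_sep = 0.75, baseline_tol = 0.75, min_length = 0.3),
    seed = 1L
  )
  user <- list(...)
  defaults[names(user)] <- user
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Write the artifacts of a pipeline run to a directory
#'
#' Writes whichever results are supplied: trajectory (XYZ), density grid,
#' profiles/events/summaries (CSV with pinned column order), the exact run
#' configuration used (YAML) and a log with seed and package version. Fails
#' before any computation if the directory cannot be created.
#'
#' @param dir Output directory.
#' @param config A [run_config()].
#' @param trajectory,grid,profiles,events,summary Optional results.
#' @return The directory path, invisibly.
#' @export
write_run_outputs <- function(dir, config, trajectory = NULL, grid = NULL,
                              profiles = NULL, events = NULL, summary = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(sprintf("Output directory %s is not writable.", dir))
  }
  write_run_config(config, file.path(dir, "config.yaml"))
  if (!is.null(trajectory)) write_xyz(trajectory, file.path(dir, "trajectory.xyz"))
  if (!is.null(grid)) write_density_grid(grid, file.path(dir, "density_grid.txt"))
  if (!is.null(profiles)) readr::write_csv(profiles, file.path(dir, "profiles.csv"))
  if (!is.null(events)) readr::write_csv(events, file.path(dir, "events.csv"))
  if (!is.null(summary)) readr::write_csv(summary, file.path(dir, "summary.csv"))
  writeLines(c(sprintf("npcmimic %s", as.character(utils::packageVersion("npcmimic"))),
               sprintf("seed: %s", config$seed),
               sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(dir, "log.txt"))
  invisible(dir)
}
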