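# Trajectory I/O (extended XYZ and LAMMPS dump dialects), result tables and
# run configuration files.

.species_letter <- c("H", "T", "C") # head, tail, cargo

#' Write frames in extended XYZ format
#'
#' One frame per configuration: an atom count line, a comment line carrying
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz" Properties=species:S:1:pos:R:3 Time=...`,
#' then one `S x y z` line per bead (H = head, T = tail, C = cargo).
#' Positions are wrapped into the box.
#'
#' @param sys a [particle_system()] or a list of them (multi-frame).
#' @param path output file.
#' @param digits coordinate precision.
#' @export
write_xyz <- function(sys, path, digits = 8) {
  frames <- if (inherits(sys, "particle_system")) list(sys) else sys
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    fr <- wrap_positions(fr)
    n <- nrow(fr$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.*g 0 0 0 %.*g 0 0 0 %.*g" Properties=species:S:1:pos:R:3 Time=%.*g',
      digits, fr$box[1], digits, fr$box[2], digits, fr$box[3], digits, fr$time), con)
    writeLines(sprintf("%s %.*g %.*g %.*g", .species_letter[fr$role],
                       digits, fr$positions[, 1], digits, fr$positions[, 2],
                       digits, fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path file path.
#' @return list of frames: each `list(positions, role, box, time)`. Raw
#'   coordinates only; attach topology with [frames_to_system()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ frame header at line ", i)
    cm <- lines[i + 1]
    lat <- regmatches(cm, regexec('Lattice="([^"]+)"', cm))[[1]][2]
    if (is.na(lat)) stop("missing Lattice in XYZ comment at line ", i + 1)
    lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    box <- lv[c(1, 5, 9)]
    tm <- regmatches(cm, regexec("Time=([0-9.eE+-]+)", cm))[[1]][2]
    body <- lines[i + 2:(n + 1)]
    if (length(body) < n || anyNA(body))
      stop("truncated XYZ frame starting at line ", i)
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad)) stop("malformed XYZ atom line ", i + 1 + bad[1])
    sp <- vapply(parts, `[[`, "", 1)
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    frames[[length(frames) + 1]] <- list(
      positions = pos, role = match(sp, .species_letter), box = box,
      time = if (is.na(tm)) NA_real_ else as.numeric(tm))
    i <- i + n + 2
  }
  frames
}

#' Write frames as a LAMMPS dump (`id type x y z`, orthogonal box)
#'
#' @inheritParams write_xyz
#' @export
write_lammps_dump <- function(sys, path, digits = 8) {
  frames <- if (inherits(sys, "particle_system")) list(sys) else sys
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    fr <- wrap_positions(fr)
    n <- nrow(fr$positions)
    writeLines(c("ITEM: TIMESTEP", as.character(as.integer(fr$step)),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.*g", digits, fr$box[1]),
                 sprintf("0 %.*g", digits, fr$box[2]),
                 sprintf("0 %.*g", digits, fr$box[3]),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %.*g %.*g %.*g", seq_len(n), fr$role,
                       digits, fr$positions[, 1], digits, fr$positions[, 2],
                       digits, fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS dump trajectory
#'
#' Accepts the `id type x y z` column layout with orthogonal box bounds.
#' @param path file path.
#' @return list of frames as in [read_xyz()] (plus `step`).
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("expected ITEM: TIMESTEP at line ", i)
    step <- as.numeric(lines[i + 1])
    if (!startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
      stop("expected ITEM: NUMBER OF ATOMS at line ", i + 2)
    n <- as.integer(lines[i + 3])
    if (!startsWith(lines[i + 4], "ITEM: BOX BOUNDS"))
      stop("expected ITEM: BOX BOUNDS at line ", i + 4)
    bb <- do.call(rbind, lapply(lines[i + 5:7], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    box <- bb[, 2] - bb[, 1]
    hdr <- lines[i + 8]
    if (!startsWith(hdr, "ITEM: ATOMS"))
      stop("expected ITEM: ATOMS at line ", i + 8)
    cols <- strsplit(sub("ITEM: ATOMS ", "", hdr), "\\s+")[[1]]
    need <- match(c("id", "type", "x", "y", "z"), cols)
    if (anyNA(need)) stop("dump must provide id type x y z columns")
    body <- lines[i + 8 + seq_len(n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                nrow = n, byrow = TRUE)
    ord <- order(m[, need[1]])
    frames[[length(frames) + 1]] <- list(
      positions = m[ord, need[3:5], drop = FALSE],
      role = as.integer(m[ord, need[2]]), box = box,
      time = NA_real_, step = step)
    i <- i + 9 + n
  }
  frames
}

#' Attach topology to a raw trajectory frame
#'
#' Builds a full [particle_system()] from a frame read by [read_xyz()] /
#' [read_lammps_dump()] and a template system providing the topology
#' (species, bonds, angles). Bead count and roles must match.
#'
#' @param frame one frame.
#' @param template a `particle_system` with the same bead layout.
#' @export
frames_to_system <- function(frame, template) {
  stopifnot(nrow(frame$positions) == nrow(template$positions))
  if (!all(frame$role == template$role))
    stop("frame roles do not match the template topology")
  template$positions <- frame$positions
  template$velocities <- matrix(0, nrow(frame$positions), 3)
  template$box <- frame$box
  template$time <- if (is.na(frame$time)) template$time else frame$time
  if (!is.null(frame$step)) template$step <- frame$step
  template
}

#' Write a result table with unit-annotated headers
#'
#' Tab-separated values; the first line is a `#` comment naming the units
#' of each column (sigma, tau, k_BT conventions).
#'
#' @param df data.frame.
#' @param path output path.
#' @param units named character vector column -> unit (unnamed columns get
#'   "-").
#' @export
write_result_table <- function(df, path, units = NULL) {
  u <- rep("-", ncol(df))
  names(u) <- names(df)
  if (!is.null(units)) u[names(units)] <- units
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(names(u), u, sep = "=", collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration

.config_schema <- list(
  experiment = c("assemble", "run", "phase-scan", "spectrum", "cylinder",
                 "gaussian", "wrap", "pores", "fit-two-state"),
  forcefield = names(formals(forcefield_params)),
  integrator = names(formals(integrator_params)),
  build = c("experiment", "n_lipids", "f_bi", "box", "cylinder_radius",
            "cylinder_length", "patch_sizes", "cargo", "seed", "spacing",
            "box_z"),
  run = c("n_steps", "steps_equil", "steps_sample", "sample_every",
          "replicates", "eps_range", "resolution"),
  grid = NULL,     # free-form data.frame-like for scans
  input = NULL,    # paths for analysis-only runs
  output = NULL,
  seed = NULL)

#' Read and validate a run configuration
#'
#' YAML document with sections `experiment`, `forcefield`, `integrator`,
#' `build`, `run`, `grid`, `input`, `output`, `seed`. Unknown sections or
#' unknown keys within a typed section are rejected before any computation;
#' defaults are resolved from [forcefield_params()]/[integrator_params()].
#'
#' @param path YAML file.
#' @return list of class `run_config` with `forcefield` and `integrator`
#'   materialised.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in c("forcefield", "integrator", "build", "run")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
      if (length(bad))
        stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$experiment)) stop("config must name an experiment")
  if (!cfg$experiment %in% .config_schema$experiment)
    stop("unknown experiment: ", cfg$experiment)
  seed <- cfg$seed %||% 1
  ff <- do.call(forcefield_params, cfg$forcefield %||% list())
  ipargs <- cfg$integrator %||% list()
  if (is.null(ipargs$seed)) ipargs$seed <- seed
  ip <- do.call(integrator_params, ipargs)
  structure(list(experiment = cfg$experiment, forcefield = ff,
                 integrator = ip, build = cfg$build %||% list(),
                 run = cfg$run %||% list(), grid = cfg$grid,
                 input = cfg$input, output = cfg$output %||% ".",
                 seed = seed, raw = cfg),
            class = "run_config")
}

#' Write the fully resolved configuration next to the outputs
#'
#' @param cfg a `run_config`.
#' @param dir output directory.
#' @export
write_resolved_config <- function(cfg, dir) {
  resolved <- cfg$raw
  resolved$forcefield <- unclass(cfg$forcefield)
  resolved$integrator <- unclass(cfg$integrator)
  resolved$seed <- cfg$seed
  path <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(resolved, path)
  invisible(path)
}
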