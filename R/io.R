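#' Default MARTINI POPC tail-bead names
#'
#' The hydrophobic selection used for the density order parameter of POPC
#' membranes in the MARTINI model (glycerol and headgroup beads excluded).
#' @return character vector of bead names.
#' @export
martini_popc_tails <- function() {
  c("C1A", "D2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B")
}

#' Read a particle configuration from a GRO or XYZ file
#'
#' GRO files carry positions in nm and the box on the last line; XYZ files
#' carry no box, so one must be supplied (coordinates are taken as nm).
#' The hydrophobic mask is resolved from atom names.
#'
#' @param path file path.
#' @param format `"gro"` or `"xyz"`; default guessed from the extension.
#' @param selection character vector of atom names forming the hydrophobic
#'   mask; default the MARTINI POPC tail beads. `NULL` selects all atoms.
#' @param box length-3 box in nm (required for XYZ, ignored for GRO).
#' @return a [particle_configuration()] with `atom_names` and `res_names`
#'   attached.
#' @export
read_particles <- function(path, format = NULL,
                           selection = martini_popc_tails(), box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("gro", "xyz"))
  parsed <- if (format == "gro") parse_gro(path) else parse_xyz(path, box)
  mask <- if (is.null(selection)) rep(TRUE, nrow(parsed$positions)) else
    parsed$names %in% selection
  if (!any(mask))
    stop("empty hydrophobic selection: no atoms named ",
         paste(selection, collapse = "/"))
  cfg <- particle_configuration(parsed$positions, parsed$box, mask = mask)
  cfg$atom_names <- parsed$names
  cfg$res_names <- parsed$resnames
  cfg
}

parse_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file at line 2: bad atom count")
  if (length(lines) < n + 3L)
    stop("malformed GRO file: expected ", n + 3L, " lines, got ",
         length(lines))
  al <- lines[3:(2 + n)]
  resnames <- trimws(substr(al, 6, 10))
  names <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (any(is.na(c(x, y, z)))) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("malformed GRO file at line ", bad + 2L, ": bad coordinates")
  }
  box <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]])
  if (length(box) < 3L || any(is.na(box[1:3])))
    stop("malformed GRO file at line ", n + 3L, ": bad box")
  list(positions = cbind(x, y, z), box = box[1:3], names = names,
       resnames = resnames)
}

parse_xyz <- function(path, box) {
  if (is.null(box)) stop("XYZ carries no box; supply box lengths (nm)")
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ file at line 1: bad atom count")
  if (length(lines) < n + 2L) stop("malformed XYZ file: truncated")
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  names <- vapply(toks, `[`, "", 1L)
  pos <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (any(is.na(pos))) {
    bad <- which(apply(is.na(pos), 1L, any))[1]
    stop("malformed XYZ file at line ", bad + 2L, ": bad coordinates")
  }
  list(positions = pos, box = as.numeric(rep_len(box, 3L)), names = names,
       resnames = rep("", n))
}

#' Write a particle configuration to GRO
#'
#' @param config a [particle_configuration()].
#' @param path output path.
#' @param names atom names; default stored names or `"C1A"`.
#' @param resname residue name (default `"POPC"`).
#' @param title comment line.
#' @return the path, invisibly.
#' @export
write_gro <- function(config, path, names = NULL, resname = "POPC",
                      title = "stalkpath configuration") {
  n <- nrow(config$positions)
  if (is.null(names)) names <- config$atom_names
  if (is.null(names)) names <- rep("C1A", n)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     rep(1L, n), resname, names, seq_len(n) %% 100000L,
                     config$positions[, 1], config$positions[, 2],
                     config$positions[, 3]),
             sprintf("%10.5f%10.5f%10.5f", config$box[1], config$box[2],
                     config$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a density field in OpenDX volumetric format
#'
#' Plain-text OpenDX regular-grid export readable by common visualization
#' tools; the origin is the first cell center.
#'
#' @param field a [density_field()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_opendx <- function(field, path) {
  g <- field$grid
  n <- g$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %g %g %g", g$dL[1] / 2, g$dL[2] / 2, g$dL[3] / 2),
    sprintf("delta %g 0 0", g$dL[1]),
    sprintf("delta 0 %g 0", g$dL[2]),
    sprintf("delta 0 0 %g", g$dL[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  # OpenDX expects z fastest
  v <- as.vector(aperm(field$values, c(3, 2, 1)))
  pad <- c(v, rep(NA_real_, (3 - length(v) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1L, function(r)
    paste(stats::na.omit(r), collapse = " "))
  writeLines(rows, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Export a 1D or 2D field slice as CSV
#'
#' @param field a [density_field()].
#' @param path output path.
#' @param axis slice normal.
#' @param coordinate slice position (nm); default box center.
#' @return the path, invisibly.
#' @export
write_field_slice_csv <- function(field, path, axis = "y",
                                  coordinate = NULL) {
  a <- axis_index(axis)
  if (is.null(coordinate)) coordinate <- field$grid$box[a] / 2
  av <- axial_view(field, a)
  S <- axial_slice(av, coordinate)
  nms <- c("x", "y", "z")[av$lat]
  df <- expand.grid(av$c1, av$c2)
  names(df) <- nms
  df$density <- as.vector(S)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

CHECKPOINT_VERSION <- 1L

#' Write a checkpoint
#'
#' Serializes any pipeline object (string paths, fields, profiles) with full
#' numeric fidelity plus provenance (seed, configuration, package version).
#' Round trips are bit-exact.
#'
#' @param object the object to store.
#' @param path output path.
#' @param provenance optional named list (seeds, configs) stored alongside.
#' @return the path, invisibly.
#' @export
write_checkpoint <- function(object, path, provenance = list()) {
  payload <- list(version = CHECKPOINT_VERSION,
                  package = "stalkpath",
                  package_version = as.character(utils::packageVersion("stalkpath")),
                  provenance = provenance,
                  object = object)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a checkpoint
#'
#' @param path checkpoint path.
#' @return list with `object` and `provenance`.
#' @export
read_checkpoint <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable checkpoint: ", conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$version))
    stop("corrupted checkpoint: missing header")
  if (payload$version != CHECKPOINT_VERSION)
    stop("checkpoint version ", payload$version,
         " needs migration; this build reads version ", CHECKPOINT_VERSION)
  payload[c("object", "provenance")]
}

#' Default run configuration
#'
#' Protocol defaults: 90^3 grid for vesicle-scale boxes (20^3 for small
#' planar boxes), 24 path replicas (19 planar), umbrella kappa = 50 kJ/mol at
#' 300 K, Allen-Cahn step from `epsilon * lambda / dV = 0.03`, iso-density
#' threshold 2.2 nm^-3.
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(grid = list(n = c(90L, 90L, 90L), box = c(26.31, 26.83, 20.74)),
       umbrella = list(kappa = 50, temperature = 300),
       string = list(n_replicas = 24L, epsilon_rel = 0.03,
                     max_iterations = 400L, tol_disp = 1e-4, tol_F = 1e-3,
                     endpoint_mode = "evolve"),
       geometry = list(threshold = 2.2),
       seed = 1L,
       output_dir = "results")
}

#' Read and validate a run configuration (YAML)
#'
#' Unknown top-level keys are rejected; supplied values override the defaults
#' of [default_run_config()] and are checked for type and sign.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  with(cfg, {
    stopifnot(length(grid$n) == 3L, all(grid$n >= 1),
              length(grid$box) == 3L, all(grid$box > 0),
              umbrella$kappa > 0, umbrella$temperature > 0,
              string$n_replicas >= 3L, string$epsilon_rel > 0,
              string$tol_disp > 0, string$tol_F > 0,
              string$endpoint_mode %in% c("evolve", "pinned"),
              geometry$threshold > 0)
  })
  cfg
}

#' Build pipeline objects from a run configuration
#'
#' @param cfg a configuration list from [read_run_config()].
#' @return list with `grid` ([grid_spec()]), `params` ([umbrella_params()])
#'   and `string` ([string_config()]).
#' @export
config_objects <- function(cfg) {
  params <- umbrella_params(cfg$umbrella$kappa, cfg$umbrella$temperature)
  list(grid = grid_spec(cfg$grid$n, cfg$grid$box),
       params = params,
       string = string_config(
         epsilon = cfg$string$epsilon_rel * params$kBT / params$kappa,
         max_iterations = cfg$string$max_iterations,
         tol_disp = cfg$string$tol_disp, tol_F = cfg$string$tol_F,
         endpoint_mode = cfg$string$endpoint_mode, seed = cfg$seed))
}
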