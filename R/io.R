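# Configuration handling, legacy-VTK snapshots, per-cycle CSV outputs and
# checkpointing.

config_defaults <- function() {
  list(
    fluid = list(),
    thrombosis = list(),
    geometry = list(kind = "idealized_dissection"),
    waveform = list(),
    run = list(n_cycles = 20, spinup_cycles = 2, coagulant_precycles = 0,
               safety = 0.4, snapshots_per_cycle = 4, tol = 1e-10,
               max_dt = Inf, outdir = NULL, checkpoint_path = NULL,
               inlet_fn = NULL, init_wall_C = NULL, pre_thrombosed = NULL),
    pas = list(n_seeds = 24, release_fracs = c(0, 0.15, 0.3, 0.45),
               dt_particle = 5e-3, max_cycles = 10)
  )
}

allowed_config_keys <- function() {
  list(
    fluid = names(formals(fluid_props)),
    thrombosis = names(formals(thrombosis_params)),
    geometry = c("kind", "length", "height", "nx", "ny", "closed",
                 "inlet_height", "step_height", "upstream_len",
                 "downstream_len", "resolution", "lumen_height",
                 "fl_height", "flap_thickness", "tear_positions",
                 "tear_widths"),
    waveform = names(formals(waveform_params)),
    run = names(config_defaults()$run),
    pas = names(config_defaults()$pas)
  )
}

#' Normalize and validate a configuration list
#'
#' Fills all defaults (the model constants and the standard run protocol),
#' rejects unknown sections or keys, and validates parameter values by
#' constructing the parameter objects.
#'
#' @param config a (possibly partial) configuration list with sections
#'   `fluid`, `thrombosis`, `geometry`, `waveform`, `run`, `pas`
#' @return the completed configuration list
#' @export
normalize_config <- function(config) {
  if (is.null(config)) config <- list()
  defaults <- config_defaults()
  allowed <- allowed_config_keys()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  }
  out <- defaults
  for (sec in names(config)) {
    keys <- names(config[[sec]])
    unknown <- setdiff(keys, allowed[[sec]])
    if (length(unknown) > 0) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(unknown, collapse = ", "))
    }
    out[[sec]] <- utils::modifyList(out[[sec]], config[[sec]],
                                    keep.null = TRUE)
  }
  # validate by construction
  do.call(fluid_props, out$fluid)
  do.call(thrombosis_params, out$thrombosis)
  do.call(waveform_params, out$waveform)
  out
}

#' Load a run configuration from a YAML file
#'
#' An empty file yields the full-default configuration (the model
#' constants and standard protocol).  Unknown sections or keys are
#' rejected with an error naming the offending key.
#'
#' @param path path to a YAML config file
#' @return a validated configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  normalize_config(raw)
}

#' Write a configuration to a YAML file
#'
#' Function-valued entries (custom inlet profiles, pre-thrombosed region
#' callbacks) are not serializable and are dropped.
#'
#' @param config a configuration list
#' @param path output path
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  drop_fn <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_fn)
      x[!vapply(x, is.null, logical(1))]
    } else if (is.function(x)) NULL else x
  }
  cfg <- drop_fn(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# dispatch a geometry section to the right builder
build_case_grid <- function(geometry) {
  kind <- geometry$kind
  if (is.null(kind)) stop("geometry section needs a 'kind' key")
  args <- geometry[setdiff(names(geometry), "kind")]
  switch(kind,
    channel = do.call(build_channel, args),
    box = do.call(build_channel, c(args, list(closed = TRUE))),
    backward_facing_step = do.call(build_backward_facing_step, args),
    idealized_dissection = do.call(build_idealized_dissection, args),
    stop("unknown geometry kind: ", kind)
  )
}

# ---- legacy VTK structured-points IO -----------------------------------

fmt <- function(x) formatC(x, format = "g", digits = 17)

#' Write a field snapshot as legacy ASCII VTK
#'
#' Structured-points dataset with all cell fields as CELL_DATA arrays
#' (cell-centered velocity components, pressure, viscosity, porosity,
#' shear rate, all species and the fluid mask) plus a FIELD block holding
#' the exact staggered face velocities and the simulation time, so
#' [read_snapshot()] round-trips a `field_state` to full float64
#' precision.
#'
#' @param state a `field_state`
#' @param grid a `case_grid`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_snapshot <- function(state, grid, path) {
  nx <- grid$nx; ny <- grid$ny
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("thromboflow snapshot t=", fmt(state$t))
  w("ASCII")
  w("DATASET STRUCTURED_POINTS")
  w("DIMENSIONS ", nx + 1, " ", ny + 1, " 1")
  w("ORIGIN 0 0 0")
  w("SPACING ", fmt(grid$dx), " ", fmt(grid$dy), " 1")
  w("CELL_DATA ", nx * ny)
  ucell <- 0.5 * (state$u[-1, ] + state$u[-(nx + 1), ])
  vcell <- 0.5 * (state$v[, -1] + state$v[, -(ny + 1)])
  arrays <- list(u = ucell, v = vcell, p = state$p, mu = state$mu,
                 eps = state$eps, gamma = state$gamma, RT = state$RT,
                 RP_rel = state$RP_rel, AP_rel = state$AP_rel,
                 C = state$C, BP = state$BP)
  for (nm in names(arrays)) {
    w("SCALARS ", nm, " double 1")
    w("LOOKUP_TABLE default")
    writeLines(fmt(as.vector(arrays[[nm]])), con)
  }
  w("SCALARS mask int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(as.vector(grid$mask)), con)
  w("FIELD FieldData 3")
  w("t 1 1 double")
  w(fmt(state$t))
  w("u_face 1 ", (nx + 1) * ny, " double")
  writeLines(fmt(as.vector(state$u)), con)
  w("v_face 1 ", nx * (ny + 1), " double")
  writeLines(fmt(as.vector(state$v)), con)
  invisible(path)
}

#' Read a legacy VTK snapshot back into a field state
#'
#' @param path a file written by [write_snapshot()]
#' @return a `field_state` (with `clips` counters reset)
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 8 || !grepl("^# vtk DataFile", lines[1]) ||
      !any(grepl("^DATASET STRUCTURED_POINTS", lines))) {
    stop("read_snapshot: not a legacy VTK structured-points file: ", path)
  }
  dims <- as.integer(strsplit(sub("^DIMENSIONS ", "",
                                  grep("^DIMENSIONS", lines, value = TRUE)),
                              " ")[[1]])
  nx <- dims[1] - 1L; ny <- dims[2] - 1L
  ncell <- nx * ny
  vals <- function(start, n) {
    out <- numeric(0)
    k <- start
    while (length(out) < n) {
      out <- c(out, as.numeric(strsplit(trimws(lines[k]), "[ \t]+")[[1]]))
      k <- k + 1
    }
    out[seq_len(n)]
  }
  get_scalar <- function(nm) {
    hit <- grep(paste0("^SCALARS ", nm, " "), lines)
    if (length(hit) == 0) stop("read_snapshot: missing array ", nm)
    matrix(vals(hit[1] + 2, ncell), nx, ny)
  }
  st <- structure(list(), class = "field_state")
  for (nm in c("p", "mu", "eps", "gamma", "RT", "RP_rel", "AP_rel",
               "C", "BP")) {
    st[[nm]] <- get_scalar(nm)
  }
  mask <- get_scalar("mask")
  hit <- grep("^u_face ", lines)
  st$u <- matrix(vals(hit + 1, (nx + 1) * ny), nx + 1, ny)
  hit <- grep("^v_face ", lines)
  st$v <- matrix(vals(hit + 1, nx * (ny + 1)), nx, ny + 1)
  hit <- grep("^t 1 1 double", lines)
  st$t <- as.numeric(lines[hit + 1])
  st$gamma_avg <- matrix(0, nx, ny)
  st$dep_kind <- matrix(0L, nx, ny)
  st$dep_tawss <- matrix(NA_real_, nx, ny)
  st$dep_gavg <- matrix(NA_real_, nx, ny)
  st$div_max <- 0
  st$clips <- c(RT = 0L, RP_rel = 0L, AP_rel = 0L, C = 0L)
  attr(st, "mask") <- matrix(as.integer(mask), nx, ny)
  st
}

# per-cycle run-directory outputs: cycles.csv and wall TAWSS CSV
write_cycle_outputs <- function(state, grid, wall, cycles, outdir, cyc) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  utils::write.csv(cycles, file.path(outdir, "cycles.csv"),
                   row.names = FALSE)
  wf <- grid$wall_faces
  utils::write.csv(data.frame(face = seq_len(nrow(wf)), x = wf$x, y = wf$y,
                              tawss = wall$tawss),
                   file.path(outdir, sprintf("wall_cycle%03d.csv", cyc)),
                   row.names = FALSE)
  invisible(NULL)
}

#' Write grid geometry as legacy VTK plus a JSON metadata sidecar
#'
#' The VTK file carries the fluid mask and region masks as CELL_DATA; the
#' sidecar (`<path>.json`) records cell sizes and the geometry metadata.
#'
#' @param grid a `case_grid`
#' @param path output VTK path
#' @return `path`, invisibly
#' @export
write_case_vtk <- function(grid, path) {
  nx <- grid$nx; ny <- grid$ny
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("thromboflow case geometry")
  w("ASCII")
  w("DATASET STRUCTURED_POINTS")
  w("DIMENSIONS ", nx + 1, " ", ny + 1, " 1")
  w("ORIGIN 0 0 0")
  w("SPACING ", fmt(grid$dx), " ", fmt(grid$dy), " 1")
  w("CELL_DATA ", nx * ny)
  w("SCALARS mask int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(as.vector(grid$mask)), con)
  for (rn in names(grid$regions)) {
    w("SCALARS ", rn, " int 1")
    w("LOOKUP_TABLE default")
    writeLines(as.character(as.integer(as.vector(grid$regions[[rn]]))), con)
  }
  meta <- c(grid$meta, list(nx = nx, ny = ny, dx = grid$dx, dy = grid$dy))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
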