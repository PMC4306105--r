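#' Run configuration
#'
#' Aggregates every knob of the pipeline in one validated object: geometry,
#' fluid and transport properties, solver settings, metric options, mesh
#' resolution and the Reynolds numbers of the sweep.  The defaults reproduce
#' the reference four-case study (Re 200--800 in a 3 mm / 10 mm / 90 degree
#' stented bend at 20 cells/mm).
#'
#' @param geometry A [stent_geometry()] object (or a named list of its
#'   arguments).
#' @param fluid A [fluid_properties()] object.
#' @param transport A [transport_properties()] object.
#' @param solver A [solver_settings()] object.
#' @param resolution Mesh resolution in cells per mm.
#' @param Re_values Reynolds numbers of the sweep.
#' @param wss_threshold Low-WSS cutoff in Pa.
#' @param line_offset Monitoring-line offset from the lumen--wall interface in
#'   m.
#' @param wss_extent `"stented"` or `"full"`: denominator of the low-WSS
#'   fraction.
#' @param output_dir Directory for file exports, or `NULL` for none.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = stent_geometry(),
                       fluid = fluid_properties(),
                       transport = transport_properties(),
                       solver = solver_settings(),
                       resolution = 20,
                       Re_values = c(200, 400, 600, 800),
                       wss_threshold = 0.5,
                       line_offset = 0.25e-3,
                       wss_extent = "stented",
                       output_dir = NULL) {
  if (is.list(geometry) && !inherits(geometry, "stent_geometry"))
    geometry <- do.call(stent_geometry, geometry)
  cfg <- structure(
    list(geometry = geometry, fluid = fluid, transport = transport,
         solver = solver, resolution = resolution, Re_values = Re_values,
         wss_threshold = wss_threshold, line_offset = line_offset,
         wss_extent = wss_extent, output_dir = output_dir),
    class = "run_config")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Re-checks every module-level invariant (geometry, fluid, transport, solver,
#' metric options) before any solve.
#'
#' @param config A [run_config()] object.
#' @return `config`, invisibly; errors on the first violated invariant.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_geometry(config$geometry)
  stopifnot(inherits(config$fluid, "fluid_properties"),
            inherits(config$transport, "transport_properties"),
            inherits(config$solver, "solver_settings"))
  if (!is.numeric(config$resolution) || config$resolution < 10)
    stop("resolution must be at least 10 cells/mm", call. = FALSE)
  if (!is.numeric(config$Re_values) || any(config$Re_values <= 0) ||
      any(config$Re_values > 2000))
    stop("Re_values must lie in (0, 2000]", call. = FALSE)
  if (config$wss_threshold <= 0)
    stop("wss_threshold must be > 0", call. = FALSE)
  if (!config$wss_extent %in% c("stented", "full"))
    stop("wss_extent must be 'stented' or 'full'", call. = FALSE)
  r <- config$geometry$lumen_diameter / 2
  if (config$line_offset <= 0 || config$line_offset >= r ||
      config$line_offset >= config$geometry$wall_thickness)
    stop("line_offset must fit inside both the lumen and the wall layer",
         call. = FALSE)
  invisible(config)
}

## Internal: plain-list view of a config (for YAML and hashing).
config_as_list <- function(config) {
  list(
    geometry = unclass(config$geometry),
    fluid = unclass(config$fluid),
    transport = unclass(config$transport),
    solver = unclass(config$solver),
    resolution = config$resolution,
    Re_values = as.numeric(config$Re_values),
    wss_threshold = config$wss_threshold,
    line_offset = config$line_offset,
    wss_extent = config$wss_extent)
}

#' Write / read a run configuration as YAML
#'
#' The YAML file stores every physical quantity in SI units.  Round-tripping
#' through [write_run_config()] and [read_run_config()] reproduces the
#' configuration exactly.
#'
#' @param config A [run_config()] object.
#' @param path File path of the YAML configuration.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config_as_list(config),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  run_config(
    geometry = do.call(stent_geometry, y$geometry),
    fluid = do.call(fluid_properties, y$fluid),
    transport = do.call(transport_properties, y$transport),
    solver = do.call(solver_settings, y$solver),
    resolution = y$resolution,
    Re_values = as.numeric(y$Re_values),
    wss_threshold = y$wss_threshold,
    line_offset = y$line_offset,
    wss_extent = y$wss_extent)
}

#' Configuration hash
#'
#' Deterministic 64-bit FNV-1a hash of the serialised configuration, written
#' into every output file so results can be traced back to the exact settings
#' that produced them.
#'
#' @param config A [run_config()] object.
#' @return A 16-character lowercase hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bytes <- charToRaw(paste(utils::capture.output(
    utils::str(config_as_list(config), digits.d = 15, vec.len = 1e6)),
    collapse = "\n"))
  ## 64-bit FNV-1a carried as two 32-bit halves held in doubles (exact below
  ## 2^53).  The FNV prime is 2^40 + 2^8 + 0xb3, so the 64-bit product
  ## h * prime splits into small exact pieces.
  two32 <- 4294967296
  lo <- 2216829221  # 0x84222325
  hi <- 3421674629  # 0xcbf29ce4
  for (b in as.integer(bytes)) {
    lo <- (lo - lo %% 256) + bitwXor(lo %% 256, b)
    A <- lo * 0xb3 + lo * 256
    new_lo <- A %% two32
    hi <- (hi * 0xb3 + hi * 256 + lo * 256 + (A - new_lo) / two32) %% two32
    lo <- new_lo
  }
  hex <- function(x) paste(sprintf("%04x", c(x %/% 65536, x %% 65536)),
                           collapse = "")
  paste0(hex(hi), hex(lo))
}

#' Export fields as a legacy-ASCII VTK structured grid
#'
#' Writes the bend-plane mesh and any number of cell fields as a
#' `STRUCTURED_GRID` legacy VTK file (ASCII), readable by ParaView and VisIt.
#' Points are the physical node coordinates from [mesh_nodes()] (z = 0); each
#' entry of `cell_data` becomes a `SCALARS` cell array.
#'
#' @param mesh A `stent_mesh`.
#' @param cell_data Named list of `nx x ny` matrices (or vectors of length
#'   `nx*ny`).
#' @param path Output file path (conventionally `.vtk`).
#' @param title Dataset title line.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(mesh, cell_data, path, title = "stentflow fields") {
  stopifnot(inherits(mesh, "stent_mesh"))
  if (length(cell_data) && is.null(names(cell_data)))
    stop("cell_data must be a named list", call. = FALSE)
  nodes <- mesh_nodes(mesh)
  npx <- mesh$nx + 1L; npy <- mesh$ny + 1L
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", title, "ASCII", "DATASET STRUCTURED_GRID",
     sprintf("DIMENSIONS %d %d 1", npx, npy),
     sprintf("POINTS %d double", npx * npy))
  ## VTK expects x fastest: loop j (rows of the grid) outermost
  pts <- sprintf("%.9g %.9g 0", as.numeric(nodes$x), as.numeric(nodes$y))
  wl(pts)
  wl(sprintf("CELL_DATA %d", mesh$nx * mesh$ny))
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (is.matrix(v)) v <- as.numeric(v)
    if (length(v) != mesh$nx * mesh$ny)
      stop("cell field '", nm, "' has the wrong length", call. = FALSE)
    wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
       sprintf("%.9g", v))
  }
  invisible(path)
}

#' Export fields as a per-cell CSV table
#'
#' One row per cell with the curvilinear coordinates, region flag and any
#' requested cell fields; a `# config` comment line carries the configuration
#' hash when one is supplied.
#'
#' @param mesh A `stent_mesh`.
#' @param fields Named list of `nx x ny` matrices.
#' @param path Output CSV path.
#' @param hash Optional configuration hash string to embed.
#' @return `path`, invisibly.
#' @export
export_field_csv <- function(mesh, fields, path, hash = NULL) {
  stopifnot(inherits(mesh, "stent_mesh"))
  df <- data.frame(
    s = rep(mesh$s_cent, mesh$ny),
    n = rep(mesh$n_cent, each = mesh$nx),
    region = as.integer(mesh$region))
  for (nm in names(fields)) df[[nm]] <- as.numeric(fields[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash))
    writeLines(sprintf("# config %s stentflow %s", hash,
                       as.character(utils::packageVersion("stentflow"))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

## Internal: assemble one SweepResult row from solved fields.
sweep_row <- function(config, Re, mesh, flow, conc) {
  g <- config$geometry
  Dn <- dean_number(Re, g$lumen_diameter / 2, g$bend_radius)
  wss <- compute_wss(flow, mesh)
  lw <- low_wss_fraction(wss, config$wss_threshold, config$wss_extent)
  ## peak velocity magnitude at the mid-bend cross-section
  s_mid <- mean(mesh$bend_s)
  i_mid <- which.min(abs(mesh$s_cent - s_mid))
  lum <- mesh$region[i_mid, ] == REGION_LUMEN
  v_peak <- max(sqrt(flow$u[i_mid, lum]^2 + flow$v[i_mid, lum]^2))
  pos <- reference_lines(mesh, config$line_offset)
  prof <- lapply(pos, function(n) line_profile(conc, mesh, n))
  segB_in <- segment_stats(prof$B_inner, mesh$stent_s)
  segB_out <- segment_stats(prof$B_outer, mesh$stent_s)
  fb <- drug_flux_balance(conc, mesh, flow, config$transport)
  row <- data.frame(
    Re = Re,
    v_char = flow$inlet$v_char,
    Dn = Dn,
    regime = classify_dean_regime(Dn),
    low_wss_total = lw$total, low_wss_inner = lw$inner,
    low_wss_outer = lw$outer,
    peak_midbend_velocity = v_peak,
    stringsAsFactors = FALSE)
  for (nm in names(prof)) {
    row[[paste0(nm, "_peak")]] <- max(prof[[nm]]$value)
    row[[paste0(nm, "_mean")]] <- mean(prof[[nm]]$value)
  }
  for (k in seq_len(nrow(segB_in))) {
    row[[paste0("B_inner_", segB_in$segment[k], "_mean")]] <- segB_in$mean[k]
    row[[paste0("B_outer_", segB_out$segment[k], "_mean")]] <- segB_out$mean[k]
  }
  row$flux_residual <- fb$residual
  row$flow_iterations <- flow$iterations
  row
}

#' Run the full pipeline for one Reynolds number
#'
#' Builds the mesh, solves the flow and the drug transport, evaluates every
#' summary metric, and (when `config$output_dir` is set) writes the VTK field
#' file, the per-cell CSV and a JSON summary, all stamped with the
#' configuration hash and package version.
#'
#' @param config A [run_config()] object.
#' @param Re Reynolds number of the case; the inlet velocity is derived from
#'   it via [velocity_for_reynolds()].
#' @param mesh Optional pre-built `stent_mesh` (rebuilt from the config when
#'   `NULL`); passing one avoids repeated meshing across a sweep.
#' @return A one-row `SweepResult` data.frame (see [run_sweep()]), with the
#'   solved fields attached as attributes `flow` and `conc`.
#' @export
run_case <- function(config, Re, mesh = NULL) {
  validate_config(config)
  if (is.null(mesh)) mesh <- build_geometry(config$geometry, config$resolution)
  v <- velocity_for_reynolds(config$fluid, Re, config$geometry$lumen_diameter)
  message(sprintf("[stentflow] Re %.6g: solving flow (v = %.4g m/s)", Re, v))
  flow <- solve_flow(mesh, config$fluid, inlet_spec(v), config$solver)
  message(sprintf("[stentflow] Re %.6g: flow converged in %d iterations",
                  Re, flow$iterations))
  conc <- solve_drug(mesh, flow, config$transport)
  row <- sweep_row(config, Re, mesh, flow, conc)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    h <- config_hash(config)
    base <- file.path(config$output_dir, sprintf("case_Re%g", Re))
    export_vtk(mesh,
               list(u = flow$u, v = flow$v, p = flow$p,
                    concentration = conc$conc,
                    region = matrix(as.numeric(mesh$region),
                                    mesh$nx, mesh$ny)),
               paste0(base, ".vtk"),
               title = sprintf("stentflow Re=%g config=%s", Re, h))
    export_field_csv(mesh,
                     list(u = flow$u, v = flow$v, p = flow$p,
                          concentration = conc$conc),
                     paste0(base, ".csv"), hash = h)
    summary <- c(list(config_hash = h,
                      package_version =
                        as.character(utils::packageVersion("stentflow"))),
                 as.list(row))
    jsonlite::write_json(summary, paste0(base, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(row, "flow") <- flow
  attr(row, "conc") <- conc
  row
}

#' Run the Reynolds-number sweep
#'
#' Runs [run_case()] for each requested Reynolds number (default: the
#' four-case study 200, 400, 600, 800) on a shared mesh and stacks the summary
#' rows.  A failing case is recorded in its row (`error` column) and the sweep
#' continues.  When `config$output_dir` is set, the combined table is written
#' as `sweep.csv` together with the per-case exports.
#'
#' @param config A [run_config()] object.
#' @param Re_values Reynolds numbers to run; defaults to `config$Re_values`.
#' @return A `sweep_result` data.frame, one row per Re, with columns Re,
#'   v_char, Dn, regime, low-WSS fractions (total/inner/outer), peak mid-bend
#'   velocity, Line A/B peaks and means per side, Line-B segment means, flux
#'   residual and solver iterations.
#' @export
run_sweep <- function(config, Re_values = config$Re_values) {
  validate_config(config)
  if (length(Re_values) == 0) {
    out <- data.frame(Re = numeric(0))
    class(out) <- c("sweep_result", "data.frame")
    return(out)
  }
  mesh <- build_geometry(config$geometry, config$resolution)
  rows <- lapply(Re_values, function(Re) {
    tryCatch({
      r <- run_case(config, Re, mesh = mesh)
      attr(r, "flow") <- NULL; attr(r, "conc") <- NULL
      r$error <- NA_character_
      r
    }, error = function(e) {
      message(sprintf("[stentflow] Re %.6g FAILED: %s", Re,
                      conditionMessage(e)))
      data.frame(Re = Re, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(config$output_dir, "sweep.csv"), "w")
    writeLines(sprintf("# config %s stentflow %s", config_hash(config),
                       as.character(utils::packageVersion("stentflow"))), con)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}
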