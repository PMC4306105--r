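#' Blood (fluid) properties
#'
#' Density and dynamic viscosity of the working fluid.  Defaults are whole
#' blood treated as an incompressible Newtonian fluid:
#' rho = 1055 kg/m^3, mu = 3.5e-3 kg/(m s).
#'
#' @param rho Density in kg/m^3.
#' @param mu Dynamic viscosity in kg/(m s).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1055, mu = 3.5e-3) {
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0", call. = FALSE)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Inlet specification
#'
#' A parabolic (plane-Poiseuille) inlet profile scaled so that its
#' cross-sectional mean equals `v_char`; in the planar channel the centreline
#' velocity is then `1.5 * v_char`.  `v_char` is the characteristic velocity
#' entering the Reynolds number Re = rho v d / mu, so the four reference cases
#' v = 0.22, 0.44, 0.66, 0.88 m/s give Re of about 200, 400, 600 and 800.
#'
#' @param v_char Characteristic (mean) inlet velocity in m/s.
#' @param profile Only `"parabolic"` is supported.
#' @return An object of class `inlet_spec`.
#' @export
inlet_spec <- function(v_char = 0.22, profile = "parabolic") {
  if (!is.numeric(v_char) || v_char <= 0) stop("v_char must be > 0", call. = FALSE)
  profile <- match.arg(profile, "parabolic")
  structure(list(v_char = v_char, profile = profile), class = "inlet_spec")
}

#' Solver settings
#'
#' Controls for the SIMPLEC segregated solver.  The scaled-residual threshold
#' defaults to 1e-4; residuals are L1 norms normalised by their value at the
#' first outer iteration.  Relaxation defaults are 0.7 (momentum) / 0.3
#' (pressure); convection defaults to deferred-correction second-order upwind.
#'
#' @param residual_tol Scaled-residual convergence threshold (> 0).
#' @param max_outer Maximum number of outer (SIMPLEC) iterations.
#' @param relax_momentum Momentum under-relaxation factor in (0, 1].
#' @param relax_pressure Pressure under-relaxation factor in (0, 1].
#' @param convection_scheme `"second_order_upwind"` (default) or
#'   `"first_order_upwind"`.
#' @param n_sweeps Gauss-Seidel sweeps per momentum solve.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(residual_tol = 1e-4,
                            max_outer = 6000,
                            relax_momentum = 0.7,
                            relax_pressure = 0.3,
                            convection_scheme = c("second_order_upwind",
                                                  "first_order_upwind"),
                            n_sweeps = 4) {
  if (residual_tol <= 0) stop("residual_tol must be > 0", call. = FALSE)
  if (relax_momentum <= 0 || relax_momentum > 1 ||
      relax_pressure <= 0 || relax_pressure > 1)
    stop("relaxation factors must lie in (0, 1]", call. = FALSE)
  convection_scheme <- match.arg(convection_scheme)
  structure(list(residual_tol = residual_tol, max_outer = max_outer,
                 relax_momentum = relax_momentum,
                 relax_pressure = relax_pressure,
                 convection_scheme = convection_scheme,
                 n_sweeps = n_sweeps),
            class = "solver_settings")
}

#' Reynolds number
#'
#' Re = rho v d / mu with the characteristic (mean) velocity and the lumen
#' diameter.  With the default blood properties and d = 3 mm, v = 0.22 m/s
#' gives Re = 198.9 (the reference cases round this to 200).
#'
#' @param fluid A [fluid_properties()] object.
#' @param v_char Characteristic velocity in m/s (>= 0).
#' @param d Lumen diameter in m.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, v_char, d) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(v_char) || any(v_char < 0)) stop("v_char must be >= 0", call. = FALSE)
  if (!is.numeric(d) || any(d <= 0)) stop("d must be > 0", call. = FALSE)
  fluid$rho * v_char * d / fluid$mu
}

#' Characteristic velocity for a target Reynolds number
#'
#' Inverse of [reynolds_number()]: v = Re mu / (rho d).  Re = 200, 400, 600,
#' 800 with the default blood properties give 0.22, 0.44, 0.66, 0.88 m/s to
#' two decimals.
#'
#' @param fluid A [fluid_properties()] object.
#' @param Re Target Reynolds number (> 0).
#' @param d Lumen diameter in m.
#' @return Velocity in m/s.
#' @export
velocity_for_reynolds <- function(fluid, Re, d) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(Re) || any(Re <= 0)) stop("Re must be > 0", call. = FALSE)
  if (!is.numeric(d) || any(d <= 0)) stop("d must be > 0", call. = FALSE)
  Re * fluid$mu / (fluid$rho * d)
}

#' Solve steady incompressible flow in the stented channel
#'
#' Finite-volume SIMPLEC solution of the steady incompressible Navier-Stokes
#' equations on a [build_geometry()] mesh: parabolic inlet (mean `v_char`),
#' zero-pressure outlet, no-slip on the lumen walls and strut surfaces; wall
#' and strut cells are solid blockages with zero velocity.  The flow must be
#' laminar: an error is raised for Re > 2000.
#'
#' @param mesh A `stent_mesh`.
#' @param fluid A [fluid_properties()] object.
#' @param inlet An [inlet_spec()] object.
#' @param settings A [solver_settings()] object.
#' @return An object of class `flow_field` with cell matrices `u` (streamwise,
#'   m/s), `v` (transverse, m/s), `p` (Pa), conservative face fluxes `flux_e`
#'   and `flux_n` (m^2/s per unit depth), the scaled-residual history, and
#'   convergence metadata.
#' @export
solve_flow <- function(mesh, fluid = fluid_properties(),
                       inlet = inlet_spec(), settings = solver_settings()) {
  stopifnot(inherits(mesh, "stent_mesh"), inherits(fluid, "fluid_properties"),
            inherits(inlet, "inlet_spec"), inherits(settings, "solver_settings"))
  d <- mesh$geom$lumen_diameter
  Re <- reynolds_number(fluid, inlet$v_char, d)
  if (Re > 2000)
    stop(sprintf(
      "Re = %.0f exceeds the steady laminar range of the model (max 2000)", Re),
      call. = FALSE)

  r <- d / 2
  uin <- ifelse(abs(mesh$n_cent) < r,
                1.5 * inlet$v_char * (1 - (mesh$n_cent / r)^2), 0)
  uin[mesh$region[1, ] != REGION_LUMEN] <- 0

  scheme <- if (settings$convection_scheme == "second_order_upwind") 2L else 1L
  out <- simplec_solve(
    mesh$nx, mesh$ny, mesh$ds_c, mesh$curv, mesh$dn, mesh$n_cent,
    mesh$n_faces, as.integer(mesh$region), fluid$rho, fluid$mu, uin,
    settings$residual_tol, as.integer(settings$max_outer),
    settings$relax_momentum, settings$relax_pressure, scheme,
    as.integer(settings$n_sweeps))

  res <- out$residuals
  colnames(res) <- c("u_momentum", "v_momentum", "continuity")
  field <- structure(
    list(
      u = matrix(out$u, mesh$nx, mesh$ny),
      v = matrix(out$v, mesh$nx, mesh$ny),
      p = matrix(out$p, mesh$nx, mesh$ny),
      flux_e = matrix(out$flux_e, mesh$nx + 1, mesh$ny),
      flux_n = matrix(out$flux_n, mesh$nx, mesh$ny + 1),
      residuals = res,
      converged = out$converged,
      iterations = out$iterations,
      inlet_flux = out$inlet_flux,
      max_cell_imbalance = out$max_cell_imbalance,
      fluid = fluid, inlet = inlet, settings = settings,
      Re = Re
    ),
    class = "flow_field"
  )
  if (!out$converged) {
    cond <- structure(
      class = c("stentflow_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "flow solver did not reach residual %.1e in %d iterations (last: u %.2e, v %.2e, cont %.2e)",
        settings$residual_tol, out$iterations,
        res[nrow(res), 1], res[nrow(res), 2], res[nrow(res), 3]),
        call = sys.call(-1), field = field))
    stop(cond)
  }
  field
}

#' Zero flow field on a mesh
#'
#' Convenience constructor of a quiescent, trivially converged `flow_field`
#' (all velocities, pressures and fluxes zero).  Used for diffusion-only
#' transport studies such as the two-layer slab benchmark.
#'
#' @param mesh A `stent_mesh`.
#' @param fluid A [fluid_properties()] object (metadata only).
#' @return A `flow_field` with zero fields.
#' @export
zero_flow <- function(mesh, fluid = fluid_properties()) {
  structure(
    list(
      u = matrix(0, mesh$nx, mesh$ny), v = matrix(0, mesh$nx, mesh$ny),
      p = matrix(0, mesh$nx, mesh$ny),
      flux_e = matrix(0, mesh$nx + 1, mesh$ny),
      flux_n = matrix(0, mesh$nx, mesh$ny + 1),
      residuals = matrix(0, 0, 3), converged = TRUE, iterations = 0L,
      inlet_flux = 0, max_cell_imbalance = 0,
      fluid = fluid, inlet = NULL, settings = NULL, Re = 0
    ),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> Re =", formatC(x$Re, format = "g"),
      if (x$converged) "(converged" else "(NOT converged", "in",
      x$iterations, "iterations)\n")
  cat("  peak |u| =", formatC(max(abs(x$u)), format = "g"),
      "m/s; max cell mass imbalance =",
      formatC(x$max_cell_imbalance, format = "e", digits = 2), "m^2/s\n")
  invisible(x)
}
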