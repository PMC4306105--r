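#' Drug transport properties
#'
#' Isotropic drug diffusivities of the eluted compound: `kf` in flowing blood
#' (lumen) and `kt` in the vessel-wall tissue.  Defaults are the reference
#' values kf = 1e-7 m^2/s and kt = 1e-12 m^2/s; the five-orders-of-magnitude
#' contrast is what makes the wall a slow reservoir.
#'
#' @param kf Lumen (blood) diffusivity in m^2/s.
#' @param kt Tissue (wall) diffusivity in m^2/s.
#' @return An object of class `transport_properties`.
#' @export
transport_properties <- function(kf = 1e-7, kt = 1e-12) {
  if (!is.numeric(kf) || kf <= 0) stop("kf must be > 0", call. = FALSE)
  if (!is.numeric(kt) || kt <= 0) stop("kt must be > 0", call. = FALSE)
  if (kt > kf) stop("kf must be >= kt", call. = FALSE)
  structure(list(kf = kf, kt = kt), class = "transport_properties")
}

## Internal: assemble the steady advection-diffusion system for the
## dimensionless drug concentration on the full lumen+wall grid.
## Cells are unknowns; strut cells carry identity rows pinned to 1 (the
## Dirichlet drug-coating condition acts on every strut face, into the lumen
## and into the wall).  Convection is implicit first-order upwind on the
## conservative face fluxes of the flow solution; diffusion uses
## harmonic-mean face diffusivities, which reproduces the exact two-layer
## interface condition (flux continuity) on a finite-volume grid.
## Returns the sparse matrix, base RHS, and the face tables needed for the
## deferred second-order correction and the flux audit.
assemble_scalar <- function(mesh, flow, props) {
  nx <- mesh$nx; ny <- mesh$ny; N <- nx * ny
  region <- mesh$region
  S <- region == REGION_STRUT
  K <- matrix(ifelse(region == REGION_WALL, props$kt, props$kf), nx, ny)
  dsl <- matrix(mesh$ds_c, nx, ny) * (1 + outer(mesh$curv, mesh$n_cent))
  dnm <- matrix(mesh$dn, nx, ny, byrow = TRUE)
  cid <- function(i, j) i + (j - 1L) * nx

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  aP <- numeric(N); b <- numeric(N)
  add_off <- function(r, c, val) {
    ti <<- c(ti, r); tj <<- c(tj, c); tx <<- c(tx, -val)
  }

  faces <- list()

  ## ---- streamwise (east) interior faces ----
  if (nx > 1) {
    i <- rep(1:(nx - 1), ny); j <- rep(1:ny, each = nx - 1)
    P <- cid(i, j); E <- cid(i + 1L, j)
    A <- mesh$dn[j]
    dP <- dsl[P] / 2; dE <- dsl[E] / 2
    Fv <- flow$flux_e[cbind(i + 1L, j)]
    both <- !S[P] & !S[E]
    Dh <- (dP + dE) / (dP / K[P] + dE / K[E]) * A / (dP + dE)
    w <- which(both)
    aP[P[w]] <- aP[P[w]] + Dh[w] + pmax(Fv[w], 0)
    aP[E[w]] <- aP[E[w]] + Dh[w] + pmax(-Fv[w], 0)
    if (length(w)) {
      add_off(P[w], E[w], Dh[w] + pmax(-Fv[w], 0))
      add_off(E[w], P[w], Dh[w] + pmax(Fv[w], 0))
    }
    wPE <- which(!S[P] & S[E])                     # strut east of P
    Dd <- K[P] * A / dP
    aP[P[wPE]] <- aP[P[wPE]] + Dd[wPE]; b[P[wPE]] <- b[P[wPE]] + Dd[wPE]
    wEP <- which(S[P] & !S[E])                     # strut west of E
    Dd2 <- K[E] * A / dE
    aP[E[wEP]] <- aP[E[wEP]] + Dd2[wEP]; b[E[wEP]] <- b[E[wEP]] + Dd2[wEP]
    faces$ew <- list(i = i, j = j, P = P, E = E, F = Fv, both = both)
  }

  ## ---- transverse (north) interior faces ----
  if (ny > 1) {
    i <- rep(1:nx, ny - 1); j <- rep(1:(ny - 1), each = nx)
    P <- cid(i, j); E <- cid(i, j + 1L)
    A <- mesh$ds_c[i] * (1 + mesh$curv[i] * mesh$n_faces[j + 1L])
    dP <- dnm[P] / 2; dE <- dnm[E] / 2
    Fv <- flow$flux_n[cbind(i, j + 1L)]
    both <- !S[P] & !S[E]
    Dh <- (dP + dE) / (dP / K[P] + dE / K[E]) * A / (dP + dE)
    w <- which(both)
    aP[P[w]] <- aP[P[w]] + Dh[w] + pmax(Fv[w], 0)
    aP[E[w]] <- aP[E[w]] + Dh[w] + pmax(-Fv[w], 0)
    if (length(w)) {
      add_off(P[w], E[w], Dh[w] + pmax(-Fv[w], 0))
      add_off(E[w], P[w], Dh[w] + pmax(Fv[w], 0))
    }
    wPE <- which(!S[P] & S[E])
    Dd <- K[P] * A / dP
    aP[P[wPE]] <- aP[P[wPE]] + Dd[wPE]; b[P[wPE]] <- b[P[wPE]] + Dd[wPE]
    wEP <- which(S[P] & !S[E])
    Dd2 <- K[E] * A / dE
    aP[E[wEP]] <- aP[E[wEP]] + Dd2[wEP]; b[E[wEP]] <- b[E[wEP]] + Dd2[wEP]
    faces$ns <- list(i = i, j = j, P = P, E = E, F = Fv, both = both)
  }

  ## ---- inlet: Dirichlet 0 in the lumen, zero flux at the wall ends ----
  j <- 1:ny
  P <- cid(1L, j)
  lum <- region[cbind(1L, j)] == REGION_LUMEN
  Din <- props$kf * mesh$dn[j] / (dsl[P] / 2)
  aP[P[lum]] <- aP[P[lum]] + Din[lum]              # face value 0: no RHS term
  faces$inlet <- list(P = P[lum], D = Din[lum], F = flow$flux_e[cbind(1L, j)][lum])

  ## ---- outlet: advective outflow in the lumen, zero flux at wall ends ----
  P <- cid(nx, j)
  lum <- region[cbind(nx, j)] == REGION_LUMEN
  Fout <- flow$flux_e[cbind(nx + 1L, j)]
  aP[P[lum]] <- aP[P[lum]] + pmax(Fout[lum], 0)
  faces$outlet <- list(P = P[lum], F = Fout[lum])

  ## ---- strut cells: identity rows pinned to the coating value ----
  aP[S] <- 1; b[S] <- 1

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N, N)) +
    Matrix::Diagonal(N, aP)
  list(A = A, b = b, faces = faces, K = K, S = S, dsl = dsl, dnm = dnm)
}

## Internal: deferred-correction RHS for limited second-order upwind
## convection.  minmod-limited linear reconstruction at the upwind cell keeps
## the scheme bounded at high Peclet number.
sou_scalar_rhs <- function(mesh, sys, phi) {
  nx <- mesh$nx; ny <- mesh$ny
  bc <- numeric(nx * ny)
  dsl <- sys$dsl; dnm <- sys$dnm; S <- sys$S
  cid <- function(i, j) i + (j - 1L) * nx
  fe <- sys$faces$ew
  if (!is.null(fe) && nx > 3) {
    up_is_P <- fe$F >= 0
    iu <- ifelse(up_is_P, fe$i, fe$i + 1L)
    iuu <- ifelse(up_is_P, fe$i - 1L, fe$i + 2L)
    valid <- iuu >= 1L & iuu <= nx
    UU <- ifelse(valid, cid(pmax(pmin(iuu, nx), 1L), fe$j), NA_integer_)
    U <- ifelse(up_is_P, fe$P, fe$E)
    Dn_ <- ifelse(up_is_P, fe$E, fe$P)
    dUf <- dsl[U] / 2
    dUUU <- ifelse(valid, (dsl[U] + dsl[ifelse(is.na(UU), U, UU)]) / 2, 1)
    dUD <- (dsl[U] + dsl[Dn_]) / 2
    ok <- fe$both & valid & !S[ifelse(is.na(UU), 1L, UU)] & fe$F != 0
    slope_up <- (phi[U] - phi[ifelse(is.na(UU), U, UU)]) / dUUU
    slope_dn <- (phi[Dn_] - phi[U]) / dUD
    m <- ifelse(slope_up * slope_dn <= 0, 0,
                ifelse(abs(slope_up) < abs(slope_dn), slope_up, slope_dn))
    corr <- ifelse(ok, m * dUf, 0)
    ## convection term of P gains +F*(phi_f); deferred part moves to the RHS
    bc_add <- fe$F * corr
    bc <- bc - tab_accum(fe$P, bc_add, nx * ny)
    bc <- bc + tab_accum(fe$E, bc_add, nx * ny)
  }
  fn <- sys$faces$ns
  if (!is.null(fn) && ny > 3) {
    up_is_P <- fn$F >= 0
    ju <- ifelse(up_is_P, fn$j, fn$j + 1L)
    juu <- ifelse(up_is_P, fn$j - 1L, fn$j + 2L)
    valid <- juu >= 1L & juu <= ny
    UU <- ifelse(valid, cid(fn$i, pmax(pmin(juu, ny), 1L)), NA_integer_)
    U <- ifelse(up_is_P, fn$P, fn$E)
    Dn_ <- ifelse(up_is_P, fn$E, fn$P)
    dUf <- dnm[U] / 2
    dUUU <- ifelse(valid, (dnm[U] + dnm[ifelse(is.na(UU), U, UU)]) / 2, 1)
    dUD <- (dnm[U] + dnm[Dn_]) / 2
    ok <- fn$both & valid & !S[ifelse(is.na(UU), 1L, UU)] & fn$F != 0
    slope_up <- (phi[U] - phi[ifelse(is.na(UU), U, UU)]) / dUUU
    slope_dn <- (phi[Dn_] - phi[U]) / dUD
    m <- ifelse(slope_up * slope_dn <= 0, 0,
                ifelse(abs(slope_up) < abs(slope_dn), slope_up, slope_dn))
    corr <- ifelse(ok, m * dUf, 0)
    bc_add <- fn$F * corr
    bc <- bc - tab_accum(fn$P, bc_add, nx * ny)
    bc <- bc + tab_accum(fn$E, bc_add, nx * ny)
  }
  bc
}

## Internal: scatter-add `val` into a length-n vector at (possibly repeated)
## integer positions.
tab_accum <- function(idx, val, n) {
  out <- numeric(n)
  w <- val != 0
  if (any(w)) {
    agg <- rowsum(val[w], idx[w])
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Solve the steady drug-transport problem
#'
#' Conjugate advection-diffusion of the dimensionless drug concentration:
#' convection plus diffusion (`kf`) in the lumen, pure diffusion (`kt`) in the
#' vessel wall, with zero concentration at the inlet, zero streamwise gradient
#' at the outlet, zero flux at the perivascular surface and at the
#' upstream/downstream wall ends, diffusive-flux and concentration continuity
#' across the lumen-wall interface (harmonic-mean face diffusivity), and unit
#' concentration on every strut surface.
#'
#' The linear system is solved by direct sparse LU factorisation; with
#' second-order upwind convection the factor is reused across the
#' deferred-correction passes.
#'
#' @param mesh A `stent_mesh`.
#' @param flow A converged [solve_flow()] field on the same mesh (or
#'   [zero_flow()] for diffusion-only problems).
#' @param props A [transport_properties()] object.
#' @param settings A [solver_settings()]; only `convection_scheme` is used.
#' @return An object of class `concentration_field` with the cell matrix
#'   `conc` (phi_f on lumen cells, phi_t on wall cells, 1 on strut cells).
#' @export
solve_drug <- function(mesh, flow, props = transport_properties(),
                       settings = solver_settings()) {
  stopifnot(inherits(mesh, "stent_mesh"), inherits(flow, "flow_field"),
            inherits(props, "transport_properties"))
  if (!isTRUE(flow$converged))
    stop("flow field is not converged; solve_drug requires a converged flow",
         call. = FALSE)
  if (!identical(dim(flow$u), c(mesh$nx, mesh$ny)))
    stop("flow field does not match the mesh", call. = FALSE)

  sys <- assemble_scalar(mesh, flow, props)
  lu <- Matrix::lu(sys$A)
  phi <- as.numeric(Matrix::solve(lu, sys$b))
  passes <- 1L
  change <- 0
  if (settings$convection_scheme == "second_order_upwind") {
    for (k in 1:30) {
      bc <- sou_scalar_rhs(mesh, sys, phi)
      phi_new <- as.numeric(Matrix::solve(lu, sys$b + bc))
      change <- max(abs(phi_new - phi))
      phi <- phi_new
      passes <- passes + 1L
      if (change < 1e-6) break
    }
  }
  structure(
    list(conc = matrix(phi, mesh$nx, mesh$ny), props = props,
         scheme = settings$convection_scheme,
         passes = passes, final_change = change),
    class = "concentration_field"
  )
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("<concentration_field> range [",
      formatC(min(x$conc), format = "g"), ",",
      formatC(max(x$conc), format = "g"), "],", x$scheme,
      "(", x$passes, "passes )\n")
  invisible(x)
}

#' Integrated drug-flux balance audit
#'
#' Integrates the drug fluxes of a converged solution: released from the strut
#' surfaces, advected out of the lumen outlet, diffused back out of the inlet,
#' net flux across the lumen-wall interface, and the net flux into the wall
#' (zero at steady state, since the wall's other boundaries are impermeable).
#' The conservation residual |release - outlet - inlet leak| / release is the
#' figure of merit; for a converged steady solution it is at the level of the
#' linear-solver and flow-continuity tolerances.
#'
#' @param field A [solve_drug()] result.
#' @param mesh The `stent_mesh` it was computed on.
#' @param flow The `flow_field` it was computed with.
#' @param props The [transport_properties()] used.
#' @return A list of class `drug_flux_balance` with components
#'   `strut_release`, `outlet_advection`, `inlet_diffusion`,
#'   `interface_to_wall`, `strut_to_wall`, `wall_net` and `residual`
#'   (dimensionless fractions of the release; fluxes in m^2/s per unit depth
#'   times concentration).
#' @export
drug_flux_balance <- function(field, mesh, flow, props = field$props) {
  stopifnot(inherits(field, "concentration_field"))
  nx <- mesh$nx; ny <- mesh$ny
  phi <- field$conc
  region <- mesh$region
  S <- region == REGION_STRUT
  K <- matrix(ifelse(region == REGION_WALL, props$kt, props$kf), nx, ny)
  dsl <- matrix(mesh$ds_c, nx, ny) * (1 + outer(mesh$curv, mesh$n_cent))
  dnm <- matrix(mesh$dn, nx, ny, byrow = TRUE)

  strut_release <- 0; strut_to_wall <- 0
  interface_to_wall <- 0
  ## streamwise faces
  for (i in 1:(nx - 1)) {
    for (j in 1:ny) {
      sP <- S[i, j]; sE <- S[i + 1, j]
      if (sP == sE) next
      A <- mesh$dn[j]
      if (!sP) {                                   # strut east of (i,j)
        D <- K[i, j] * A / (dsl[i, j] / 2)
        q <- D * (1 - phi[i, j])
      } else {
        D <- K[i + 1, j] * A / (dsl[i + 1, j] / 2)
        q <- D * (1 - phi[i + 1, j])
      }
      strut_release <- strut_release + q
      if ((!sP && region[i, j] == REGION_WALL) ||
          (sP && region[i + 1, j] == REGION_WALL))
        strut_to_wall <- strut_to_wall + q
    }
  }
  ## transverse faces
  for (j in 1:(ny - 1)) {
    for (i in 1:nx) {
      sP <- S[i, j]; sE <- S[i, j + 1]
      A <- mesh$ds_c[i] * (1 + mesh$curv[i] * mesh$n_faces[j + 1])
      if (xor(sP, sE)) {
        if (!sP) {
          D <- K[i, j] * A / (dnm[i, j] / 2)
          q <- D * (1 - phi[i, j])
          into_wall <- region[i, j] == REGION_WALL
        } else {
          D <- K[i, j + 1] * A / (dnm[i, j + 1] / 2)
          q <- D * (1 - phi[i, j + 1])
          into_wall <- region[i, j + 1] == REGION_WALL
        }
        strut_release <- strut_release + q
        if (into_wall) strut_to_wall <- strut_to_wall + q
      } else if (!sP && !sE &&
                 xor(region[i, j] == REGION_WALL,
                     region[i, j + 1] == REGION_WALL)) {
        dP <- dnm[i, j] / 2; dE <- dnm[i, j + 1] / 2
        Dh <- (dP + dE) / (dP / K[i, j] + dE / K[i, j + 1]) * A / (dP + dE)
        q <- Dh * (phi[i, j] - phi[i, j + 1])      # positive toward +n
        if (region[i, j + 1] == REGION_WALL) interface_to_wall <- interface_to_wall + q
        else interface_to_wall <- interface_to_wall - q
      }
    }
  }
  ## outlet advection and inlet diffusive leak (lumen only)
  outlet_advection <- 0; inlet_diffusion <- 0
  for (j in 1:ny) {
    if (region[nx, j] == REGION_LUMEN)
      outlet_advection <- outlet_advection +
        max(flow$flux_e[nx + 1, j], 0) * phi[nx, j]
    if (region[1, j] == REGION_LUMEN)
      inlet_diffusion <- inlet_diffusion +
        props$kf * mesh$dn[j] / (dsl[1, j] / 2) * phi[1, j]
  }
  wall_net <- strut_to_wall + interface_to_wall
  residual <- if (strut_release > 0)
    abs(strut_release - outlet_advection - inlet_diffusion) / strut_release
  else abs(outlet_advection) + abs(inlet_diffusion)
  structure(list(strut_release = strut_release,
                 outlet_advection = outlet_advection,
                 inlet_diffusion = inlet_diffusion,
                 interface_to_wall = interface_to_wall,
                 strut_to_wall = strut_to_wall,
                 wall_net = wall_net,
                 residual = residual),
            class = "drug_flux_balance")
}

#' @export
print.drug_flux_balance <- function(x, ...) {
  cat("<drug_flux_balance>\n")
  cat("  strut release     :", formatC(x$strut_release, format = "e"), "\n")
  cat("  outlet advection  :", formatC(x$outlet_advection, format = "e"), "\n")
  cat("  inlet diffusion   :", formatC(x$inlet_diffusion, format = "e"), "\n")
  cat("  net into wall     :", formatC(x$wall_net, format = "e"), "\n")
  cat("  residual fraction :", formatC(x$residual, format = "e"), "\n")
  invisible(x)
}
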