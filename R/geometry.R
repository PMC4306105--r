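#' Parameterised stented curved-vessel geometry
#'
#' Describes the bend-plane reduction of a stented curved artery: a channel of
#' width `lumen_diameter` bounded by two vessel-wall layers of thickness
#' `wall_thickness`, following a circular arc of radius `bend_radius` over
#' `bend_angle` degrees, with straight extensions of `extension_length` at the
#' inlet and outlet.  `n_struts` square stent struts of side `strut_size` sit on
#' each lumen--wall interface, equally spaced along the stented arc of length
#' `stent_length` centred on the bend.
#'
#' All lengths are in metres.  The defaults are the reference coronary case:
#' a 3 mm lumen on a 10 mm-radius 90 degree bend, 0.5 mm wall, six
#' 0.10 x 0.10 mm struts over a 15 mm stented segment, and 30 mm straight
#' inlet/outlet tubes so the flow arrives fully developed.
#'
#' @param lumen_diameter Channel (lumen) width d in m.
#' @param bend_radius Radius of curvature R of the centreline in m.
#' @param bend_angle Bend angle in degrees, in `[0, 180]`; 0 gives a straight
#'   channel.
#' @param wall_thickness Thickness of each vessel-wall layer in m.
#' @param stent_length Arc length of the stented segment in m (measured along
#'   the centreline).
#' @param n_struts Number of struts per wall side.
#' @param strut_size Side of the square strut cross-section in m.
#' @param extension_length Length of each straight extension in m.
#' @return An object of class `stent_geometry`.
#' @examples
#' geom <- stent_geometry()
#' geom
#' @export
stent_geometry <- function(lumen_diameter = 3e-3,
                           bend_radius = 10e-3,
                           bend_angle = 90,
                           wall_thickness = 0.5e-3,
                           stent_length = 15e-3,
                           n_struts = 6,
                           strut_size = 0.1e-3,
                           extension_length = 30e-3) {
  g <- structure(
    list(
      lumen_diameter = lumen_diameter,
      bend_radius = bend_radius,
      bend_angle = bend_angle,
      wall_thickness = wall_thickness,
      stent_length = stent_length,
      n_struts = n_struts,
      strut_size = strut_size,
      extension_length = extension_length
    ),
    class = "stent_geometry"
  )
  validate_geometry(g)
  g
}

#' Validate a stent geometry
#'
#' Checks the geometric invariants: positive lengths, bend radius larger than
#' the lumen radius, bend angle in `[0, 180]` degrees, struts smaller than the
#' lumen half-width, struts fitting along the stented segment without overlap,
#' and the stented segment fitting inside the bend.
#'
#' @param geom A [stent_geometry()] object.
#' @return `geom`, invisibly; throws an error describing the violated
#'   invariant otherwise.
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "stent_geometry"))
  with(geom, {
    if (!is.numeric(lumen_diameter) || lumen_diameter <= 0)
      stop("lumen_diameter must be > 0", call. = FALSE)
    if (bend_radius <= lumen_diameter / 2)
      stop("bend_radius must exceed the lumen radius (R > d/2)", call. = FALSE)
    if (bend_angle < 0 || bend_angle > 180)
      stop("bend_angle must lie in [0, 180] degrees", call. = FALSE)
    if (wall_thickness <= 0)
      stop("wall_thickness must be > 0", call. = FALSE)
    if (strut_size >= lumen_diameter / 2)
      stop("strut_size must be smaller than the lumen half-width", call. = FALSE)
    if (n_struts < 0 || n_struts != round(n_struts))
      stop("n_struts must be a non-negative integer", call. = FALSE)
    if (n_struts * strut_size > stent_length)
      stop("struts do not fit along the stented segment ",
           "(n_struts * strut_size > stent_length)", call. = FALSE)
    if (extension_length < 0)
      stop("extension_length must be >= 0", call. = FALSE)
    L_centre <- if (bend_angle > 0) bend_radius * bend_angle * pi / 180
                else stent_length
    if (stent_length > L_centre + 1e-12)
      stop("stented segment is longer than the bend arc", call. = FALSE)
  })
  invisible(geom)
}

#' @export
print.stent_geometry <- function(x, ...) {
  mm <- function(v) formatC(v * 1e3, format = "g")
  cat("<stent_geometry>\n")
  cat("  lumen diameter   :", mm(x$lumen_diameter), "mm\n")
  cat("  bend radius      :", mm(x$bend_radius), "mm  (angle",
      x$bend_angle, "deg)\n")
  cat("  wall thickness   :", mm(x$wall_thickness), "mm\n")
  cat("  stented segment  :", mm(x$stent_length), "mm,", x$n_struts,
      "struts of", mm(x$strut_size), "mm per side\n")
  cat("  extensions       :", mm(x$extension_length), "mm each\n")
  invisible(x)
}

## Region flag codes used throughout the package.
REGION_LUMEN <- 0L
REGION_WALL  <- 1L
REGION_STRUT <- 2L

## Geometric sizes for a graded streamwise extension: start at ds0 next to the
## bend, grow geometrically (ratio `g`) up to ds_max, then pad with constant
## cells; the whole set is rescaled so the lengths sum exactly to L.
grade_extension <- function(L, ds0, g = 1.2, ds_max = 1e-3) {
  if (L <= 0) return(numeric(0))
  sizes <- numeric(0)
  ds <- ds0
  while (sum(sizes) < L) {
    sizes <- c(sizes, ds)
    ds <- min(ds * g, ds_max)
  }
  sizes * (L / sum(sizes))
}

#' Build the structured curvilinear mesh of a stented curved channel
#'
#' Meshes the bend-plane domain with a structured grid: polar cells inside the
#' bend (streamwise faces are radial lines), Cartesian cells in the straight
#' extensions.  The transverse coordinate n runs from the inner-bend
#' perivascular surface (`-d/2 - t`) to the outer-bend one (`+d/2 + t`), with
#' n > 0 toward the outer bend; the streamwise station s is the centreline arc
#' length from the inlet.  Cells carry a region flag (lumen, wall or strut);
#' strut cells are blocked rectangles of side `strut_size` protruding from each
#' lumen--wall interface into the lumen.
#'
#' The transverse spacing is uniform (`1/resolution`) in the lumen; each wall
#' layer is meshed with at least 8 cells.  The streamwise spacing equals the
#' transverse one through the bend/stented segment and is geometrically graded
#' up to 1 mm in the extensions.
#'
#' @param geom A [stent_geometry()] object.
#' @param resolution Target resolution in cells per mm (default 20).  Must be
#'   at least 10 so a 0.1 mm strut spans a whole cell.
#' @return An object of class `stent_mesh`; see Details.
#' @details The returned list contains, among others: `nx`, `ny` (cells),
#'   `region` (`nx` x `ny` integer matrix, 0 = lumen, 1 = wall, 2 = strut),
#'   `s_cent`/`s_faces` (streamwise stations, m), `n_cent`/`n_faces`
#'   (transverse stations, m), `ds_c` (centreline cell lengths), `dn` (per-row
#'   transverse spacings), `curv` (per-column centreline curvature, 1/m; 0 in
#'   the extensions), `vol` (cell areas per unit depth, m^2), `stent_s`
#'   (streamwise extent of the stented segment) and `struts` (a data.frame of
#'   strut footprints).
#' @examples
#' mesh <- build_geometry(stent_geometry(), resolution = 10)
#' mesh
#' @export
build_geometry <- function(geom, resolution = 20) {
  validate_geometry(geom)
  res_min <- if (geom$n_struts > 0) max(10, ceiling(1e-3 / geom$strut_size)) else 10
  if (resolution < res_min)
    stop(sprintf(
      "resolution %g cells/mm too coarse to resolve the geometry; minimum is %d cells/mm",
      resolution, res_min), call. = FALSE)

  d <- geom$lumen_diameter
  t_w <- geom$wall_thickness
  h <- 1e-3 / resolution                       # nominal cell size (m)

  ## --- transverse grid: wall | lumen | wall ---------------------------------
  n_lum <- max(2L, round(d / h))
  dn_l <- d / n_lum
  n_wall <- max(8L, round(t_w / h))
  dn_w <- t_w / n_wall
  n_faces <- c(-d / 2 - t_w + dn_w * (0:n_wall),
               -d / 2 + dn_l * (1:n_lum),
               d / 2 + dn_w * (1:n_wall))
  ny <- length(n_faces) - 1L
  n_cent <- (n_faces[-1] + n_faces[-length(n_faces)]) / 2
  dn <- diff(n_faces)

  ## --- streamwise grid: extension | bend (or straight core) | extension ----
  L_centre <- if (geom$bend_angle > 0) {
    geom$bend_radius * geom$bend_angle * pi / 180
  } else {
    geom$stent_length
  }
  nc <- max(1L, round(L_centre / h))
  ds_core <- rep(L_centre / nc, nc)
  ds_in <- rev(grade_extension(geom$extension_length, L_centre / nc))
  ds_out <- grade_extension(geom$extension_length, L_centre / nc)
  ds_c <- c(ds_in, ds_core, ds_out)
  nx <- length(ds_c)
  s_faces <- c(0, cumsum(ds_c))
  s_cent <- (s_faces[-1] + s_faces[-length(s_faces)]) / 2
  bend_s <- c(geom$extension_length, geom$extension_length + L_centre)
  curv <- ifelse(s_cent > bend_s[1] & s_cent < bend_s[2] & geom$bend_angle > 0,
                 1 / geom$bend_radius, 0)

  ## --- region flags ---------------------------------------------------------
  region <- matrix(REGION_LUMEN, nx, ny)
  region[, abs(n_cent) > d / 2] <- REGION_WALL

  stent_s <- bend_s[1] + (L_centre - geom$stent_length) / 2 +
    c(0, geom$stent_length)
  struts <- NULL
  if (geom$n_struts > 0) {
    w <- geom$strut_size
    centres <- stent_s[1] +
      (seq_len(geom$n_struts) - 0.5) * geom$stent_length / geom$n_struts
    struts <- do.call(rbind, lapply(centres, function(sc) {
      data.frame(s0 = sc - w / 2, s1 = sc + w / 2,
                 side = c("inner_bend", "outer_bend"),
                 n0 = c(-d / 2, d / 2 - w), n1 = c(-d / 2 + w, d / 2),
                 stringsAsFactors = FALSE)
    }))
    for (k in seq_len(nrow(struts))) {
      ii <- which(s_cent >= struts$s0[k] & s_cent < struts$s1[k])
      jj <- which(n_cent > struts$n0[k] & n_cent < struts$n1[k] &
                    abs(n_cent) < d / 2)
      region[ii, jj] <- REGION_STRUT
    }
  }

  vol <- outer(ds_c, seq_len(ny), function(ds, j) ds) *
    (1 + outer(curv, n_cent)) * rep(dn, each = nx)

  structure(
    list(
      geom = geom, resolution = resolution,
      nx = nx, ny = ny,
      ds_c = ds_c, s_faces = s_faces, s_cent = s_cent, curv = curv,
      dn = dn, n_faces = n_faces, n_cent = n_cent,
      region = region, vol = vol,
      bend_s = bend_s, stent_s = stent_s, struts = struts,
      n_lumen = n_lum, n_wall = n_wall
    ),
    class = "stent_mesh"
  )
}

#' @export
print.stent_mesh <- function(x, ...) {
  cat("<stent_mesh>", x$nx, "x", x$ny, "cells (",
      sum(x$region == REGION_LUMEN), "lumen /", sum(x$region == REGION_WALL),
      "wall /", sum(x$region == REGION_STRUT), "strut )\n")
  cat("  streamwise extent:", formatC(max(x$s_faces) * 1e3), "mm; stented:",
      formatC(x$stent_s[1] * 1e3), "-", formatC(x$stent_s[2] * 1e3), "mm\n")
  cat("  resolution:", x$resolution, "cells/mm\n")
  invisible(x)
}

#' Analytic area of the meshed domain
#'
#' Closed-form planar area (per unit depth) of the channel plus wall layers:
#' the bend contributes an annular-sector area equal to the centreline arc
#' length times the total width (the transverse grid is symmetric about the
#' centreline), and each straight piece a rectangle.
#'
#' @param geom A [stent_geometry()].
#' @return Area in m^2 (per unit depth).
#' @export
analytic_domain_area <- function(geom) {
  width <- geom$lumen_diameter + 2 * geom$wall_thickness
  L_centre <- if (geom$bend_angle > 0)
    geom$bend_radius * geom$bend_angle * pi / 180 else geom$stent_length
  (L_centre + 2 * geom$extension_length) * width
}

#' Canonical test geometries
#'
#' Returns the canonical fixtures used throughout the verification suite:
#' \describe{
#'   \item{`reference_default`}{the full reference geometry (3 mm lumen, 10 mm
#'     bend radius, 90 degrees, six struts).}
#'   \item{`straight_channel`}{the same channel with no bend and no struts
#'     (plane-Poiseuille benchmark).}
#'   \item{`bare_bend`}{the curved channel with no struts (fully developed
#'     curved-channel benchmark).}
#'   \item{`slab_1d`}{a single-row, two-layer slab: a lumen layer followed by
#'     a wall layer with the strut at the far end (closed-form two-layer
#'     diffusion benchmark).}
#' }
#'
#' @param name One of `"reference_default"`, `"straight_channel"`, `"bare_bend"`,
#'   `"slab_1d"`.
#' @param resolution Cells per mm passed to [build_geometry()].
#' @param ... Geometry fields overriding the fixture defaults (e.g.
#'   `bend_angle = 180` for a longer benchmark bend).
#' @return A list with elements `geometry` and `mesh`.
#' @examples
#' fx <- make_fixture("straight_channel", resolution = 10)
#' fx$mesh
#' @export
make_fixture <- function(name, resolution = 20, ...) {
  valid <- c("reference_default", "straight_channel", "bare_bend", "slab_1d")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    stop("unknown fixture; valid names are: ", paste(valid, collapse = ", "),
         call. = FALSE)
  over <- list(...)
  mk <- function(defaults) {
    args <- utils::modifyList(defaults, over)
    do.call(stent_geometry, args)
  }
  if (name == "reference_default") {
    geom <- mk(list())
    return(list(geometry = geom, mesh = build_geometry(geom, resolution)))
  }
  if (name == "straight_channel") {
    geom <- mk(list(bend_angle = 0, n_struts = 0))
    return(list(geometry = geom, mesh = build_geometry(geom, resolution)))
  }
  if (name == "bare_bend") {
    geom <- mk(list(n_struts = 0))
    return(list(geometry = geom, mesh = build_geometry(geom, resolution)))
  }
  ## slab_1d: one transverse row; streamwise axis plays the role of the
  ## layer-normal coordinate.  Lumen layer of length d, wall layer of
  ## thickness t, strut (drug coating, Dirichlet phi = 1) occupying the last
  ## strut_size of the wall so the two layers sit in series between the
  ## zero-concentration lumen face and the unit-concentration strut face.
  geom <- mk(list(bend_angle = 0, n_struts = 0, extension_length = 0))
  h <- 1e-3 / resolution
  d <- geom$lumen_diameter; t_w <- geom$wall_thickness; w <- geom$strut_size
  nf <- max(4L, round(d / h)); nt <- max(8L, round(t_w / h))
  ds_c <- c(rep(d / nf, nf), rep(t_w / nt, nt))
  nx <- length(ds_c)
  s_faces <- c(0, cumsum(ds_c))
  s_cent <- (s_faces[-1] + s_faces[-(nx + 1)]) / 2
  region <- matrix(ifelse(s_cent <= d, REGION_LUMEN, REGION_WALL), nx, 1)
  region[s_cent > d + t_w - w, 1] <- REGION_STRUT
  dn <- h
  mesh <- structure(
    list(
      geom = geom, resolution = resolution, nx = nx, ny = 1L,
      ds_c = ds_c, s_faces = s_faces, s_cent = s_cent,
      curv = rep(0, nx), dn = dn, n_faces = c(-dn / 2, dn / 2), n_cent = 0,
      region = region, vol = matrix(ds_c * dn, nx, 1),
      bend_s = c(0, 0), stent_s = c(0, d + t_w), struts = NULL,
      n_lumen = 1L, n_wall = 0L, slab = TRUE
    ),
    class = "stent_mesh"
  )
  list(geometry = geom, mesh = mesh)
}

#' Physical node coordinates of a mesh
#'
#' Maps the (s, n) grid to bend-plane x/y coordinates: the inlet extension runs
#' along +x from the origin, the bend turns counter-clockwise about a centre at
#' distance R to the left of the centreline, and the outlet extension continues
#' straight.  Used for VTK export and plotting.
#'
#' @param mesh A `stent_mesh`.
#' @return A list with `(nx+1) x (ny+1)` matrices `x` and `y` in m.
#' @export
mesh_nodes <- function(mesh) {
  g <- mesh$geom
  sf <- mesh$s_faces; nf <- mesh$n_faces
  ang <- g$bend_angle * pi / 180
  s0 <- mesh$bend_s[1]; s1 <- mesh$bend_s[2]
  R <- g$bend_radius
  ## centreline point and unit tangent/normal (normal points toward outer bend)
  centreline <- function(s) {
    if (g$bend_angle <= 0 || s <= s0) {
      list(x = s, y = 0, tx = 1, ty = 0, nx = 0, ny = -1)
    } else if (s <= s1) {
      th <- (s - s0) / R
      list(x = s0 + R * sin(th), y = R * (1 - cos(th)),
           tx = cos(th), ty = sin(th), nx = sin(th), ny = -cos(th))
    } else {
      th <- ang
      ds <- s - s1
      list(x = s0 + R * sin(th) + ds * cos(th),
           y = R * (1 - cos(th)) + ds * sin(th),
           tx = cos(th), ty = sin(th), nx = sin(th), ny = -cos(th))
    }
  }
  X <- matrix(0, length(sf), length(nf)); Y <- X
  for (i in seq_along(sf)) {
    c0 <- centreline(sf[i])
    X[i, ] <- c0$x + nf * c0$nx
    Y[i, ] <- c0$y + nf * c0$ny
  }
  list(x = X, y = Y)
}
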