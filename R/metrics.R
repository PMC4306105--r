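#' Wall shear stress along the lumen surfaces
#'
#' Computes the wall shear stress tau = mu du/dn at the lumen-facing surface on
#' both sides of the channel, for every streamwise station.  The derivative is
#' one-sided second-order, built from the first two fluid cells off the
#' surface with the no-slip value at the surface itself.  Where a strut blocks
#' the near-wall cells the surface is the strut's lumen-facing face, so the
#' profile covers the full stented extent including the strut tops (strut side
#' faces are not sampled).
#'
#' @param flow A converged `flow_field` from [solve_flow()].
#' @param mesh The `stent_mesh` the flow was solved on.
#' @return An object of class `wss_profile`: a list with `s` (streamwise
#'   stations, m), `inner` / `outer` (WSS magnitude, Pa), `arc_inner` /
#'   `arc_outer` (surface arc length attached to each station, m),
#'   `on_strut_inner` / `on_strut_outer` (logical), and the mesh extents.
#' @export
compute_wss <- function(flow, mesh) {
  stopifnot(inherits(flow, "flow_field"), inherits(mesh, "stent_mesh"))
  d <- mesh$geom$lumen_diameter
  mu <- flow$fluid$mu
  lum <- which(abs(mesh$n_cent) < d / 2)
  one_side <- function(i, jorder, face_of) {
    ok <- mesh$region[i, jorder] != REGION_STRUT
    js <- jorder[ok]
    j1 <- js[1]; j2 <- js[2]
    n_surf <- face_of(j1)
    d1 <- abs(n_surf - mesh$n_cent[j1])
    d2 <- abs(n_surf - mesh$n_cent[j2])
    u1 <- flow$u[i, j1]; u2 <- flow$u[i, j2]
    dudn <- (u1 * d2^2 - u2 * d1^2) / (d1 * d2 * (d2 - d1))
    c(mu * abs(dudn), n_surf, !ok[1])
  }
  nx <- mesh$nx
  inner <- outer_ <- numeric(nx)
  n_in <- n_out <- numeric(nx)
  st_in <- st_out <- logical(nx)
  j_in <- lum[order(mesh$n_cent[lum])]               # innermost first
  j_out <- rev(j_in)
  for (i in seq_len(nx)) {
    a <- one_side(i, j_in, function(j) mesh$n_faces[j])
    b <- one_side(i, j_out, function(j) mesh$n_faces[j + 1L])
    inner[i] <- a[1]; n_in[i] <- a[2]; st_in[i] <- a[3] > 0
    outer_[i] <- b[1]; n_out[i] <- b[2]; st_out[i] <- b[3] > 0
  }
  structure(
    list(s = mesh$s_cent,
         inner = inner, outer = outer_,
         arc_inner = mesh$ds_c * (1 + mesh$curv * n_in),
         arc_outer = mesh$ds_c * (1 + mesh$curv * n_out),
         on_strut_inner = st_in, on_strut_outer = st_out,
         stent_s = mesh$stent_s, bend_s = mesh$bend_s),
    class = "wss_profile"
  )
}

#' Fraction of wall surface below a WSS threshold
#'
#' Arc-length-weighted fraction of the lumen surface whose wall shear stress
#' falls below `threshold` (default 0.5 Pa, a standard low-WSS cutoff for
#' restenosis risk).  Both sides are pooled for the total; per-side fractions
#' are also reported.  By default only the stented extent is assessed;
#' `extent = "full"` uses the whole channel.
#'
#' @param wss A [compute_wss()] result.
#' @param threshold Low-WSS cutoff in Pa.
#' @param extent `"stented"` (default) or `"full"`.
#' @return A list with `total`, `inner`, `outer` fractions in `[0, 1]`, plus
#'   the threshold and the assessed arc length per side.
#' @export
low_wss_fraction <- function(wss, threshold = 0.5,
                             extent = c("stented", "full")) {
  stopifnot(inherits(wss, "wss_profile"))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  extent <- match.arg(extent)
  sel <- if (extent == "stented") {
    wss$s > wss$stent_s[1] & wss$s < wss$stent_s[2]
  } else rep(TRUE, length(wss$s))
  frac <- function(v, a) sum(a[sel] * (v[sel] < threshold)) / sum(a[sel])
  li <- sum(wss$arc_inner[sel]); lo <- sum(wss$arc_outer[sel])
  tot <- (sum(wss$arc_inner[sel] * (wss$inner[sel] < threshold)) +
          sum(wss$arc_outer[sel] * (wss$outer[sel] < threshold))) / (li + lo)
  list(total = tot,
       inner = frac(wss$inner, wss$arc_inner),
       outer = frac(wss$outer, wss$arc_outer),
       threshold = threshold, extent = extent,
       arc_inner = li, arc_outer = lo)
}

#' Reference sampling lines for near-wall concentration
#'
#' Transverse positions of the four monitoring lines used throughout the
#' analysis: Line A runs `offset` into the lumen from each lumen--wall
#' interface, Line B runs `offset` into the wall.  With the default 3 mm lumen
#' and 0.25 mm offset: A at n = -/+ 1.25 mm, B at n = -/+ 1.75 mm.
#'
#' @param mesh A `stent_mesh`.
#' @param offset Distance from the lumen--wall interface in m.
#' @return Named numeric vector `A_inner`, `A_outer`, `B_inner`, `B_outer`
#'   (transverse coordinates, m).
#' @export
reference_lines <- function(mesh, offset = 0.25e-3) {
  stopifnot(inherits(mesh, "stent_mesh"))
  r <- mesh$geom$lumen_diameter / 2
  if (offset <= 0 || offset >= r || offset >= mesh$geom$wall_thickness)
    stop("offset must fit inside both the lumen and the wall layer",
         call. = FALSE)
  c(A_inner = -(r - offset), A_outer = r - offset,
    B_inner = -(r + offset), B_outer = r + offset)
}

#' Sample a cell field along a streamwise line
#'
#' Linearly interpolates a cell-centred field (e.g. drug concentration) in the
#' transverse direction at a fixed transverse position `n`, for every
#' streamwise station inside `s_range` (default: the stented extent).
#'
#' @param field An `nx x ny` matrix of cell values, or an object carrying one
#'   (`concentration_field` uses `$conc`, `flow_field` uses `$u`).
#' @param mesh The `stent_mesh` the field lives on.
#' @param n Transverse position in m (within the meshed band).
#' @param s_range Length-2 streamwise window in m, or `NULL` for the whole
#'   channel.
#' @return A data.frame with columns `s` (m) and `value`.
#' @export
line_profile <- function(field, mesh, n, s_range = mesh$stent_s) {
  stopifnot(inherits(mesh, "stent_mesh"))
  m <- if (is.matrix(field)) field
       else if (inherits(field, "concentration_field")) field$conc
       else if (inherits(field, "flow_field")) field$u
       else stop("field must be a matrix, concentration_field or flow_field",
                 call. = FALSE)
  nc <- mesh$n_cent
  if (n < nc[1] || n > nc[length(nc)])
    stop("line position lies outside the cell-centre band", call. = FALSE)
  j <- findInterval(n, nc)
  j <- min(max(j, 1L), length(nc) - 1L)
  wgt <- (n - nc[j]) / (nc[j + 1] - nc[j])
  value <- (1 - wgt) * m[, j] + wgt * m[, j + 1]
  sel <- if (is.null(s_range)) rep(TRUE, mesh$nx)
         else mesh$s_cent > s_range[1] & mesh$s_cent < s_range[2]
  data.frame(s = mesh$s_cent[sel], value = value[sel])
}

#' Segment statistics of a streamwise profile
#'
#' Splits the streamwise window into three equal segments (proximal, middle,
#' distal) and reports the mean and peak of the profile in each.
#'
#' @param profile A data.frame with columns `s` and `value` (as returned by
#'   [line_profile()]), or any object coercible to one.
#' @param s_range Length-2 window defining the segments; defaults to the range
#'   of `profile$s`.
#' @return A data.frame with columns `segment`, `mean`, `peak`, `n`.
#' @export
segment_stats <- function(profile, s_range = range(profile$s)) {
  profile <- as.data.frame(profile)
  stopifnot(all(c("s", "value") %in% names(profile)))
  edges <- seq(s_range[1], s_range[2], length.out = 4)
  seg <- cut(profile$s, edges, include.lowest = TRUE,
             labels = c("proximal", "middle", "distal"))
  out <- do.call(rbind, lapply(levels(seg), function(lv) {
    v <- profile$value[seg == lv]
    data.frame(segment = lv,
               mean = if (length(v)) mean(v) else NA_real_,
               peak = if (length(v)) max(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  out
}

#' Inner-/outer-bend concentration asymmetry
#'
#' Summarises the drug concentration along the four reference lines (see
#' [reference_lines()]) over the stented extent: per-line peak and mean, and
#' the inner-over-outer ratios for Line A (near-wall lumen) and Line B
#' (intra-wall).
#'
#' @param conc A `concentration_field` from [solve_drug()].
#' @param mesh The `stent_mesh`.
#' @param offset Line offset from the interface in m (see
#'   [reference_lines()]).
#' @return A list with `lines` (a data.frame of line, peak, mean) and the
#'   ratios `A_peak_ratio`, `A_mean_ratio`, `B_peak_ratio`, `B_mean_ratio`
#'   (inner divided by outer).
#' @export
concentration_ratios <- function(conc, mesh, offset = 0.25e-3) {
  pos <- reference_lines(mesh, offset)
  prof <- lapply(pos, function(n) line_profile(conc, mesh, n))
  lines <- data.frame(
    line = names(pos),
    peak = vapply(prof, function(p) max(p$value), 0),
    mean = vapply(prof, function(p) mean(p$value), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  pk <- stats::setNames(lines$peak, lines$line)
  mn <- stats::setNames(lines$mean, lines$line)
  list(lines = lines,
       A_peak_ratio = unname(pk["A_inner"] / pk["A_outer"]),
       A_mean_ratio = unname(mn["A_inner"] / mn["A_outer"]),
       B_peak_ratio = unname(pk["B_inner"] / pk["B_outer"]),
       B_mean_ratio = unname(mn["B_inner"] / mn["B_outer"]))
}

#' @export
print.wss_profile <- function(x, ...) {
  sel <- x$s > x$stent_s[1] & x$s < x$stent_s[2]
  cat("<wss_profile>", length(x$s), "stations\n")
  cat("  stented extent: inner mean",
      formatC(sum((x$inner * x$arc_inner)[sel]) / sum(x$arc_inner[sel]),
              format = "g"),
      "Pa; outer mean",
      formatC(sum((x$outer * x$arc_outer)[sel]) / sum(x$arc_outer[sel]),
              format = "g"), "Pa\n")
  invisible(x)
}
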