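# Closed-form oracles used by the equivalence tests.  Each is derived
# independently of the solvers under test.

## Plane Poiseuille flow between parallel plates at y = +-H, mean velocity
## v_mean: u(y) = 1.5 v_mean (1 - (y/H)^2).
poiseuille_profile <- function(y, H, v_mean) {
  1.5 * v_mean * (1 - (y / H)^2)
}

## Wall shear stress of the plane Poiseuille profile: tau = 6 mu v_mean / (2H).
poiseuille_wss <- function(v_mean, H, mu) {
  3 * mu * v_mean / H
}

## Fully developed azimuthal flow in a curved channel (annulus sector) driven
## by a constant azimuthal pressure gradient:
##   u(r) = A r + B / r + C r ln r,
## with no slip at r_i and r_o and volumetric flux Q per unit depth.  The
## three coefficients are fixed by the two no-slip conditions and the flux.
curved_channel_profile <- function(r, r_i, r_o, Q) {
  basis <- list(function(r) r, function(r) 1 / r, function(r) r * log(r))
  M <- rbind(
    vapply(basis, function(f) f(r_i), numeric(1)),
    vapply(basis, function(f) f(r_o), numeric(1)),
    vapply(basis, function(f) stats::integrate(f, r_i, r_o)$value, numeric(1))
  )
  cf <- solve(M, c(0, 0, Q))
  cf[1] * r + cf[2] / r + cf[3] * r * log(r)
}

## Steady two-layer diffusion slab: phi = 0 at x = 0, layer 1 (diffusivity
## k1) on [0, L1], layer 2 (diffusivity k2) on [L1, L1 + L2], phi = 1 at the
## far face.  Flux continuity gives piecewise-linear profiles with slope
## ratio k2/k1 at the interface.
two_layer_slab <- function(x, L1, L2, k1, k2) {
  Rtot <- L1 / k1 + L2 / k2
  phi_i <- (L1 / k1) / Rtot           # interface value
  ifelse(x <= L1,
         phi_i * x / L1,
         phi_i + (1 - phi_i) * (x - L1) / L2)
}

## Relative L2 norm of (a - b) with quadrature weights w.
rel_l2 <- function(a, b, w = rep(1, length(a))) {
  sqrt(sum((a - b)^2 * w) / sum(b^2 * w))
}
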