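test_that("Reynolds helpers are mutually consistent", {
  fl <- fluid_properties()
  expect_equal(fl$rho, 1055)
  expect_equal(fl$mu, 3.5e-3)
  v <- velocity_for_reynolds(fl, 400, 3e-3)
  expect_equal(reynolds_number(fl, v, 3e-3), 400)
  ## the four study velocities map to the nominal Reynolds numbers
  Re <- reynolds_number(fl, c(0.22, 0.44, 0.66, 0.88), 3e-3)
  expect_equal(Re, c(200, 400, 600, 800), tolerance = 0.01)
})

test_that("straight-channel flow matches plane Poiseuille within 1% L2", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  m <- fx$mesh
  fl <- cached("flow_straight10", solve_flow(m, inlet = inlet_spec(0.22)))
  expect_true(fl$converged)
  H <- m$geom$lumen_diameter / 2
  lum <- which(m$region[1, ] == 0L)
  i <- which.min(abs(m$s_cent - mean(range(m$s_cent))))
  u_num <- fl$u[i, lum]
  u_an <- poiseuille_profile(m$n_cent[lum], H, 0.22)
  expect_lt(rel_l2(u_num, u_an, m$dn[lum]), 0.01)
})

test_that("straight-channel wall shear stress matches 6 mu U / h within 1%", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  fl <- cached("flow_straight10", solve_flow(fx$mesh, inlet = inlet_spec(0.22)))
  wss <- compute_wss(fl, fx$mesh)
  tau_an <- poiseuille_wss(0.22, fx$mesh$geom$lumen_diameter / 2,
                           fluid_properties()$mu)
  i <- which.min(abs(wss$s - mean(range(wss$s))))
  expect_lt(abs(wss$inner[i] - tau_an) / tau_an, 0.01)
  expect_lt(abs(wss$outer[i] - tau_an) / tau_an, 0.01)
})

test_that("curved-channel flow matches the exact annular ODE within 2% L2", {
  fx <- make_fixture("bare_bend", resolution = 10, bend_angle = 180)
  m <- fx$mesh
  fl <- solve_flow(m, inlet = inlet_spec(0.044))  # Re ~ 40, fully developed
  expect_true(fl$converged)
  s_mid <- m$bend_s[1] + 0.67 * diff(m$bend_s)
  i <- which.min(abs(m$s_cent - s_mid))
  lum <- which(m$region[i, ] == 0L)
  Rb <- m$geom$bend_radius
  r <- Rb + m$n_cent[lum]
  r_i <- Rb + m$n_faces[min(lum)]
  r_o <- Rb + m$n_faces[max(lum) + 1]
  u_num <- fl$u[i, lum]
  Q <- sum(u_num * m$dn[lum])
  u_an <- curved_channel_profile(r, r_i, r_o, Q)
  expect_lt(rel_l2(u_num, u_an, m$dn[lum]), 0.02)
})

test_that("discrete mass flux closes to 1e-6 relative in every cell", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  fl <- cached("flow_straight10", solve_flow(fx$mesh, inlet = inlet_spec(0.22)))
  expect_lt(fl$max_cell_imbalance / fl$inlet_flux, 1e-6)
})

test_that("solver refuses Reynolds numbers beyond the laminar model range", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  expect_error(solve_flow(fx$mesh, inlet = inlet_spec(3)),
               regexp = "laminar")
})

test_that("non-convergence raises a typed condition carrying the field", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  cnd <- tryCatch(
    solve_flow(fx$mesh, inlet = inlet_spec(0.22),
               settings = solver_settings(residual_tol = 1e-14,
                                          max_outer = 8)),
    stentflow_nonconvergence = function(e) e)
  expect_s3_class(cnd, "stentflow_nonconvergence")
  expect_s3_class(cnd$field, "flow_field")
  expect_false(cnd$field$converged)
})

test_that("zero_flow returns a quiescent converged field", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  z <- zero_flow(fx$mesh)
  expect_true(z$converged)
  expect_true(all(z$u == 0) && all(z$v == 0))
})
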