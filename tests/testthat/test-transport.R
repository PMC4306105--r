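test_that("transport property validation enforces the physical ordering", {
  pr <- transport_properties()
  expect_equal(pr$kf, 1e-7)
  expect_equal(pr$kt, 1e-12)
  expect_error(transport_properties(kf = 1e-13, kt = 1e-12))
  expect_error(transport_properties(kf = -1))
})

test_that("quiescent slab matches the analytic two-layer profile to 0.5%", {
  sl <- make_fixture("slab_1d", resolution = 20)
  m <- sl$mesh
  conc <- solve_drug(m, zero_flow(m))
  pr <- transport_properties()
  ## diffusion path: lumen layer (kf) then wall tissue up to the strut face
  d <- m$geom$lumen_diameter
  strut_face <- m$s_faces[min(which(m$region[, 1] == 2L))]
  x <- m$s_cent[m$region[, 1] != 2L]
  phi_num <- conc$conc[m$region[, 1] != 2L, 1]
  phi_an <- two_layer_slab(x, d, strut_face - d, pr$kf, pr$kt)
  w <- m$ds_c[m$region[, 1] != 2L]
  expect_lt(rel_l2(phi_num, phi_an, w), 0.005)
  ## strut cells pinned at unit concentration
  expect_true(all(conc$conc[m$region[, 1] == 2L, 1] == 1))
})

test_that("concentration stays within [0, 1] on the full geometry", {
  case <- cached_case(200, 10)
  conc <- attr(case, "conc")
  expect_gte(min(conc$conc), -1e-8)
  expect_lte(max(conc$conc), 1 + 1e-8)
})

test_that("drug flux balance closes to 1e-3 relative", {
  case <- cached_case(200, 10)
  fb <- drug_flux_balance(attr(case, "conc"), cached_mesh(10),
                          attr(case, "flow"))
  expect_lt(abs(fb$residual), 1e-3)
  ## struts are sources; the outlet carries drug out of the domain
  expect_gt(fb$strut_release, 0)
  expect_gt(fb$outlet_advection, 0)
})

test_that("solve_drug requires a converged matching flow field", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  bad <- zero_flow(fx$mesh)
  bad$converged <- FALSE
  expect_error(solve_drug(fx$mesh, bad), regexp = "converged")
  other <- make_fixture("slab_1d", resolution = 20)$mesh
  expect_error(solve_drug(other, zero_flow(fx$mesh)), regexp = "mesh")
})

test_that("deferred second-order correction converges below tolerance", {
  case <- cached_case(200, 10)
  conc <- attr(case, "conc")
  expect_true(conc$passes <= 31)
  expect_lt(conc$final_change, 1e-6)
})
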