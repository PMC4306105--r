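test_that("Dean numbers for the four study Reynolds numbers are reproduced", {
  Dn <- dean_number(c(200, 400, 600, 800), 1.5e-3, 10e-3)
  expect_equal(signif(Dn, 3), c(77.5, 155, 232, 310))
  expect_error(dean_number(200, 2e-3, 1e-3), regexp = "curvature")
})

test_that("regime classification uses the critical Dean number 36", {
  expect_equal(classify_dean_regime(35.9), "stable")
  expect_equal(classify_dean_regime(36), "stable")
  expect_equal(classify_dean_regime(36.1), "unstable")
  expect_equal(classify_dean_regime(dean_number(200, 1.5e-3, 10e-3)),
               "unstable")
})

test_that("cross-section solver matches the perturbation series at low Dn", {
  for (Dn in c(5, 10)) {
    Re <- Dn / sqrt(0.15)
    sol <- cached(sprintf("dean_%g", Dn), solve_dean_cross_section(Re, 0.15))
    expect_true(sol$converged)
    ser <- dean_series_solution(sol$Dn, nr = nrow(sol$psi),
                                ntheta = ncol(sol$psi))
    expect_true(ser$series_valid)
    w <- sol$grid$vol
    expect_lt(rel_l2(sol$psi, ser$psi, w), 0.05)
    expect_lt(rel_l2(sol$w, ser$w, w), 0.05)
  }
})

test_that("secondary-flow stream function is antisymmetric about the bend plane", {
  sol <- cached("dean_10", solve_dean_cross_section(10 / sqrt(0.15), 0.15))
  mirrored <- sol$psi[, rev(seq_len(ncol(sol$psi)))]
  expect_lt(max(abs(sol$psi + mirrored)) / max(abs(sol$psi)), 1e-10)
  ## axial velocity is symmetric
  wm <- sol$w[, rev(seq_len(ncol(sol$w)))]
  expect_lt(max(abs(sol$w - wm)) / max(sol$w), 1e-10)
})

test_that("physical scaling of the cross-section solution is consistent", {
  sol <- cached("dean_phys", solve_dean_cross_section(200, 0.15))
  expect_true(sol$converged)
  expect_equal(sol$Dn, dean_number(200, 1.5e-3, 10e-3))
  ## axial peak near (but above, due to the secondary shift) Poiseuille peak
  v_mean <- 200 * fluid_properties()$mu / (fluid_properties()$rho * 3e-3)
  expect_gt(sol$summary$peak_axial_mps, v_mean)
  expect_lt(sol$summary$peak_axial_mps, 2 * v_mean)
  ## secondary flow is a modest fraction of the axial flow
  expect_gt(sol$summary$peak_secondary_mps, 0)
  expect_lt(sol$summary$peak_secondary_mps, sol$summary$peak_axial_mps)
  ## outward shift of the axial peak toward the outer bend
  expect_gt(sol$summary$peak_axial_x, 0)
})
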