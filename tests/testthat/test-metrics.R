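test_that("WSS profile on a straight channel is uniform and analytic", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  fl <- cached("flow_straight10", solve_flow(fx$mesh, inlet = inlet_spec(0.22)))
  wss <- compute_wss(fl, fx$mesh)
  expect_s3_class(wss, "wss_profile")
  tau <- poiseuille_wss(0.22, fx$mesh$geom$lumen_diameter / 2,
                        fluid_properties()$mu)
  ## away from inlet/outlet development zones
  core <- wss$s > 0.2 * max(wss$s) & wss$s < 0.8 * max(wss$s)
  expect_lt(max(abs(wss$inner[core] - tau)) / tau, 0.01)
  expect_lt(max(abs(wss$outer[core] - tau)) / tau, 0.01)
  ## straight geometry: unit metric, arc weights equal the cell spacing
  expect_equal(wss$arc_inner, fx$mesh$ds_c)
  expect_equal(wss$arc_outer, fx$mesh$ds_c)
})

test_that("low WSS fraction is an exact arc-length average", {
  fx <- cached("straight10", make_fixture("straight_channel", resolution = 10))
  fl <- cached("flow_straight10", solve_flow(fx$mesh, inlet = inlet_spec(0.22)))
  wss <- compute_wss(fl, fx$mesh)
  ## fabricate known fields: inner below threshold on cells with s < L/3
  wss$inner <- ifelse(wss$s < max(wss$s) / 3, 0.1, 2)
  wss$outer <- rep(2, length(wss$s))
  lw <- low_wss_fraction(wss, threshold = 0.5, extent = "full")
  want_inner <- sum(wss$arc_inner[wss$s < max(wss$s) / 3]) / sum(wss$arc_inner)
  expect_equal(lw$inner, want_inner)
  expect_equal(lw$outer, 0)
  expect_equal(lw$total, want_inner / 2)
  expect_error(low_wss_fraction(wss, threshold = -1))
})

test_that("reference lines sit 0.25 mm either side of the interfaces", {
  mesh <- cached_mesh(10)
  pos <- reference_lines(mesh)
  expect_equal(unname(pos["A_inner"]), -1.25e-3)
  expect_equal(unname(pos["A_outer"]), 1.25e-3)
  expect_equal(unname(pos["B_inner"]), -1.75e-3)
  expect_equal(unname(pos["B_outer"]), 1.75e-3)
  expect_error(reference_lines(mesh, offset = 1e-3), regexp = "offset")
})

test_that("line_profile reproduces a linear transverse field exactly", {
  mesh <- cached_mesh(10)
  a <- 0.3; b <- 150
  f <- matrix(rep(a + b * mesh$n_cent, each = mesh$nx), mesh$nx, mesh$ny)
  for (n0 in c(-1.25e-3, 0.6e-3, 1.75e-3)) {
    pr <- line_profile(f, mesh, n0)
    expect_equal(pr$value, rep(a + b * n0, nrow(pr)), tolerance = 1e-12)
  }
  ## restricted streamwise range is honoured
  pr <- line_profile(f, mesh, 0, s_range = mesh$stent_s)
  expect_true(all(pr$s >= mesh$stent_s[1] & pr$s <= mesh$stent_s[2]))
})

test_that("segment_stats splits a profile into equal thirds", {
  prof <- data.frame(s = seq(0, 3, length.out = 300), value = seq(0, 3, length.out = 300))
  st <- segment_stats(prof)
  expect_equal(st$segment, c("proximal", "middle", "distal"))
  expect_equal(st$mean, c(0.5, 1.5, 2.5), tolerance = 0.02)
  expect_equal(st$peak, c(1, 2, 3), tolerance = 0.02)
  expect_equal(sum(st$n), 300)
})

test_that("concentration_ratios reports inner/outer ratios of a known field", {
  mesh <- cached_mesh(10)
  ## concentration twice as high on the inner bend (n < 0)
  f <- matrix(rep(ifelse(mesh$n_cent < 0, 0.8, 0.4), each = mesh$nx),
              mesh$nx, mesh$ny)
  cr <- concentration_ratios(f, mesh)
  expect_equal(cr$A_peak_ratio, 2)
  expect_equal(cr$A_mean_ratio, 2)
  expect_equal(cr$B_peak_ratio, 2)
  expect_equal(cr$B_mean_ratio, 2)
  expect_setequal(cr$lines$line, c("A_inner", "A_outer", "B_inner", "B_outer"))
})
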