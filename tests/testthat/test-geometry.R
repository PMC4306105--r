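test_that("default geometry validates and carries the reference dimensions", {
  g <- stent_geometry()
  expect_s3_class(g, "stent_geometry")
  expect_equal(g$lumen_diameter, 3e-3)
  expect_equal(g$bend_radius, 10e-3)
  expect_equal(g$bend_angle, 90)
  expect_equal(g$wall_thickness, 0.5e-3)
  expect_equal(g$n_struts, 6)
  expect_equal(g$strut_size, 0.1e-3)
  expect_silent(validate_geometry(g))
})

test_that("invalid geometries are rejected", {
  expect_error(stent_geometry(lumen_diameter = -1))
  expect_error(stent_geometry(bend_angle = 400))
  expect_error(stent_geometry(strut_size = 2e-3))
  expect_error(stent_geometry(n_struts = 200))
  expect_error(stent_geometry(stent_length = 50e-3),
               regexp = "stent")
})

test_that("mesh covers the analytic domain area and regions partition cells", {
  mesh <- cached_mesh(10)
  expect_s3_class(mesh, "stent_mesh")
  expect_true(all(mesh$vol > 0))
  expect_equal(sum(mesh$vol), analytic_domain_area(mesh$geom),
               tolerance = 1e-10)
  expect_setequal(unique(as.integer(mesh$region)), c(0L, 1L, 2L))
  expect_equal(sum(mesh$region == 0L) + sum(mesh$region == 1L) +
                 sum(mesh$region == 2L), mesh$nx * mesh$ny)
  ## n_lumen counts transverse lumen cells: d / h at this resolution
  expect_equal(mesh$n_lumen,
               round(mesh$geom$lumen_diameter * mesh$resolution * 1e3))
})

test_that("strut cells form the prescribed pattern on both walls", {
  mesh <- cached_mesh(10)
  st <- mesh$struts
  g <- mesh$geom
  ## six struts per side, on both lumen-wall interfaces
  expect_equal(nrow(st), 2 * g$n_struts)
  expect_setequal(unique(st$side), c("inner_bend", "outer_bend"))
  ## struts lie within the stented extent
  expect_true(all(st$s0 >= mesh$stent_s[1] - 1e-12))
  expect_true(all(st$s1 <= mesh$stent_s[2] + 1e-12))
  ## strut cells exist and sit adjacent to the lumen
  expect_gt(sum(mesh$region == 2L), 0)
})

test_that("curvature metric terms are confined to the bend", {
  mesh <- cached_mesh(10)
  inside <- mesh$s_cent > mesh$bend_s[1] & mesh$s_cent < mesh$bend_s[2]
  expect_true(all(mesh$curv[inside] > 0))
  expect_true(all(mesh$curv[!inside] == 0))
  expect_equal(unique(mesh$curv[inside]), 1 / mesh$geom$bend_radius)
})

test_that("resolution floor guarantees struts are resolved", {
  g <- stent_geometry()
  expect_error(build_geometry(g, resolution = 5), regexp = "resolution")
  m <- build_geometry(g, resolution = 10)
  ## every strut footprint contains at least one cell centre streamwise
  for (k in seq_len(nrow(m$struts)))
    expect_true(any(m$s_cent >= m$struts$s0[k] & m$s_cent < m$struts$s1[k]))
})

test_that("graded extension spacing is monotone and bounded", {
  ds <- grade_extension(30e-3, ds0 = 5e-5, g = 1.2, ds_max = 1e-3)
  expect_equal(sum(ds), 30e-3, tolerance = 1e-12)
  expect_true(all(diff(ds) >= -1e-12))
  expect_lte(max(ds), 1e-3 + 1e-12)
})

test_that("mesh_nodes returns physical coordinates of the expected shape", {
  mesh <- cached_mesh(10)
  nodes <- mesh_nodes(mesh)
  expect_equal(dim(nodes$x), c(mesh$nx + 1L, mesh$ny + 1L))
  expect_equal(dim(nodes$y), c(mesh$nx + 1L, mesh$ny + 1L))
  expect_true(all(is.finite(nodes$x)) && all(is.finite(nodes$y)))
})

test_that("fixtures build and unknown names fail", {
  expect_error(make_fixture("nope"), regexp = "valid names")
  fx <- make_fixture("straight_channel", resolution = 10)
  expect_true(all(fx$mesh$curv == 0))
  expect_equal(sum(fx$mesh$region == 2L), 0)
  sl <- make_fixture("slab_1d", resolution = 20)
  expect_equal(sl$mesh$ny, 1L)
  expect_gt(sum(sl$mesh$region == 2L), 0)
})
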