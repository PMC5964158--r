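test_that("project_to_scalp preserves count/order and is idempotent", {
  ph <- fx_phantom4()
  surf <- fx_surf4()
  icss <- project_to_scalp(ph$truth$sulcus_gt, surf)
  expect_identical(icss$space, "scalp")
  expect_lte(nrow(icss$points), nrow(ph$truth$sulcus_gt$points))
  # re-projection is a no-op
  again <- project_to_scalp(icss, surf, require_inside = FALSE)
  expect_equal(again$points, icss$points, tolerance = 1e-12)
  # a point on the surface projects to itself
  v1 <- surf$vertices[10, ]
  r <- closest_point_mesh(rbind(v1), surf)
  expect_lt(r$dist, 1e-9)
})

test_that("points outside the surface are rejected", {
  surf <- fx_surf4()
  outside <- sulcus_trace(rbind(c(0, 0, 500), c(0, 0, 510)), "individual")
  expect_error(project_to_scalp(outside, surf), class = "repe_projection_error")
})

test_that("arc-length flattening preserves length exactly", {
  # straight line at 5 mm spacing
  tr <- sulcus_trace(cbind(seq(0, 175, 5), 0, 0), "scalp")
  fl <- flatten_trace(tr)
  expect_identical(fl$points[, 1], seq(0, 175, 5))
  # random 3D polyline: total planar length equals 3D length to machine eps
  set.seed(3)
  wiggle <- apply(matrix(rnorm(60, sd = 4), 20, 3), 2, cumsum)
  tr2 <- sulcus_trace(wiggle, "scalp")
  fl2 <- flatten_trace(tr2)
  expect_equal(trace_length(fl2), trace_length(tr2), tolerance = 1e-14)
  # semicircle r = 50 sampled at 1 degree: length within 0.1% of pi*r
  th <- seq(0, pi, by = pi / 180)
  semi <- sulcus_trace(cbind(50 * cos(th), 50 * sin(th), 0), "scalp")
  expect_lt(abs(trace_length(flatten_trace(semi)) / (pi * 50) - 1), 0.001)
  # duplicate consecutive points rejected (at construction)
  expect_error(sulcus_trace(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "scalp"),
               class = "repe_input_error")
})

test_that("pca flattening returns an in-plane trace", {
  th <- seq(0, pi / 2, length.out = 50)
  arc <- sulcus_trace(cbind(60 * cos(th), 60 * sin(th), 5 * sin(3 * th)), "scalp")
  fp <- flatten_trace(arc, method = "pca")
  expect_identical(fp$space, "plane")
  expect_true(all(fp$points[, 3] == 0))
})

test_that("electrode outline: area, width scaling, degenerate width", {
  tr <- sulcus_trace(cbind(seq(0, 175, length.out = 123), 0, 0), "scalp")
  fl <- flatten_trace(tr)
  out <- build_electrode_outline(fl, width_mm = 20)
  expect_equal(out$area_mm2, 3500, tolerance = 1e-9)  # 35 cm^2
  expect_error(build_electrode_outline(fl, width_mm = 0),
               class = "repe_geometry_error")
  # area = length x width within 1e-6 for arbitrary traces; linear in width
  set.seed(11)
  for (i in 1:5) {
    pts <- apply(matrix(abs(rnorm(45, sd = 6)) + 0.5, 15, 3), 2, cumsum)
    fli <- flatten_trace(sulcus_trace(pts, "scalp"))
    L <- trace_length(fli)
    o20 <- build_electrode_outline(fli, 20)
    o40 <- build_electrode_outline(fli, 40)
    expect_equal(o20$area_mm2, L * 20, tolerance = 1e-6)
    expect_equal(o40$area_mm2 / o20$area_mm2, 2, tolerance = 1e-9)
    # shoelace oracle on the polygon itself
    expect_equal(abs(repe:::polygon_area(o20$plane_polygon)), L * 20,
                 tolerance = 1e-6)
  }
})

test_that("SVG export round-trips coordinates at true scale", {
  tr <- sulcus_trace(cbind(seq(0, 175, 25), 0, 0), "scalp")
  out <- build_electrode_outline(flatten_trace(tr), 20)
  p <- file.path(tempdir(), "electrode.svg")
  export_outline(out, p)
  rt <- read_outline_svg(p)
  expect_lt(max(abs(rt$polygon - out$plane_polygon)), 1e-6)
  expect_identical(rt$ruler_length_mm, 100)
  # rectangle corners present at exact coordinates
  expect_true(all(c(0, 175) %in% rt$polygon[, 1]))
  expect_true(all(c(0, -20) %in% rt$polygon[, 2]))
})
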