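test_that("voxelized ball triangulates to the analytic sphere", {
  b <- fx_ball()
  expect_lt(abs(mesh_area(b$surf) / (4 * pi * 40^2) - 1), 0.05)
  expect_identical(mesh_euler(b$surf), 2L)
  expect_true(mesh_is_closed_manifold(b$surf))
})

test_that("phantom scalp surface is a closed genus-0 manifold", {
  surf <- fx_surf4()
  expect_identical(mesh_euler(surf), 2L)
  expect_true(mesh_is_closed_manifold(surf))
})

test_that("every boundary voxel lies within one voxel of the surface", {
  b <- fx_ball()
  mask <- b$mask
  boundary <- mask & !repe:::erode6(mask)
  pts <- voxel_to_world(b$affine, repe:::lin_to_ijk0(which(boundary), dim(mask)))
  nn <- FNN::get.knnx(b$surf$vertices, pts, k = 1)
  expect_lt(max(nn$nn.dist), 2)   # 1 voxel = 2 mm
})

test_that("mesh normals point outward (positive enclosed volume)", {
  b <- fx_ball()
  V <- b$surf$vertices; Tr <- b$surf$triangles
  v1 <- V[Tr[, 1], ]; v2 <- V[Tr[, 2], ]; v3 <- V[Tr[, 3], ]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
             v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
             v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  expect_gt(vol, 0.9 * 4 / 3 * pi * 40^3)
  expect_lt(vol, 1.1 * 4 / 3 * pi * 40^3)
})

test_that("closest_point_mesh: sphere-centre distance and idempotence", {
  b <- fx_ball()
  r <- closest_point_mesh(rbind(c(0, 0, 0)), b$surf)
  expect_equal(r$dist, 40, tolerance = 0.03)
  # projecting a projection is a no-op
  r2 <- closest_point_mesh(r$points, b$surf)
  expect_equal(r2$points, r$points, tolerance = 1e-12)
  expect_lt(r2$dist, 1e-9)
})

test_that("kNN-filtered projection equals pure brute force", {
  b <- fx_ball()
  set.seed(42)
  q <- matrix(runif(60, -30, 30), ncol = 3)
  rf <- closest_point_mesh(q, b$surf)
  rb <- closest_point_mesh(q, b$surf, k_filter = Inf)
  expect_identical(rf$points, rb$points)
  expect_identical(rf$dist, rb$dist)
})

test_that("projection distance is minimal over all surface vertices", {
  b <- fx_ball()
  set.seed(7)
  q <- matrix(runif(30, -30, 30), ncol = 3)
  r <- closest_point_mesh(q, b$surf)
  nnv <- FNN::get.knnx(b$surf$vertices, q, k = 1)
  expect_true(all(r$dist <= nnv$nn.dist[, 1] + 1e-12))
})

test_that("PLY export writes a parseable mesh", {
  b <- fx_ball()
  p <- file.path(tempdir(), "ball.ply")
  write_ply(b$surf, p)
  lines <- readLines(p)
  expect_identical(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("element face", lines, value = TRUE)))
  expect_identical(nv, nrow(b$surf$vertices))
  expect_identical(nf, nrow(b$surf$triangles))
  hdr <- which(lines == "end_header")
  expect_identical(length(lines), hdr + nv + nf)
})
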