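test_that("geodesic distance: identity, symmetry, great-circle bound", {
  b <- fx_ball()
  expect_identical(geodesic_distance(b$surf, c(0, 0, 40), c(0, 0, 40)), 0)
  d1 <- geodesic_distance(b$surf, c(40, 0, 0), c(0, 0, 40))
  d2 <- geodesic_distance(b$surf, c(0, 0, 40), c(40, 0, 0))
  expect_identical(d1, d2)
  # antipodal: edge-graph metric overestimates pi*r by a few percent
  d <- geodesic_distance(b$surf, c(0, 0, 40), c(0, 0, -40))
  expect_lt(abs(d / (pi * 40) - 1), 0.08)
  expect_error(geodesic_distance(b$surf, c(0, 0, 80), c(0, 0, 40)),
               class = "repe_snap_error")
})

test_that("placement sheet on the symmetric phantom", {
  ph <- fx_phantom2()
  surf <- fx_surf2()
  sheet <- compute_placement_sheet(surf, ph$truth$fiducials, fx_footprint2_sym())
  expect_true(all(c(sheet$d_NI, sheet$d_N_C, sheet$d_N_L, sheet$d_N_R) > 0))
  expect_lt(sheet$d_N_C, sheet$d_NI)
  # mirror-symmetric phantom + mirror-symmetric electrode
  expect_lt(abs(sheet$d_N_L - sheet$d_N_R), 2)
  # off-midline footprint errors
  lateral <- fx_footprint2_sym()
  lateral[, 1] <- lateral[, 1] + 500
  expect_error(compute_placement_sheet(surf, ph$truth$fiducials, lateral),
               class = "repe_error")
})

test_that("electrode through the sphere vertex gives a quarter great circle", {
  b <- fx_ball()
  fid <- fiducial_set(nasion = c(0, 40, 0), inion = c(0, -40, 0))
  # footprint: arc over the vertex in the x-z plane (y = 0)
  th <- seq(-1.2, 1.2, length.out = 61)
  fp <- cbind(40 * sin(th), 0, 40 * cos(th))
  sheet <- compute_placement_sheet(b$surf, fid, fp)
  expect_lt(abs(sheet$d_N_C / (pi * 40 / 2) - 1), 0.08)
})

test_that("repe_points resamples 27 markers at 5 mm spacing", {
  fp <- fx_footprint4()
  rp <- repe_points(fp)
  expect_identical(dim(rp), c(27L, 3L))
  # chord spacing: at most 5 mm (arc spacing is exactly 5 by construction;
  # chords shorten where the projected footprint is jagged at mesh scale)
  spacing <- rownorms(diff(rp))
  expect_true(all(spacing <= 5 + 1e-9))
  # on a smooth footprint the chords are 5 +/- 1 mm
  th <- seq(-1.2, 1.2, length.out = 241)
  smooth_fp <- cbind(80 * sin(th), 0, 80 * cos(th))
  sp2 <- rownorms(diff(repe_points(smooth_fp)))
  expect_true(all(abs(sp2 - 5) <= 1))
  short <- cbind(seq(0, 50, 5), 0, 0)
  expect_error(repe_points(short), class = "repe_input_error")
})

test_that("repositioning simulation: determinism and noiseless identity", {
  fp <- fx_footprint4()
  rp <- repe_points(fp)
  r0 <- simulate_repositioning(rp, surf = NULL, n_reps = 3, sd_mm = c(0, 0, 0),
                               seed = 1)
  for (k in 1:3) expect_equal(r0[[k]], rp, tolerance = 1e-15)
  ra <- simulate_repositioning(rp, surf = NULL, n_reps = 3, seed = 9)
  rb <- simulate_repositioning(rp, surf = NULL, n_reps = 3, seed = 9)
  expect_identical(ra, rb)
  expect_false(isTRUE(all.equal(ra[[1]],
    simulate_repositioning(rp, surf = NULL, n_reps = 3, seed = 10)[[1]])))
})

test_that("isotropic noise matches the 3D half-normal mean", {
  # distance of N(0, sigma^2 I3) displacements from a single reference point
  sigma <- 2
  p0 <- rbind(c(10, 20, 30))
  reps <- simulate_repositioning(p0[rep(1, 200), ], surf = NULL, n_reps = 30,
                                 sd_mm = rep(sigma, 3), seed = 4)
  rep_mean <- positioning_error(reps, p0)$overall_mean
  expect_equal(rep_mean, sigma * sqrt(8 / pi), tolerance = 0.05)
})

test_that("positioning error: identity and 3-4-5 offsets", {
  ref <- cbind(seq(0, 100, 5), 0, 0)
  r <- positioning_error(list(ref), ref)
  expect_identical(r$overall_mean, 0)
  off <- ref
  off[, 2] <- off[, 2] + 3; off[, 3] <- off[, 3] + 4
  r2 <- positioning_error(list(off), ref)
  expect_equal(r2$overall_mean, 5, tolerance = 1e-12)
  expect_equal(unname(unlist(r2$per_rep[1, c("dy", "dz")])), c(3, 4),
               tolerance = 1e-12)
  expect_error(positioning_error(list(), ref), class = "repe_input_error")
})

test_that("overall mean equals the mean of repetition means", {
  fp <- fx_footprint4()
  rp <- repe_points(fp)
  reps <- simulate_repositioning(rp, fx_surf4(), n_reps = 4, seed = 2)
  rep_report <- positioning_error(reps, sulcus_trace(fp, "scalp"))
  expect_equal(rep_report$overall_mean, mean(rep_report$per_rep$mean_dist),
               tolerance = 1e-12)
  expect_true(all(rep_report$deltas$dist >= 0))
})
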