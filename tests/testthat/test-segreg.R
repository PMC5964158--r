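test_that("brain extraction meets the Dice contract against ground truth", {
  # the Dice >= 0.95 contract holds at the default 2 mm scale
  pair <- fx_pair2()
  seg2 <- fx_seg_pair2()
  gt2 <- array(pair$individual$labels$labels %in% c(5L, 6L),
               dim(pair$individual$labels$labels))
  expect_gte(dice(seg2$ind$iBrain$mask, gt2), 0.95)
  # coarse 4 mm phantom still segments reasonably and nests correctly
  ph <- fx_phantom4()
  seg <- fx_seg4()
  gt <- array(ph$labels$labels %in% c(5L, 6L), dim(ph$labels$labels))
  expect_gte(dice(seg$iBrain$mask, gt), 0.90)
  # scalp strictly contains brain
  expect_false(any(seg$iBrain$mask & !seg$iScalp$mask))
  # scalp is one 6-connected component
  lab <- repe:::label_components6(seg$iScalp$mask)
  expect_identical(max(lab), 1L)
})

test_that("auto (Otsu) thresholds segment the phantom too", {
  ph <- fx_phantom2()
  seg <- extract_brain_and_scalp(ph$intensity, cfg = list(method = "auto"))
  gt <- array(ph$labels$labels %in% c(5L, 6L), dim(seg$iBrain$mask))
  expect_gte(dice(seg$iBrain$mask, gt), 0.90)
})

test_that("segmentation errors on degenerate input", {
  g <- grid_params(n = 16L, voxel = 4)
  airvol <- intensity_volume(array(0, g$n), g$affine)
  expect_error(extract_brain_and_scalp(airvol), class = "repe_segmentation_error")
  badvol <- array(0, g$n); badvol[1] <- NA
  expect_error(intensity_volume(badvol, g$affine), class = "repe_input_error")
})

test_that("self-registration returns the identity", {
  seg <- fx_seg4()
  tm <- fit_affine(seg$iBrain, seg$iBrain)
  expect_lt(norm(tm$matrix - diag(4), "F"), 1e-3)
})

test_that("pure translation is recovered to sub-voxel accuracy", {
  g <- grid_params(n = 48L, voxel = 4)
  W <- make_affine(trans = c(6, -4, 3))
  pair <- generate_template_pair(grid = g, perturb = W, seed = 5L)
  tm <- fit_affine(extract_brain_and_scalp(pair$individual$intensity)$iBrain,
                   extract_brain_and_scalp(pair$template$intensity)$iBrain)
  gt <- pair$individual$truth$template_affine_gt
  # centroid oracle: translation column within half a voxel
  expect_lt(max(abs(tm$matrix[1:3, 4] - gt[1:3, 4])), 2)
  expect_lt(max(abs(tm$matrix[1:3, 1:3] - diag(3))), 0.03)
})

test_that("fit_affine is equivariant under a rigid pre-motion", {
  # pre-composing the moving phantom with a rigid motion changes the fitted
  # affine by exactly that motion (2% at the default 2 mm scale)
  tm <- fx_tm2()                              # individual -> template
  Q <- make_affine(rot_deg = c(0, 0, 5), trans = c(4, 2, 0))
  W <- fx_perturb()
  moved <- generate_head_phantom(seed = derive_seed(1L, 2L), warp = Q %*% W)
  seg_m <- extract_brain_and_scalp(moved$intensity)
  tm2 <- fit_affine(seg_m$iBrain, fx_seg_pair2()$tpl$iBrain)
  # expected: tm2 = tm o Q^-1
  want <- tm$matrix %*% solve(Q)
  expect_lt(max(abs(tm2$matrix - want)), 0.02 * max(1, max(abs(want))))
})

test_that("degenerate masks raise registration errors", {
  g <- grid_params(n = 16L, voxel = 4)
  flat <- array(FALSE, g$n); flat[, , 8] <- TRUE   # coplanar support
  ok <- array(FALSE, g$n); ok[4:12, 4:12, 4:12] <- TRUE
  expect_error(fit_affine(binary_mask(flat, g$affine), binary_mask(ok, g$affine)),
               class = "repe_registration_error")
})

test_that("template sulcus mapping preserves order and count", {
  tpl <- sulcus_trace(cbind(seq(-60, 60, length.out = 123), -15, 70), "template")
  idt <- affine_transform(diag(4))
  out <- map_template_sulcus(tpl, idt)
  expect_equal(out$points, tpl$points)
  expect_identical(out$space, "individual")
  expect_identical(nrow(out$points), 123L)
  W <- fx_perturb()
  out2 <- map_template_sulcus(tpl, affine_transform(solve(W)))
  expect_equal(out2$points, apply_affine(W, tpl$points), tolerance = 1e-12)
  # singular transform refuses
  expect_error(affine_transform(matrix(0, 4, 4)), class = "repe_transform_error")
})

test_that("round trip through a transform and its inverse is exact", {
  W <- fx_perturb()
  tm <- affine_transform(W)
  pts <- matrix(rnorm(30, sd = 40), 10, 3)
  back <- apply_affine(solve(tm$matrix), apply_affine(tm$matrix, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("affine text round trip (FLIRT-style .mat)", {
  tm <- affine_transform(fx_perturb())
  p <- file.path(tempdir(), "tm.mat")
  write_affine(tm, p)
  expect_equal(read_affine(p)$matrix, tm$matrix, tolerance = 1e-15)
})
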