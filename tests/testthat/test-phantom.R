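test_that("default phantom contains all tissue classes with proper nesting", {
  ph <- fx_phantom4()
  lab <- ph$labels$labels
  expect_setequal(sort(unique(as.vector(lab))), 0:6)
  # nesting: no white matter voxel 6-adjacent to air
  white_near_air <- repe:::dilate6(lab == 0L, 1L) & (lab == 6L)
  expect_false(any(white_near_air))
  # white only touches gray, CSF (sulcus cleft) or white
  nb_of_white <- repe:::dilate6(lab == 6L, 1L) & !(lab == 6L)
  expect_true(all(lab[nb_of_white] %in% c(4L, 5L)))
})

test_that("phantom generation is seed-deterministic", {
  g <- grid_params(n = 32L, voxel = 4)
  a <- generate_head_phantom(grid = g, seed = 7L)
  b <- generate_head_phantom(grid = g, seed = 7L)
  c <- generate_head_phantom(grid = g, seed = 8L)
  expect_identical(a$intensity$values, b$intensity$values)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_false(identical(a$intensity$values, c$intensity$values))
})

test_that("degenerate groove (depth 0) still defines the midline ridge", {
  g <- grid_params(n = 32L, voxel = 4)
  ph <- generate_head_phantom(sulcus = sulcus_params(depth = 0), grid = g, seed = 1L)
  gt <- ph$truth$sulcus_gt
  expect_s3_class(gt, "sulcus_trace")
  expect_gte(nrow(gt$points), 100L)
  # no CSF cleft voxels were carved inside gray
  ph1 <- generate_head_phantom(grid = g, seed = 1L)
  expect_gt(sum(ph1$labels$labels == 4L), sum(ph$labels$labels == 4L))
})

test_that("invalid shape parameters error", {
  expect_error(phantom_shape_params(skull = 0), class = "repe_parameter_error")
  expect_error(phantom_shape_params(rx = 10), class = "repe_parameter_error")
  expect_error(generate_template_pair(perturb = matrix(0, 4, 4)),
               class = "repe_parameter_error")
})

test_that("template pair carries the exact applied affine and 123 points", {
  g <- grid_params(n = 32L, voxel = 4)
  W <- fx_perturb()
  pair <- generate_template_pair(grid = g, perturb = W, seed = 3L)
  expect_identical(nrow(pair$template$sulcus$points), 123L)
  tm_gt <- pair$individual$truth$template_affine_gt
  expect_lt(max(abs(tm_gt %*% W - diag(4))), 1e-10)
  # round trip of the ground-truth sulcus through the affine
  p <- pair$individual$truth$sulcus_gt$points
  back <- apply_affine(W, apply_affine(tm_gt, p))
  expect_lt(max(abs(back - p)), 1e-9)
  # identity perturbation reproduces the template labels
  pid <- generate_template_pair(grid = g, perturb = make_affine(), seed = 3L)
  expect_identical(pid$individual$labels$labels, pid$template$labels$labels)
})

test_that("ROI masks partition gray matter around the sulcus", {
  ph <- fx_phantom4()
  rois <- roi_masks(ph$labels, ph$truth)
  gray <- ph$labels$labels == 5L
  expect_true(all(rois$S1[!gray] == FALSE))
  expect_false(any(rois$S1 & rois$M1))
  # sections partition their band
  s1_secs <- Reduce(`|`, rois[c("S1_L", "S1_mL", "S1_C", "S1_mR", "S1_R")])
  expect_identical(s1_secs, rois$S1)
})
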