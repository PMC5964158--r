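# Shared fixtures, built once per test session (memoised).

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# desk-scale phantom: 4 mm grid, 48^3 (fast; used by most tests)
fx_phantom4 <- function() fx_get("phantom4", function() {
  generate_head_phantom(grid = grid_params(n = 48L, voxel = 4), seed = 1L)
})

fx_seg4 <- function() fx_get("seg4", function() {
  extract_brain_and_scalp(fx_phantom4()$intensity)
})

fx_surf4 <- function() fx_get("surf4", function() {
  with_mesh_graph(surface_from_mask(fx_seg4()$iScalp))
})

fx_footprint4 <- function() fx_get("footprint4", function() {
  project_to_scalp(fx_phantom4()$truth$sulcus_gt, fx_surf4())$points
})

# full-resolution template/individual pair (2 mm, 96^3) with the package's
# default perturbation; shared by registration unit tests and acceptance
fx_pair2 <- function() fx_get("pair2", function() {
  generate_template_pair(perturb = fx_perturb(), seed = 1L)
})

fx_perturb <- function() {
  make_affine(scale = c(1.05, 0.97, 1.03), rot_deg = c(4, -3, 2),
              shear = c(0.03, 0.02, -0.02), trans = c(4, -3, 5))
}

fx_seg_pair2 <- function() fx_get("seg_pair2", function() {
  pair <- fx_pair2()
  list(ind = extract_brain_and_scalp(pair$individual$intensity),
       tpl = extract_brain_and_scalp(pair$template$intensity))
})

fx_tm2 <- function() fx_get("tm2", function() {
  s <- fx_seg_pair2()
  fit_affine(s$ind$iBrain, s$tpl$iBrain)
})

# symmetric single phantom at the default 2 mm scale, with a scalp surface
# built from the ground-truth head mask and the projected sulcus footprint
fx_phantom2 <- function() fx_get("phantom2", function() {
  generate_head_phantom(seed = 1L)
})

fx_surf2 <- function() fx_get("surf2", function() {
  ph <- fx_phantom2()
  head <- array(ph$labels$labels > 0L, dim(ph$labels$labels))
  with_mesh_graph(surface_from_mask(head, ph$labels$affine))
})

fx_footprint2 <- function() fx_get("footprint2", function() {
  project_to_scalp(fx_phantom2()$truth$sulcus_gt, fx_surf2())$points
})

# analytically mirror-symmetric electrode footprint on the skin surface
fx_footprint2_sym <- function() fx_get("footprint2_sym", function() {
  ph <- fx_phantom2()
  shape <- ph$truth$shape
  shape$radii["gray", ] <- shape$radii["skin", ]
  curve <- repe:::sulcus_midline_points(shape, ph$truth$sulcus)
  closest_point_mesh(curve, fx_surf2())$points
})

# voxelized ball r = 40 mm at 2 mm (sphere geometry oracles)
fx_ball <- function() fx_get("ball", function() {
  g <- grid_params(n = 48L, voxel = 2)
  pts <- voxel_to_world(g$affine, cbind(
    rep(0:(g$n[1] - 1), times = g$n[2] * g$n[3]),
    rep(rep(0:(g$n[2] - 1), each = g$n[1]), times = g$n[3]),
    rep(0:(g$n[3] - 1), each = g$n[1] * g$n[2])))
  mask <- array(sqrt(rowSums(pts^2)) <= 40, g$n)
  list(mask = mask, affine = g$affine,
       surf = with_mesh_graph(surface_from_mask(mask, g$affine)))
})
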