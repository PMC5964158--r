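# Synthetic head phantoms with known ground truth.
#
# The head is a stack of concentric ellipsoidal tissue shells (skin, fat,
# skull, CSF, gray, white) with a cylindrical neck stub appended inferiorly
# and a single parametric central-sulcus groove: a coronal, laterally curved
# CSF-filled cleft cut into the gray shell. Geometry is evaluated
# analytically at voxel centres, so an affinely deformed "individual" can be
# produced exactly (no resampling).

#' Phantom shape parameters
#'
#' Outer skin semi-axes and layer thicknesses, all in mm. Defaults give an
#' adult-sized head (140 x 170 x 160 mm) with realistic shell thicknesses.
#'
#' The shells are tapered ovoids, not exact ellipsoids: the lateral and
#' vertical semi-axes shrink/grow linearly along the anterior-posterior
#' axis (`taper`), giving the scaphoid "egg" shape of a real head. Besides
#' realism this makes the head affinely rigid: an exact ellipsoid is
#' invariant under a continuous family of affines, so registration could
#' not recover rotations from masks alone.
#'
#' @param rx,ry,rz outer skin semi-axes (right, anterior, superior), mm.
#' @param skin,fat,skull,csf,gray layer thicknesses, mm.
#' @param taper length-2: fractional change of the x and z semi-axes per
#'   unit `y/ry` (anterior positive).
#' @param neck_radius neck stub radius, mm.
#' @param neck_z_frac neck starts below `-neck_z_frac * rz`.
#' @export
phantom_shape_params <- function(rx = 70, ry = 85, rz = 80,
                                 skin = 4, fat = 3, skull = 6, csf = 4, gray = 4,
                                 taper = c(-0.06, 0.05),
                                 neck_radius = 28, neck_z_frac = 0.55) {
  th <- c(skin = skin, fat = fat, skull = skull, csf = csf, gray = gray)
  if (any(th <= 0)) stop_repe("layer thicknesses must be positive", "repe_parameter_error")
  r <- c(rx, ry, rz)
  radii <- rbind(skin = r,
                 fat   = r - skin,
                 skull = r - skin - fat,
                 csf   = r - skin - fat - skull,
                 gray  = r - skin - fat - skull - csf,
                 white = r - skin - fat - skull - csf - gray)
  if (any(radii <= 0)) stop_repe("radii leave no room for inner shells", "repe_parameter_error")
  list(radii = radii, taper = taper, ry_ref = ry,
       neck_radius = neck_radius, neck_z_frac = neck_z_frac)
}

# taper factors for the x and z semi-axes at anterior-posterior position y
taper_factors <- function(shape, y) {
  u <- y / shape$ry_ref
  list(gx = 1 + shape$taper[1] * u, gz = 1 + shape$taper[2] * u)
}

#' Sulcus groove parameters
#'
#' The groove midline runs coronally over the crown from left to right,
#' bowing anteriorly by `curvature` mm towards its lateral ends (so that a
#' straight strip electrode cannot follow it).
#'
#' @param depth groove depth below the outer gray surface, mm (0 = no cut).
#' @param curvature anterior bowing amplitude, mm.
#' @param y_center anterior-posterior position of the crown crossing, mm.
#' @param half_width half-width of the CSF cleft, mm.
#' @param psi_max lateral angular extent, degrees from the vertex.
#' @param n_points number of midline ground-truth points.
#' @export
sulcus_params <- function(depth = 6, curvature = 25, y_center = -15,
                          half_width = 2, psi_max = 75, n_points = 123L) {
  if (depth < 0 || half_width <= 0 || psi_max <= 0 || n_points < 2)
    stop_repe("invalid sulcus parameters", "repe_parameter_error")
  list(depth = depth, curvature = curvature, y_center = y_center,
       half_width = half_width, psi_max = psi_max * pi / 180, n_points = as.integer(n_points))
}

#' Phantom grid parameters
#' @param n grid size per axis (voxels).
#' @param voxel isotropic voxel size, mm (default 2; use 1 for fine grids).
#' @export
grid_params <- function(n = 96L, voxel = 2) {
  n <- rep(as.integer(n), length.out = 3)
  affine <- diag(c(voxel, voxel, voxel, 1))
  affine[1:3, 4] <- -voxel * (n - 1) / 2
  list(n = n, voxel = voxel, affine = affine)
}

# anterior-posterior position of the sulcus midline at lateral angle psi
sulcus_y_at <- function(psi, sp) {
  sp$y_center + sp$curvature * (1 - cos(pi / 2 * pmin(abs(psi) / sp$psi_max, 1)))
}

# Midline ground-truth points on the outer gray surface.
sulcus_midline_points <- function(shape, sp, n = sp$n_points) {
  rg <- shape$radii["gray", ]
  psi <- seq(-sp$psi_max, sp$psi_max, length.out = n)
  y <- sulcus_y_at(psi, sp)
  tf <- taper_factors(shape, y)
  s <- sqrt(pmax(1 - (y / rg[2])^2, 0))
  cbind(rg[1] * tf$gx * s * sin(psi), y, rg[3] * tf$gz * s * cos(psi))
}

# Analytic tissue label at world points (template frame).
phantom_label_at <- function(pts, shape, sp) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  tf <- taper_factors(shape, y)
  lab <- integer(length(x))
  for (i in seq_len(nrow(shape$radii))) {
    r <- shape$radii[i, ]
    inside <- (x / (r[1] * tf$gx))^2 + (y / r[2])^2 + (z / (r[3] * tf$gz))^2 <= 1
    lab[inside] <- i  # 1=skin .. 6=white
  }
  # neck stub: all-soft-tissue (skin) cylinder below the head
  rs <- shape$radii["skin", ]
  z_top <- -shape$neck_z_frac * rs[3]
  neck <- lab == 0L & z <= z_top & (x^2 + (y + 10)^2) <= shape$neck_radius^2
  lab[neck] <- 1L
  # sulcus groove: CSF cleft around the midline curve, within `depth` of the
  # outer gray surface
  if (sp$depth > 0) {
    rg <- shape$radii["gray", ]
    cand <- lab %in% c(5L, 6L)
    if (any(cand)) {
      xi <- x[cand]; yi <- y[cand]; zi <- z[cand]
      tfi <- taper_factors(shape, yi)
      psi <- atan2(xi / (rg[1] * tfi$gx), zi / (rg[3] * tfi$gz))
      u <- sqrt((xi / (rg[1] * tfi$gx))^2 + (yi / rg[2])^2 + (zi / (rg[3] * tfi$gz))^2)
      dist_below_surface <- (1 - u) * mean(rg)
      hit <- abs(psi) <= sp$psi_max &
        abs(yi - sulcus_y_at(psi, sp)) <= sp$half_width &
        dist_below_surface <= sp$depth & zi > 0
      idx <- which(cand)[hit]
      lab[idx] <- 4L
    }
  }
  lab
}

default_tissue_means <- c(air = 0, skin = 80, fat = 110, skull = 30,
                          csf = 20, gray = 60, white = 90)

phantom_fiducials <- function(shape) {
  rs <- shape$radii["skin", ]
  fiducial_set(nasion = c(0, rs[2], 0), inion = c(0, -rs[2], 0))
}

#' Generate a synthetic head phantom
#'
#' Builds a layered ellipsoidal head with a curved central-sulcus groove and
#' returns the intensity volume, the tissue-label volume and the ground
#' truth (sulcus midline, fiducials, individual-to-template affine).
#'
#' @param shape output of [phantom_shape_params()].
#' @param sulcus output of [sulcus_params()].
#' @param grid output of [grid_params()].
#' @param seed integer seed fixing the intensity noise.
#' @param noise_sd Gaussian intensity noise SD (arbitrary units).
#' @param warp optional 4x4 affine mapping template geometry to this
#'   individual's space (used by [generate_template_pair()]).
#' @return list with `intensity`, `labels` and `truth` (fields `sulcus_gt`,
#'   `template_affine_gt` mapping individual to template, `fiducials`).
#' @export
generate_head_phantom <- function(shape = phantom_shape_params(),
                                  sulcus = sulcus_params(),
                                  grid = grid_params(),
                                  seed = 1L, noise_sd = 5, warp = NULL) {
  d <- grid$n
  ijk <- lin_to_ijk0(seq_len(prod(d)), d)
  pts <- voxel_to_world(grid$affine, ijk)
  if (!is.null(warp)) {
    if (abs(det(warp)) < 1e-12) stop_repe("warp affine is singular", "repe_parameter_error")
    pts_eval <- apply_affine(solve(warp), pts)
  } else pts_eval <- pts
  lab <- array(phantom_label_at(pts_eval, shape, sulcus), d)
  set.seed(derive_seed(seed, 0L))
  vals <- array(default_tissue_means[lab + 1L] + stats::rnorm(prod(d), 0, noise_sd), d)

  mid <- sulcus_midline_points(shape, sulcus)
  fid <- phantom_fiducials(shape)
  if (!is.null(warp)) {
    mid <- apply_affine(warp, mid)
    fid <- fiducial_set(apply_affine(warp, rbind(fid$nasion))[1, ],
                        apply_affine(warp, rbind(fid$inion))[1, ])
    tm_gt <- solve(warp)   # individual -> template
  } else tm_gt <- diag(4)

  truth <- structure(list(sulcus_gt = sulcus_trace(mid, "individual"),
                          template_affine_gt = tm_gt,
                          fiducials = fid,
                          shape = shape, sulcus = sulcus, grid = grid),
                     class = "phantom_truth")
  list(intensity = intensity_volume(vals, grid$affine),
       labels = labeled_volume(lab, grid$affine),
       truth = truth)
}

#' Build an affine from interpretable perturbation parameters
#'
#' Composes translation %*% rotation %*% shear %*% scale (applied in that
#' order to template coordinates).
#'
#' @param scale length-3 scale factors.
#' @param rot_deg length-3 rotation angles about x, y, z (degrees).
#' @param shear length-3 shear coefficients (xy, xz, yz).
#' @param trans length-3 translation (mm).
#' @export
make_affine <- function(scale = c(1, 1, 1), rot_deg = c(0, 0, 0),
                        shear = c(0, 0, 0), trans = c(0, 0, 0)) {
  r <- rot_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  sh <- diag(3); sh[1, 2] <- shear[1]; sh[1, 3] <- shear[2]; sh[2, 3] <- shear[3]
  m <- rz %*% ry %*% rx %*% sh %*% diag(scale)
  out <- diag(4)
  out[1:3, 1:3] <- m
  out[1:3, 4] <- trans
  if (abs(det(out)) < 1e-12) stop_repe("perturbation affine is singular", "repe_parameter_error")
  out
}

#' Generate a template / individual phantom pair with known affine
#'
#' The template carries a 123-point sulcus midline (in template space); the
#' individual is the template geometry warped by a known affine, rendered
#' analytically on its own grid, plus independent intensity noise.
#'
#' @param shape,sulcus,grid phantom parameters (shared geometry).
#' @param perturb 4x4 affine mapping template to individual space
#'   (e.g. from [make_affine()]).
#' @param seed integer seed.
#' @return list with `template` (fields `labels`, `intensity`, `sulcus` with
#'   123 points, `fiducials`) and `individual` (output of
#'   [generate_head_phantom()]; its `truth$template_affine_gt` equals
#'   `solve(perturb)`).
#' @export
generate_template_pair <- function(shape = phantom_shape_params(),
                                   sulcus = sulcus_params(),
                                   grid = grid_params(),
                                   perturb = make_affine(),
                                   seed = 1L) {
  if (abs(det(perturb)) < 1e-12)
    stop_repe("perturbation affine is singular", "repe_parameter_error")
  tpl <- generate_head_phantom(shape, sulcus, grid, seed = derive_seed(seed, 1L))
  tpl_sulcus <- sulcus_trace(sulcus_midline_points(shape, sulcus, n = 123L), "template")
  ind <- generate_head_phantom(shape, sulcus, grid, seed = derive_seed(seed, 2L),
                               warp = perturb)
  list(template = list(labels = tpl$labels, intensity = tpl$intensity,
                       sulcus = tpl_sulcus, fiducials = tpl$truth$fiducials),
       individual = ind)
}

#' Gray-matter ROI masks around the sulcus (S1, M1 and lateral sections)
#'
#' Splits the gray matter near the sulcus into a posterior band (S1,
#' postcentral) and an anterior band (M1, precentral), each `band_mm` wide,
#' and partitions them into `n_sections` equal lateral sections
#' (L, mL, C, mR, R).
#'
#' @param labels a `labeled_volume`.
#' @param truth the phantom's `phantom_truth`.
#' @param band_mm band width on each side of the sulcus, mm.
#' @param n_sections number of lateral sections.
#' @return named list of logical arrays: `S1`, `M1`, and per-section masks
#'   `S1_L`, ..., `M1_R`.
#' @export
roi_masks <- function(labels, truth, band_mm = 15, n_sections = 5L) {
  d <- dim(labels$labels)
  gray <- which(labels$labels == tissue_label("gray"))
  pts <- voxel_to_world(labels$affine, lin_to_ijk0(gray, d))
  curve <- truth$sulcus_gt$points
  nn <- FNN::get.knnx(curve, pts, k = 1)
  near <- nn$nn.dist[, 1] <= sqrt(2) * band_mm
  dy <- pts[, 2] - curve[nn$nn.index[, 1], 2]
  hw <- truth$sulcus$half_width
  s1 <- near & dy < -hw & dy >= -band_mm - hw   # posterior band
  m1 <- near & dy > hw & dy <= band_mm + hw     # anterior band
  # lateral sections by position along the curve
  frac <- (nn$nn.index[, 1] - 1) / (nrow(curve) - 1)
  sec <- pmin(floor(frac * n_sections) + 1L, n_sections)
  sec_names <- if (n_sections == 5L) c("L", "mL", "C", "mR", "R")
               else paste0("s", seq_len(n_sections))
  mk <- function(sel) { m <- array(FALSE, d); m[gray[sel]] <- TRUE; m }
  out <- list(S1 = mk(s1), M1 = mk(m1))
  for (i in seq_len(n_sections)) {
    out[[paste0("S1_", sec_names[i])]] <- mk(s1 & sec == i)
    out[[paste0("M1_", sec_names[i])]] <- mk(m1 & sec == i)
  }
  out
}
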