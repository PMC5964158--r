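# Segmentation of scalp/brain masks and affine normalization.
#
# Brain/scalp extraction is threshold + morphology (any segmentation meeting
# the Dice contract conforms). Affine estimation is moment matching followed
# by affine ICP (point-to-point, then point-to-plane) on sub-voxel level-set
# surface samples. Point mapping through the fitted affine is an exact
# matrix multiply; no volume is ever resampled.

#' Extract brain and scalp masks from an intensity volume
#'
#' The scalp mask is the largest above-air connected component, hole-filled
#' and morphologically closed. The brain mask is the largest high-intensity
#' component strictly interior to the scalp (the low-intensity skull/CSF gap
#' separates it from the skin shell), after a speckle-removing opening.
#'
#' @param vol an `intensity_volume`.
#' @param cfg list with `air_thresh` and `tissue_thresh` (intensity units),
#'   or `method = "auto"` for Otsu-derived thresholds.
#' @return list with `iBrain` and `iScalp` (`binary_mask` objects).
#' @export
extract_brain_and_scalp <- function(vol, cfg = list()) {
  v <- vol$values
  if (!all(is.finite(v))) stop_repe("non-finite intensities", "repe_input_error")
  if (identical(cfg$method, "auto")) {
    # air is the dominant histogram mode; threshold 3 SD above its peak,
    # then Otsu among the remaining tissue intensities
    h <- graphics::hist(v, breaks = 256L, plot = FALSE)
    air_mode <- h$mids[which.max(h$counts)]
    air_sd <- stats::mad(v[abs(v - air_mode) <= 15], center = air_mode)
    air_thresh <- air_mode + 3 * max(air_sd, 1)
    tissue_thresh <- otsu_threshold(v[v > air_thresh])
  } else {
    air_thresh <- cfg$air_thresh %||% 12
    tissue_thresh <- cfg$tissue_thresh %||% 45
  }
  head <- v > air_thresh
  if (!any(head)) stop_repe("no voxels above air threshold", "repe_segmentation_error")
  scalp <- fill_holes6(close6(largest_component6(head), 1L))

  tiss <- v > tissue_thresh & scalp
  tiss <- open6(tiss, 1L)
  if (!any(tiss)) stop_repe("no voxels above tissue threshold", "repe_segmentation_error")
  lab <- label_components6(tiss)
  # drop components touching the head exterior (the skin/fat shell)
  exterior <- dilate6(!scalp, 1L)
  touching <- unique(lab[lab > 0L & exterior])
  sizes <- tabulate(lab[lab > 0L])
  sizes[touching] <- 0L
  if (all(sizes == 0L)) stop_repe("no interior brain component found", "repe_segmentation_error")
  brain <- dilate6(lab == which.max(sizes), 1L) & scalp
  list(iBrain = binary_mask(brain, vol$affine, "iBrain"),
       iScalp = binary_mask(scalp, vol$affine, "iScalp"))
}

mask_world_coords <- function(bm) {
  voxel_to_world(bm$affine, lin_to_ijk0(which(bm$mask), dim(bm$mask)))
}

sqrtm_sym <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

mask_boundary_coords <- function(bm) {
  b <- bm$mask & !erode6(bm$mask)
  voxel_to_world(bm$affine, lin_to_ijk0(which(b), dim(bm$mask)))
}

# Sub-voxel surface samples: boundary voxel centres Newton-projected onto the
# 0.5 level set of the Gaussian-smoothed mask, plus outward-ish normals there.
# Removes the half-voxel phase bias of raw boundary voxel centres.
subvoxel_boundary <- function(bm, sigma = 1.5, steps = 3L) {
  G <- gauss_smooth3(bm$mask + 0, sigma)
  gr <- grad3(G)
  b <- bm$mask & !erode6(bm$mask)
  pts <- voxel_to_world(bm$affine, lin_to_ijk0(which(b), dim(bm$mask)))
  vox <- mean(abs(diag(bm$affine)[1:3]))
  g1 <- g2 <- g3 <- NULL
  for (s in seq_len(steps)) {
    gv <- interp_trilinear(G, bm$affine, pts)
    g1 <- interp_trilinear(gr[[1]], bm$affine, pts) / vox
    g2 <- interp_trilinear(gr[[2]], bm$affine, pts) / vox
    g3 <- interp_trilinear(gr[[3]], bm$affine, pts) / vox
    gm2 <- pmax(g1^2 + g2^2 + g3^2, 1e-12)
    corr <- (gv - 0.5) / gm2
    pts <- pts - cbind(corr * g1, corr * g2, corr * g3)
  }
  n <- cbind(g1, g2, g3) / sqrt(pmax(g1^2 + g2^2 + g3^2, 1e-12))
  list(pts = pts, normals = n)
}

grad3 <- function(a) {
  list((shift_array(a, -1, 1) - shift_array(a, 1, 1)) / 2,
       (shift_array(a, -1, 2) - shift_array(a, 1, 2)) / 2,
       (shift_array(a, -1, 3) - shift_array(a, 1, 3)) / 2)
}

#' Fit a 12-parameter affine between two binary masks
#'
#' Estimates the world-mm affine mapping the moving mask (e.g. iBrain) onto
#' the fixed mask (e.g. the template brain). Three stages: moment matching
#' (centroid + covariance, symmetric square-root) for the initialization; a
#' few point-to-point ICP iterations on sub-voxel surface samples
#' (closed-form least-squares update of all 12 parameters); then
#' point-to-plane ICP against the smoothed fixed mask's 0.5 level set, which
#' resolves the tangential components (rotations, shears) that point
#' matching alone cannot. Surface samples are boundary voxel centres
#' Newton-projected onto the level set, removing half-voxel phase bias.
#'
#' @param moving,fixed `binary_mask` objects.
#' @param iters_point,iters_plane iteration caps for the two ICP stages.
#' @param trim fraction of best-matching boundary points kept per iteration.
#' @return an `affine_transform` mapping moving to fixed world coordinates.
#' @export
fit_affine <- function(moving, fixed, iters_point = 10L, iters_plane = 50L,
                       trim = 0.98) {
  mp <- mask_world_coords(moving)
  fp <- mask_world_coords(fixed)
  if (nrow(mp) < 4L || nrow(fp) < 4L) stop_repe("degenerate mask", "repe_registration_error")
  Cm <- stats::cov(mp); Cf <- stats::cov(fp)
  if (min(eigen(Cm, symmetric = TRUE, only.values = TRUE)$values) < 1e-6)
    stop_repe("moving mask has coplanar support", "repe_registration_error")
  A <- sqrtm_sym(Cf) %*% solve(sqrtm_sym(Cm))
  tt <- colMeans(fp) - as.numeric(A %*% colMeans(mp))

  mbs <- subvoxel_boundary(moving)
  fbs <- subvoxel_boundary(fixed)
  mb <- mbs$pts
  fb <- fbs$pts
  N <- fbs$normals

  mb1 <- cbind(mb, 1)
  total <- iters_point + iters_plane
  for (it in seq_len(total)) {
    moved <- sweep(mb %*% t(A), 2, tt, "+")
    nn <- FNN::get.knnx(fb, moved, k = 1)
    keep <- nn$nn.dist[, 1] <= stats::quantile(nn$nn.dist[, 1], trim)
    q <- fb[nn$nn.index[, 1], , drop = FALSE]
    if (it <= iters_point) {
      B <- qr.solve(mb1[keep, , drop = FALSE], q[keep, , drop = FALSE])
      Anew <- t(B[1:3, ]); tnew <- B[4, ]
    } else {
      p <- mb[keep, , drop = FALSE]
      nk <- N[nn$nn.index[keep, 1], , drop = FALSE]
      qk <- q[keep, , drop = FALSE]
      X <- cbind(nk[, 1] * p, nk[, 2] * p, nk[, 3] * p, nk)
      sol <- qr.solve(X, rowSums(nk * qk))
      Anew <- matrix(sol[1:9], 3, 3, byrow = TRUE); tnew <- sol[10:12]
    }
    delta <- max(abs(Anew - A), abs(tnew - tt))
    A <- Anew; tt <- tnew
    if (delta < 1e-10 && it > iters_point) break
  }
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- tt
  affine_transform(m)
}

#' Map a template-space sulcus trace into individual space
#'
#' Applies the inverse of the individual-to-template transform to every
#' point; order and count are preserved.
#'
#' @param mni_cs a `sulcus_trace` with `space == "template"`.
#' @param tm an `affine_transform` (individual -> template).
#' @return a `sulcus_trace` in individual space.
#' @export
map_template_sulcus <- function(mni_cs, tm) {
  if (!inherits(mni_cs, "sulcus_trace") || mni_cs$space != "template")
    stop_repe("expected a template-space trace", "repe_input_error")
  inv <- tryCatch(solve(tm$matrix),
                  error = function(e) stop_repe("singular transform", "repe_transform_error"))
  sulcus_trace(apply_affine(inv, mni_cs$points), "individual")
}

#' Dice coefficient between two logical arrays
#' @param a,b logical arrays of identical dimension.
#' @export
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

#' Write/read a 4x4 affine as a FLIRT-style plain-text matrix
#' @param tm an `affine_transform` (or 4x4 matrix).
#' @param path output path.
#' @export
write_affine <- function(tm, path) {
  m <- if (inherits(tm, "affine_transform")) tm$matrix else tm
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  affine_transform(unname(as.matrix(utils::read.table(path))))
}
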