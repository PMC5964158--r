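# Scalp-distance placement sheet and (re)positioning error simulation.
#
# On-surface distances emulate the clinical flexible-meter procedure:
# Dijkstra over the triangulation's edge graph gives an initial path, which
# is then straightened on the surface (iterative midpoint relaxation with
# reprojection). The raw edge-graph metric overestimates true geodesics by
# a few percent and is anisotropic (the tetrahedral split has a chirality);
# straightening removes most of both errors (sphere great circles agree to
# well under 1%).

# curve-shortening on the mesh: relax interior points toward their
# neighbours' midpoint, reproject onto the surface, resample evenly
straighten_on_surface <- function(surf, pts, iters = 40L, spacing = NULL,
                                  rel_tol = 1e-5) {
  if (is.null(spacing)) spacing <- max(mean(rownorms(diff(pts))), 1)
  len_prev <- sum(rownorms(diff(pts)))
  for (it in seq_len(iters)) {
    s <- c(0, cumsum(rownorms(diff(pts))))
    n_out <- max(ceiling(s[length(s)] / spacing) + 1, 5)
    pts <- interp_polyline(pts, s, seq(0, s[length(s)], length.out = n_out))
    n <- nrow(pts)
    prev <- pts[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
    nxt <- pts[pmin(seq_len(n) + 1L, n), , drop = FALSE]
    mid <- (prev + nxt) / 2
    mid[1, ] <- pts[1, ]; mid[n, ] <- pts[n, ]
    relaxed <- 0.5 * pts + 0.5 * mid
    pts <- closest_point_mesh(relaxed, surf)$points
    pts[1, ] <- relaxed[1, ]; pts[n, ] <- relaxed[n, ]
    len <- sum(rownorms(diff(pts)))
    if (abs(len - len_prev) < rel_tol * len_prev && it > 3L) break
    len_prev <- len
  }
  pts
}

snap_to_vertices <- function(surf, pts, tol = 5) {
  nn <- FNN::get.knnx(surf$vertices, as_points(pts), k = 1)
  if (any(nn$nn.dist[, 1] > tol))
    stop_repe(sprintf("point %.1f mm from surface (tol %.1f)",
                      max(nn$nn.dist[, 1]), tol), "repe_snap_error")
  nn$nn.index[, 1]
}

#' On-surface (geodesic) distance between two points
#'
#' Dijkstra shortest path over the mesh edge graph, endpoints snapped to
#' their nearest vertices.
#'
#' @param surf a `scalp_surface` (ideally from [with_mesh_graph()]).
#' @param a,b 3-vectors (mm), within `tol` of the surface.
#' @param tol snap tolerance, mm.
#' @return distance in mm.
#' @export
geodesic_distance <- function(surf, a, b, tol = 5) {
  v <- snap_to_vertices(surf, rbind(a, b), tol)
  if (v[1] == v[2]) return(0)
  g <- mesh_graph(surf)
  sp <- igraph::shortest_paths(g, v[1], v[2], output = "vpath")$vpath[[1]]
  pts <- surf$vertices[as.integer(sp), , drop = FALSE]
  # endpoints: exact surface projections of the queries, not snapped
  # vertices (removes up-to-one-voxel endpoint quantization)
  ends <- closest_point_mesh(rbind(a, b), surf)$points
  pts[1, ] <- ends[1, ]
  pts[nrow(pts), ] <- ends[2, ]
  pts <- straighten_on_surface(surf, pts)
  sum(rownorms(diff(pts)))
}

#' Midline path from nasion to inion
#'
#' The flexible meter runs along the midsagittal line, so the path is the
#' shortest path restricted to vertices near the x = 0 plane (plus the
#' endpoints). Returns the ordered path vertices and cumulative arc length.
#'
#' @param surf a `scalp_surface`.
#' @param fid a `fiducial_set`.
#' @param band half-width of the sagittal corridor, mm.
#' @return list with `points` (k x 3, straightened path), `s` (cumulative
#'   mm), `length` (total mm).
#' @export
scalp_midline <- function(surf, fid, band = 10) {
  v <- snap_to_vertices(surf, rbind(fid$nasion, fid$inion))
  # corridor: near the midsagittal plane AND not below the fiducials (the
  # meter runs over the crown, never under the chin)
  z_floor <- min(fid$nasion[3], fid$inion[3]) - band / 2
  keep <- which(abs(surf$vertices[, 1]) <= band & surf$vertices[, 3] >= z_floor)
  keep <- union(keep, v)
  g <- mesh_graph(surf)
  sg <- igraph::induced_subgraph(g, keep)
  from <- match(v[1], keep); to <- match(v[2], keep)
  sp <- igraph::shortest_paths(sg, from, to, output = "vpath")$vpath[[1]]
  if (length(sp) == 0) stop_repe("no midline path found", "repe_geometry_error")
  vids <- keep[as.integer(sp)]
  pts <- surf$vertices[vids, , drop = FALSE]
  ends <- closest_point_mesh(rbind(fid$nasion, fid$inion), surf)$points
  pts[1, ] <- ends[1, ]
  pts[nrow(pts), ] <- ends[2, ]
  pts <- straighten_on_surface(surf, pts)
  s <- c(0, cumsum(rownorms(diff(pts))))
  list(points = pts, s = s, length = s[length(s)])
}

#' Compute the placement sheet (N-I and N-electrode scalp distances)
#'
#' RePE-S1_C is the electrode footprint point nearest the N-I midline;
#' RePE-S1_L/R are the footprint endpoints. d(N, C) is measured along the
#' midline (the meter is laid along N-I and the electrode centre is marked
#' at that distance); d(N, L) and d(N, R) are unconstrained on-surface
#' distances.
#'
#' @param surf a `scalp_surface`.
#' @param fid a `fiducial_set`.
#' @param footprint n x 3 matrix: the electrode's scalp footprint polyline.
#' @param max_offset_mm error if the footprint's closest approach to the
#'   midline exceeds this.
#' @return a `placement_sheet`: `d_NI`, `d_N_C`, `d_N_L`, `d_N_R` (mm) and
#'   the three anchor points.
#' @export
compute_placement_sheet <- function(surf, fid, footprint, max_offset_mm = 30) {
  footprint <- as_points(footprint)
  ml <- scalp_midline(surf, fid)
  nn <- FNN::get.knnx(ml$points, footprint, k = 1)
  ic <- which.min(nn$nn.dist[, 1])
  if (nn$nn.dist[ic, 1] > max_offset_mm)
    stop_repe("electrode footprint does not reach the midline", "repe_placement_error")
  p_c <- footprint[ic, ]
  d_nc <- ml$s[nn$nn.index[ic, 1]]
  left_first <- footprint[1, 1] <= footprint[nrow(footprint), 1]
  p_l <- if (left_first) footprint[1, ] else footprint[nrow(footprint), ]
  p_r <- if (left_first) footprint[nrow(footprint), ] else footprint[1, ]
  structure(list(
    d_NI = ml$length,
    d_N_C = d_nc,
    d_N_L = geodesic_distance(surf, fid$nasion, p_l),
    d_N_R = geodesic_distance(surf, fid$nasion, p_r),
    center = p_c, left = p_l, right = p_r), class = "placement_sheet")
}

#' @export
print.placement_sheet <- function(x, ...) {
  cat(sprintf(paste0("<placement_sheet> (scalp distances, mm)\n",
                     "  N-I   %7.1f\n  N-C   %7.1f\n  N-L   %7.1f\n  N-R   %7.1f\n"),
              x$d_NI, x$d_N_C, x$d_N_L, x$d_N_R))
  invisible(x)
}

#' Marker points along the electrode edge (central + 13 left + 13 right)
#'
#' Resamples the footprint polyline at 5 mm spacing around its arc-length
#' midpoint, giving the 27 standard test points.
#'
#' @param footprint n x 3 scalp footprint polyline (mm).
#' @param n_side points on each side of the central point.
#' @param spacing_mm spacing along the electrode edge.
#' @return (2 * n_side + 1) x 3 matrix.
#' @export
repe_points <- function(footprint, n_side = 13L, spacing_mm = 5) {
  footprint <- as_points(footprint)
  seg <- rownorms(diff(footprint))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  need <- 2 * n_side * spacing_mm
  if (total < need)
    stop_repe(sprintf("footprint too short (%.0f mm < %.0f mm)", total, need),
              "repe_input_error")
  want <- total / 2 + seq(-n_side, n_side) * spacing_mm
  interp_polyline(footprint, s, want)
}

interp_polyline <- function(pts, s, want) {
  idx <- findInterval(want, s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(s) - 1L)
  f <- (want - s[idx]) / (s[idx + 1] - s[idx])
  pts[idx, , drop = FALSE] + f * (pts[idx + 1, , drop = FALSE] - pts[idx, , drop = FALSE])
}

#' Simulate repeated electrode positioning with placement noise
#'
#' Each repetition displaces the ground-truth marker points by seeded
#' per-axis Gaussian noise plus an optional systematic shift, then re-snaps
#' them to the scalp surface (an electrode always sits on the scalp).
#'
#' @param points_gt m x 3 ground-truth marker points (e.g. [repe_points()]).
#' @param surf a `scalp_surface` for re-snapping (NULL to skip snapping).
#' @param n_reps number of repetitions.
#' @param sd_mm length-3 per-axis noise SD (mm).
#' @param shift_mm systematic shift: a 3-vector applied to every repetition,
#'   or an n_reps x 3 matrix (one row per repetition).
#' @param seed integer seed.
#' @return list of m x 3 matrices, one per repetition.
#' @export
simulate_repositioning <- function(points_gt, surf = NULL, n_reps = 5L,
                                   sd_mm = c(2, 2, 2), shift_mm = c(0, 0, 0),
                                   seed = 1L) {
  points_gt <- as_points(points_gt)
  if (n_reps < 1L) stop_repe("n_reps must be >= 1", "repe_parameter_error")
  sd_mm <- rep(as.numeric(sd_mm), length.out = 3)
  if (any(sd_mm < 0)) stop_repe("negative noise sd", "repe_parameter_error")
  if (is.null(dim(shift_mm))) shift_mm <- matrix(shift_mm, n_reps, 3, byrow = TRUE)
  set.seed(derive_seed(seed, 3L))
  m <- nrow(points_gt)
  lapply(seq_len(n_reps), function(k) {
    noise <- matrix(stats::rnorm(3 * m), m, 3) %*% diag(sd_mm)
    pts <- points_gt + noise
    pts <- sweep(pts, 2, shift_mm[k, ], "+")
    if (!is.null(surf)) pts <- closest_point_mesh(pts, surf)$points
    pts
  })
}

#' Positioning error of repeated placements against a reference trace
#'
#' For every marker point of every repetition: Euclidean distance to the
#' nearest point of the reference (scalp-projected sulcus) trace, plus
#' per-axis deltas against the matched reference points.
#'
#' @param reps list of m x 3 matrices (repetitions).
#' @param reference a `sulcus_trace` (scalp space) or n x 3 matrix.
#' @return a `positioning_report`: data.frame `per_rep` (mean, sd per
#'   repetition; per-axis mean deltas), `overall_mean`, `overall_sd`, and
#'   `deltas` (long data.frame: rep, point, axis, delta).
#' @export
positioning_error <- function(reps, reference) {
  ref <- if (inherits(reference, "sulcus_trace")) reference$points else as_points(reference)
  if (nrow(ref) < 1) stop_repe("empty reference", "repe_input_error")
  if (length(reps) < 1) stop_repe("no repetitions", "repe_input_error")
  per <- lapply(seq_along(reps), function(k) {
    pts <- as_points(reps[[k]])
    nn <- FNN::get.knnx(ref, pts, k = 1)
    dd <- pts - ref[nn$nn.index[, 1], , drop = FALSE]
    data.frame(rep = k, point = seq_len(nrow(pts)),
               dist = nn$nn.dist[, 1], dx = dd[, 1], dy = dd[, 2], dz = dd[, 3])
  })
  long <- do.call(rbind, per)
  per_rep <- do.call(rbind, lapply(split(long, long$rep), function(df) {
    data.frame(rep = df$rep[1], mean_dist = mean(df$dist), sd_dist = stats::sd(df$dist),
               dx = mean(df$dx), dy = mean(df$dy), dz = mean(df$dz))
  }))
  structure(list(per_rep = per_rep,
                 overall_mean = mean(per_rep$mean_dist),
                 overall_sd = stats::sd(per_rep$mean_dist),
                 deltas = long),
            class = "positioning_report")
}

#' @export
print.positioning_report <- function(x, ...) {
  cat(sprintf("<positioning_report> %d repetitions, error %.2f +/- %.2f mm\n",
              nrow(x$per_rep), x$overall_mean,
              ifelse(is.na(x$overall_sd), 0, x$overall_sd)))
  invisible(x)
}
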