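# Triangulated scalp surface from a binary mask, and mesh utilities.
#
# Iso-surface extraction uses marching tetrahedra on the Gaussian-smoothed
# mask (iso level 0.5): each grid cube is split into the standard six
# tetrahedra around the main diagonal, which share face diagonals across
# neighbouring cubes, so the result is a closed 2-manifold without the
# ambiguous cases of classic marching cubes. Smoothing the binary mask first
# places interpolated vertices close to the true underlying surface, so
# areas converge (a voxelized ball's raw boundary area would be ~50% high).

# 6-tet decomposition of a cube around the 0-7 diagonal; corners numbered by
# bits (x = 1, y = 2, z = 4).
tet_corner_table <- rbind(
  c(0L, 1L, 5L, 7L), c(0L, 5L, 4L, 7L), c(0L, 4L, 6L, 7L),
  c(0L, 6L, 2L, 7L), c(0L, 2L, 3L, 7L), c(0L, 3L, 1L, 7L))

# per inside-pattern triangle table: list over pattern 1..14 of an integer
# matrix, each row a triangle given as 6 local corner ids = 3 edges (a,b)
tet_tri_table <- local({
  tbl <- vector("list", 15L)
  for (p in 1:14) {
    ins <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) > 0L)
    out <- setdiff(1:4, ins)
    if (length(ins) == 1L) {
      a <- ins
      tbl[[p]] <- matrix(c(a, out[1], a, out[2], a, out[3]), nrow = 1)
    } else if (length(ins) == 3L) {
      a <- out
      tbl[[p]] <- matrix(c(a, ins[1], a, ins[2], a, ins[3]), nrow = 1)
    } else {
      a <- ins[1]; b <- ins[2]; c <- out[1]; d <- out[2]
      tbl[[p]] <- rbind(c(a, c, a, d, b, d),
                        c(a, c, b, d, b, c))
    }
  }
  tbl
})

#' Triangulate the outer surface of a binary mask
#'
#' Marching tetrahedra on the smoothed mask at iso level 0.5, in world
#' coordinates. The output is a closed, consistently outward-oriented
#' triangle mesh.
#'
#' @param mask a `binary_mask` (or 3D logical array with `affine` given).
#' @param affine 4x4 voxel-to-world matrix when `mask` is a plain array.
#' @param sigma Gaussian pre-smoothing in voxels.
#' @return a `scalp_surface`: `vertices` (n x 3 mm), `triangles` (m x 3
#'   indices), `areas` (per-triangle mm^2).
#' @export
surface_from_mask <- function(mask, affine = NULL, sigma = 1) {
  if (inherits(mask, "binary_mask")) { affine <- mask$affine; mask <- mask$mask }
  if (is.null(affine)) stop_repe("affine required", "repe_input_error")
  d <- dim(mask)
  f <- gauss_smooth3(mask + 0, sigma)
  iso <- 0.5
  f[f == iso] <- iso + 1e-9
  inside <- f > iso

  # active cubes: mixed-sign corners
  sub <- function(a, ox, oy, oz)
    a[(1 + ox):(d[1] - 1 + ox), (1 + oy):(d[2] - 1 + oy), (1 + oz):(d[3] - 1 + oz)]
  cnt <- array(0L, d - 1L)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1)
    cnt <- cnt + sub(inside, cx, cy, cz)
  active <- which(cnt > 0L & cnt < 8L)
  if (length(active) == 0L) stop_repe("no surface found", "repe_geometry_error")
  ijk <- lin_to_ijk0(active, d - 1L)  # 0-based cube origin
  base_lin <- 1L + ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
  corner_off <- integer(8)
  for (c in 0:7) {
    corner_off[c + 1] <- bitwAnd(c, 1L) + d[1] * (bitwAnd(c, 2L) %/% 2L +
                         d[2] * (bitwAnd(c, 4L) %/% 4L))
  }

  corner_xyz <- cbind(bitwAnd(0:7, 1L), bitwAnd(0:7, 2L) %/% 2L,
                      bitwAnd(0:7, 4L) %/% 4L)
  key <- function(a, b) pmin(a, b) * (prod(d) + 1) + pmax(a, b)
  tris <- NULL       # rows of 3 edge keys
  oin <- oout <- NULL  # in/out corner centroids, 0-based ijk
  for (tq in seq_len(nrow(tet_corner_table))) {
    gid <- matrix(0L, length(active), 4L)
    for (j in 1:4) gid[, j] <- base_lin + corner_off[tet_corner_table[tq, j] + 1L]
    fin <- matrix(inside[gid], ncol = 4L)
    pat <- as.integer(fin %*% c(1L, 2L, 4L, 8L))
    for (p in 1:14) {
      rows <- which(pat == p)
      if (length(rows) == 0L) next
      tt <- tet_tri_table[[p]]
      ins <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) > 0L)
      out <- setdiff(1:4, ins)
      off_in <- colMeans(corner_xyz[tet_corner_table[tq, ins] + 1L, , drop = FALSE])
      off_out <- colMeans(corner_xyz[tet_corner_table[tq, out] + 1L, , drop = FALSE])
      cin <- sweep(ijk[rows, , drop = FALSE], 2, off_in, "+")
      cot <- sweep(ijk[rows, , drop = FALSE], 2, off_out, "+")
      for (r in seq_len(nrow(tt))) {
        g1a <- gid[rows, tt[r, 1]]; g1b <- gid[rows, tt[r, 2]]
        g2a <- gid[rows, tt[r, 3]]; g2b <- gid[rows, tt[r, 4]]
        g3a <- gid[rows, tt[r, 5]]; g3b <- gid[rows, tt[r, 6]]
        tris <- rbind(tris, cbind(key(g1a, g1b), key(g2a, g2b), key(g3a, g3b)))
        oin <- rbind(oin, cin)
        oout <- rbind(oout, cot)
      }
    }
  }
  ukeys <- unique(as.vector(tris))
  vid <- matrix(match(as.vector(tris), ukeys), ncol = 3L)
  ua <- ukeys %/% (prod(d) + 1)
  ub <- ukeys %% (prod(d) + 1)
  fa <- f[ua]; fb <- f[ub]
  tfrac <- (iso - fa) / (fb - fa)
  pa <- voxel_to_world(affine, lin_to_ijk0(ua, d))
  pb <- voxel_to_world(affine, lin_to_ijk0(ub, d))
  verts <- pa + tfrac * (pb - pa)

  # orientation: normal must point from the inside corners towards the
  # outside corners of the generating tetrahedron
  v1 <- verts[vid[, 1], ]; v2 <- verts[vid[, 2], ]; v3 <- verts[vid[, 3], ]
  e1 <- v2 - v1; e2 <- v3 - v1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  dirv <- voxel_to_world(affine, oout) - voxel_to_world(affine, oin)
  flip <- nx * dirv[, 1] + ny * dirv[, 2] + nz * dirv[, 3] < 0
  vid[flip, c(2, 3)] <- vid[flip, c(3, 2)]

  area <- 0.5 * sqrt(nx^2 + ny^2 + nz^2)
  structure(list(vertices = verts, triangles = vid, areas = area),
            class = "scalp_surface")
}

#' @export
print.scalp_surface <- function(x, ...) {
  cat(sprintf("<scalp_surface> %d vertices, %d triangles, area %.1f cm^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas) / 100))
  invisible(x)
}

#' Total mesh area (mm^2)
#' @param surf a `scalp_surface`.
#' @export
mesh_area <- function(surf) sum(surf$areas)

# unique undirected edges as a 2-column matrix of vertex ids
mesh_edges <- function(surf) {
  tr <- surf$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e[, 1] * (nrow(surf$vertices) + 1) + e[, 2]), , drop = FALSE]
}

#' Euler characteristic V - E + F of a mesh
#' @param surf a `scalp_surface`.
#' @export
mesh_euler <- function(surf) {
  nrow(surf$vertices) - nrow(mesh_edges(surf)) + nrow(surf$triangles)
}

#' Check that every edge is shared by exactly two triangles
#' @param surf a `scalp_surface`.
#' @export
mesh_is_closed_manifold <- function(surf) {
  tr <- surf$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(surf$vertices) + 1) + pmax(e[, 1], e[, 2])
  all(table(key) == 2L)
}

# cached igraph over mesh edges, weights = Euclidean length
mesh_graph <- function(surf) {
  g <- attr(surf, "graph")
  if (!is.null(g)) return(g)
  e <- mesh_edges(surf)
  w <- rownorms(surf$vertices[e[, 1], , drop = FALSE] -
                surf$vertices[e[, 2], , drop = FALSE])
  g <- igraph::make_graph(edges = as.numeric(t(e)), n = nrow(surf$vertices),
                          directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Attach the cached edge graph to a surface (idempotent)
#' @param surf a `scalp_surface`.
#' @export
with_mesh_graph <- function(surf) {
  if (is.null(attr(surf, "graph"))) attr(surf, "graph") <- mesh_graph(surf)
  surf
}

#' Export a surface as ASCII PLY
#' @param surf a `scalp_surface`.
#' @param path output file.
#' @export
write_ply <- function(surf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(surf$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(surf$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(surf$vertices, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, surf$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- exact closest point on a triangle mesh (Eberly's region algorithm) ----

# closest points from a single point p to all triangles (A, B, C matrices);
# returns list(dist2, points)
closest_on_triangles <- function(p, A, B, C) {
  E0 <- B - A; E1 <- C - A
  D <- cbind(A[, 1] - p[1], A[, 2] - p[2], A[, 3] - p[3])
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  d <- rowSums(E0 * D);  e <- rowSums(E1 * D)
  det <- pmax(a * c - b * b, 1e-300)
  s <- b * e - c * d
  t <- b * d - a * e
  # region classification (vectorized Eberly)
  sf <- s; tf <- t
  r1 <- s + t <= det
  # region 4: s<0, t<0
  reg4 <- r1 & s < 0 & t < 0
  # region 3: s<0, t>=0
  reg3 <- r1 & s < 0 & t >= 0
  # region 5: s>=0, t<0
  reg5 <- r1 & s >= 0 & t < 0
  # region 0 interior
  reg0 <- r1 & s >= 0 & t >= 0
  # outside: s<0 -> region 2; t<0 -> region 6; else region 1
  reg2 <- !r1 & s < 0
  reg6 <- !r1 & t < 0
  reg1 <- !r1 & s >= 0 & t >= 0

  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  sf[reg0] <- (s / det)[reg0]; tf[reg0] <- (t / det)[reg0]
  if (any(reg3)) { sf[reg3] <- 0; tf[reg3] <- clamp01((-e / c)[reg3]) }
  if (any(reg5)) { tf[reg5] <- 0; sf[reg5] <- clamp01((-d / a)[reg5]) }
  if (any(reg4)) {
    i <- reg4
    use_s <- d[i] < 0
    sf[i] <- ifelse(use_s, clamp01((-d / a)[i]), 0)
    tf[i] <- ifelse(use_s, 0, clamp01((-e / c)[i]))
  }
  if (any(reg1)) {
    i <- reg1
    numer <- (c + e - b - d)[i]
    denom <- (a - 2 * b + c)[i]
    sf[i] <- clamp01(ifelse(denom > 0, numer / denom, 0))
    tf[i] <- 1 - sf[i]
  }
  if (any(reg2)) {
    i <- reg2
    tmp0 <- (b + d)[i]; tmp1 <- (c + e)[i]
    on_edge01 <- tmp1 > tmp0
    numer <- (tmp1 - tmp0)
    denom <- (a - 2 * b + c)[i]
    sf[i] <- ifelse(on_edge01, clamp01(ifelse(denom > 0, numer / denom, 1)), 0)
    tf[i] <- ifelse(on_edge01, 1 - sf[i], clamp01((-e / c)[i]))
  }
  if (any(reg6)) {
    i <- reg6
    tmp0 <- (b + e)[i]; tmp1 <- (a + d)[i]
    on_edge01 <- tmp1 > tmp0
    numer <- (tmp1 - tmp0)
    denom <- (a - 2 * b + c)[i]
    tf[i] <- ifelse(on_edge01, clamp01(ifelse(denom > 0, numer / denom, 1)), 0)
    sf[i] <- ifelse(on_edge01, 1 - tf[i], clamp01((-d / a)[i]))
  }
  q <- A + sf * E0 + tf * E1
  dd <- cbind(q[, 1] - p[1], q[, 2] - p[2], q[, 3] - p[3])
  list(dist2 = rowSums(dd * dd), points = q)
}

#' Closest points on a mesh for a set of query points
#'
#' Exact brute-force nearest point-to-triangle search over all triangles,
#' with a vertex-kNN pre-filter for speed. Ties break to the lowest
#' triangle index.
#'
#' @param pts n x 3 query points (mm).
#' @param surf a `scalp_surface`.
#' @param k_filter number of nearest vertices used to pre-select candidate
#'   triangles; set `Inf` for pure brute force over every triangle.
#' @return list with `points` (n x 3 projections), `dist` (mm),
#'   `triangle` (indices).
#' @export
closest_point_mesh <- function(pts, surf, k_filter = 40L) {
  pts <- as_points(pts)
  V <- surf$vertices; Tr <- surf$triangles
  A <- V[Tr[, 1], , drop = FALSE]
  B <- V[Tr[, 2], , drop = FALSE]
  C <- V[Tr[, 3], , drop = FALSE]
  out_p <- matrix(0, nrow(pts), 3)
  out_d <- numeric(nrow(pts))
  out_t <- integer(nrow(pts))
  use_filter <- is.finite(k_filter) && nrow(Tr) > 2000L
  if (use_filter) {
    # map vertex -> incident triangles
    vt <- split(rep(seq_len(nrow(Tr)), 3L), as.vector(Tr))
    nnv <- FNN::get.knnx(V, pts, k = min(k_filter, nrow(V)))
  }
  for (i in seq_len(nrow(pts))) {
    if (use_filter) {
      cand <- unique(unlist(vt[as.character(nnv$nn.index[i, ])], use.names = FALSE))
      cand <- sort(cand)
      r <- closest_on_triangles(pts[i, ], A[cand, , drop = FALSE],
                                B[cand, , drop = FALSE], C[cand, , drop = FALSE])
      j <- which.min(r$dist2)
      out_t[i] <- cand[j]
    } else {
      r <- closest_on_triangles(pts[i, ], A, B, C)
      j <- which.min(r$dist2)
      out_t[i] <- j
    }
    out_p[i, ] <- r$points[j, ]
    out_d[i] <- sqrt(r$dist2[j])
  }
  list(points = out_p, dist = out_d, triangle = out_t)
}
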