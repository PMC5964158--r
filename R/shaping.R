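# From the individual sulcus trace to the printable electrode outline.

#' Project a sulcus trace onto the scalp surface by minimal distance
#'
#' Each point is replaced by its (exact) nearest point on the triangulated
#' scalp; order and count are preserved. Projection is idempotent.
#'
#' @param ics a `sulcus_trace` in individual space.
#' @param surf a `scalp_surface`.
#' @param require_inside error if a point lies outside the closed surface
#'   (checked by ray parity).
#' @return a `sulcus_trace` with `space = "scalp"`; the per-point projection
#'   distances are in `attr(, "distance")`.
#' @export
project_to_scalp <- function(ics, surf, require_inside = TRUE) {
  pts <- ics$points
  if (require_inside && !all(points_inside_mesh(pts, surf)))
    stop_repe("sulcus point outside the scalp surface", "repe_projection_error")
  r <- closest_point_mesh(pts, surf)
  out <- sulcus_trace(dedupe_consecutive(r$points), "scalp")
  attr(out, "distance") <- r$dist
  out
}

# drop exactly-coincident consecutive projections (can happen when two
# close input points hit the same triangle vertex)
dedupe_consecutive <- function(pts) {
  if (nrow(pts) < 2L) return(pts)
  keep <- c(TRUE, rownorms(diff(pts)) > 0)
  pts[keep, , drop = FALSE]
}

# parity test with majority vote over three fixed irrational ray
# directions (a single axis-aligned ray can graze shared mesh vertices and
# miscount)
points_inside_mesh <- function(pts, surf) {
  dirs <- rbind(c(0.8017837, 0.5345225, 0.2672612),
                c(-0.3713907, 0.7427814, 0.5570860),
                c(0.4558423, -0.2279212, 0.8603429))
  votes <- vapply(1:3, function(k) ray_parity(pts, surf, dirs[k, ]),
                  logical(nrow(pts)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  rowSums(votes) >= 2
}

ray_parity <- function(pts, surf, dir) {
  V <- surf$vertices; Tr <- surf$triangles
  A <- V[Tr[, 1], , drop = FALSE]
  B <- V[Tr[, 2], , drop = FALSE]
  C <- V[Tr[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  # Moller-Trumbore, vectorized over triangles
  pvec <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
                dir[3] * e2[, 1] - dir[1] * e2[, 3],
                dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pvec)
  ok0 <- abs(det) > 1e-12
  vapply(seq_len(nrow(pts)), function(i) {
    tv <- cbind(pts[i, 1] - A[, 1], pts[i, 2] - A[, 2], pts[i, 3] - A[, 3])
    u <- rowSums(tv * pvec) / det
    qvec <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                  tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                  tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    v <- qvec[, 1] * dir[1] + qvec[, 2] * dir[2] + qvec[, 3] * dir[3]
    v <- v / det
    tt <- rowSums(e2 * qvec) / det
    hits <- ok0 & u >= 0 & v >= 0 & (u + v) <= 1 & tt > 1e-9
    sum(hits) %% 2L == 1L
  }, logical(1))
}

#' Flatten a scalp trace to a plane
#'
#' Default method is arc-length unrolling: point i maps to
#' (cumulative chord length, 0, 0), so the planar trace has exactly the 3D
#' polyline length (an isometry along the trace -- what a printed electrode
#' wrapped on the scalp needs). `method = "pca"` instead projects
#' orthogonally onto the best-fit plane (foreshortens; for comparison only).
#'
#' @param icss a `sulcus_trace` with `space = "scalp"` (or any 3D trace).
#' @param method `"arclength"` (default) or `"pca"`.
#' @return a `sulcus_trace` with `space = "plane"`.
#' @export
flatten_trace <- function(icss, method = c("arclength", "pca")) {
  method <- match.arg(method)
  pts <- icss$points
  seg <- rownorms(diff(pts))
  if (any(seg == 0)) stop_repe("duplicate consecutive points", "repe_input_error")
  if (method == "arclength") {
    s <- c(0, cumsum(seg))
    out <- cbind(s, 0, 0)
  } else {
    ctr <- colMeans(pts)
    pc <- stats::prcomp(pts, center = TRUE)
    out <- cbind(pc$x[, 1], pc$x[, 2], 0)
  }
  sulcus_trace(out, "plane")
}

#' Build the printable electrode outline from a flattened trace
#'
#' The outline is the flattened trace, its parallel copy offset by
#' `width_mm` on the anterior side, and two straight lateral closing
#' segments. For the arc-length flattening the result is a rectangle of
#' area trace length x width.
#'
#' @param icssp a `sulcus_trace` with `space = "plane"`.
#' @param width_mm electrode width (offset distance), default 20 mm (2 cm).
#' @param scalp_points optional n x 3 matrix of the corresponding 3D scalp
#'   points (stored as the electrode's scalp footprint).
#' @return an `electrode_outline`: `plane_polygon` (closed, k x 2 mm),
#'   `width_mm`, `area_mm2`, `scalp_footprint`.
#' @export
build_electrode_outline <- function(icssp, width_mm = 20, scalp_points = NULL) {
  if (!inherits(icssp, "sulcus_trace") || icssp$space != "plane")
    stop_repe("expected a plane-space trace", "repe_input_error")
  if (width_mm <= 0) stop_repe("width_mm must be positive", "repe_geometry_error")
  tr <- icssp$points[, 1:2, drop = FALSE]
  off <- tr
  off[, 2] <- off[, 2] - width_mm     # anterior side at -y (worn toward the face)
  poly <- rbind(tr, off[rev(seq_len(nrow(off))), , drop = FALSE])
  area <- abs(polygon_area(poly))
  if (!polygon_is_simple(poly)) stop_repe("self-intersecting outline", "repe_geometry_error")
  structure(list(plane_polygon = poly, width_mm = width_mm, area_mm2 = area,
                 scalp_footprint = scalp_points),
            class = "electrode_outline")
}

#' @export
print.electrode_outline <- function(x, ...) {
  cat(sprintf("<electrode_outline> %d vertices, width %.1f mm, area %.1f cm^2\n",
              nrow(x$plane_polygon), x$width_mm, x$area_mm2 / 100))
  invisible(x)
}

# shoelace (signed) area of a closed polygon given as k x 2 vertices
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# O(k^2) segment-intersection scan; fine at trace scale (k ~ 250)
polygon_is_simple <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip segments sharing a vertex
    if (length(js) == 0) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  q1 <- matrix(q1, ncol = 2); q2 <- matrix(q2, ncol = 2)
  d <- p2 - p1
  e1 <- q2 - q1
  denom <- d[1] * e1[, 2] - d[2] * e1[, 1]
  w <- cbind(q1[, 1] - p1[1], q1[, 2] - p1[2])
  t <- (w[, 1] * e1[, 2] - w[, 2] * e1[, 1]) / denom
  u <- (w[, 1] * d[2] - w[, 2] * d[1]) / -denom
  ok <- abs(denom) > 1e-12
  ok & t > 1e-9 & t < 1 - 1e-9 & u > 1e-9 & u < 1 - 1e-9
}

#' Export an electrode outline as a true-scale SVG
#'
#' One SVG user unit equals 1 mm (the document width/height are given in mm
#' and the viewBox matches), so the file prints at physical scale. A 100 mm
#' calibration ruler with 10 mm ticks is drawn below the outline.
#'
#' @param outline an `electrode_outline`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_outline <- function(outline, path) {
  p <- outline$plane_polygon
  ruler_y <- max(p[, 2]) + 15
  xmin <- min(p[, 1], 0) - 10
  xmax <- max(p[, 1], 100) + 10
  ymin <- min(p[, 2]) - 10
  ymax <- ruler_y + 10
  fmt <- function(v) formatC(v, format = "fg", digits = 15, width = 1)
  pts_attr <- paste(paste(fmt(p[, 1]), fmt(p[, 2]), sep = ","), collapse = " ")
  ticks <- vapply(seq(0, 100, 10), function(x) sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="0.3"/>',
    fmt(x), fmt(ruler_y), fmt(x), fmt(ruler_y + 3)), character(1))
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%smm" height="%smm" viewBox="%s %s %s %s">',
            fmt(xmax - xmin), fmt(ymax - ymin), fmt(xmin), fmt(ymin),
            fmt(xmax - xmin), fmt(ymax - ymin)),
    sprintf('<polygon id="electrode" points="%s" fill="none" stroke="black" stroke-width="0.5"/>',
            pts_attr),
    sprintf('<line id="ruler" x1="0" y1="%s" x2="100" y2="%s" stroke="black" stroke-width="0.5"/>',
            fmt(ruler_y), fmt(ruler_y)),
    ticks,
    sprintf('<text x="0" y="%s" font-size="5">100 mm</text>', fmt(ruler_y + 9)),
    '</svg>')
  writeLines(svg, path)
  invisible(path)
}

#' Re-read an exported outline SVG
#'
#' @param path SVG written by [export_outline()].
#' @return list with `polygon` (k x 2 mm) and `ruler_length_mm`.
#' @export
read_outline_svg <- function(path) {
  doc <- xml2::read_xml(path)
  poly <- xml2::xml_find_first(doc, "//*[@id='electrode']")
  pts <- xml2::xml_attr(poly, "points")
  toks <- strsplit(strsplit(trimws(pts), "\\s+")[[1]], ",")
  m <- do.call(rbind, lapply(toks, as.numeric))
  ruler <- xml2::xml_find_first(doc, "//*[@id='ruler']")
  rl <- abs(as.numeric(xml2::xml_attr(ruler, "x2")) -
            as.numeric(xml2::xml_attr(ruler, "x1")))
  list(polygon = m, ruler_length_mm = rl)
}
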