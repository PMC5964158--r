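# Low-level array / geometry helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_repe <- function(msg, class) {
  stop(structure(class = c(class, "repe_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Apply a 4x4 affine to world points
#'
#' @param affine 4x4 matrix (homogeneous, mm).
#' @param pts n x 3 matrix of points.
#' @return n x 3 matrix of transformed points.
#' @export
apply_affine <- function(affine, pts) {
  pts <- as_points(pts)
  out <- cbind(pts, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop_repe("points must have 3 columns", "repe_input_error")
  pts
}

# voxel (0-based ijk) -> world mm
voxel_to_world <- function(affine, ijk) apply_affine(affine, as_points(ijk))
world_to_voxel <- function(affine, xyz) apply_affine(solve(affine), as_points(xyz))

# 1-based linear index -> 0-based (i,j,k)
lin_to_ijk0 <- function(lin, dim3) {
  lin0 <- lin - 1L
  i <- lin0 %% dim3[1]
  j <- (lin0 %/% dim3[1]) %% dim3[2]
  k <- lin0 %/% (dim3[1] * dim3[2])
  cbind(i, j, k)
}

ijk0_to_lin <- function(ijk, dim3) {
  1L + ijk[, 1] + dim3[1] * (ijk[, 2] + dim3[2] * ijk[, 3])
}

# shift array contents by s along axis ax, zero-filled
shift_array <- function(a, s, ax) {
  if (s == 0) return(a)
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[ax]
  if (abs(s) >= n) return(out)
  if (s > 0) { dst[[ax]] <- (s + 1):n; src[[ax]] <- 1:(n - s) }
  else       { dst[[ax]] <- 1:(n + s); src[[ax]] <- (1 - s):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# separable Gaussian smoothing, zero-padded boundary
gauss_smooth3 <- function(a, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(a)
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  for (ax in 1:3) {
    acc <- array(0, dim(a))
    for (i in seq_along(k)) acc <- acc + k[i] * shift_array(a, i - radius - 1L, ax)
    a <- acc
  }
  a
}

# 6-neighbourhood binary erosion/dilation, zero padding (iterated)
erode6 <- function(m, iter = 1L) {
  for (it in seq_len(iter)) {
    out <- m
    for (ax in 1:3) out <- out & shift_array(m, 1L, ax) & shift_array(m, -1L, ax)
    m <- out
  }
  m
}

dilate6 <- function(m, iter = 1L) {
  for (it in seq_len(iter)) {
    out <- m
    for (ax in 1:3) out <- out | shift_array(m, 1L, ax) | shift_array(m, -1L, ax)
    m <- out
  }
  m
}

close6 <- function(m, iter = 1L) erode6(dilate6(m, iter), iter)
open6  <- function(m, iter = 1L) dilate6(erode6(m, iter), iter)

# 6-connected component labelling via igraph; returns integer array (0 = background)
label_components6 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  ijk <- lin_to_ijk0(idx, d)
  edges <- NULL
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- ijk[, ax] < d[ax] - 1L
    nb <- idx[ok] + strides[ax]
    has <- pos[nb] > 0L
    if (any(has)) edges <- c(edges, rbind(pos[idx[ok]][has], pos[nb][has]))
  }
  g <- igraph::make_graph(edges = as.numeric(edges), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

largest_component6 <- function(mask) {
  lab <- label_components6(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  best <- which.max(tabulate(lab[lab > 0L]))
  lab == best
}

# fill interior holes: background components not touching the array border
fill_holes6 <- function(mask) {
  lab <- label_components6(!mask)
  if (max(lab) == 0L) return(mask)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# Otsu threshold on a numeric vector
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  h <- graphics::hist(x, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# trilinear interpolation of a 3D array at world points (outside -> 0)
interp_trilinear <- function(a, affine, pts) {
  d <- dim(a)
  v <- world_to_voxel(affine, pts)  # 0-based continuous voxel coords
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(nrow(v))
  get <- function(ii, jj, kk) {
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 & kk >= 0 & kk <= d[3] - 1
    val <- numeric(length(ii))
    if (any(ok)) val[ok] <- a[1L + ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok])]
    val
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    out <- out + w * get(x0 + dx, y0 + dy, z0 + dz)
  }
  out
}

# deterministic sub-seed derivation (exact in doubles; result < 2^31)
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9176) %% 214748329)
}

vnorm <- function(x) sqrt(sum(x^2))
rownorms <- function(m) sqrt(rowSums(m^2))
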