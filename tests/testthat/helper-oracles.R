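# Independent oracles used to cross-check package routines. These stay
# deliberately naive / closed-form and never call the code paths they check.

# Legendre polynomial table P_0..P_L at x (recursion)
oracle_legendre <- function(L, x) {
  P <- matrix(0, length(x), L + 1)
  P[, 1] <- 1
  if (L >= 1) P[, 2] <- x
  for (l in 2:L) P[, l + 1] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1]) / l
  P
}

# Analytic potential of a 3-shell concentric sphere with a mirrored pair of
# uniform-current spherical-cap electrodes (anode at +axis, cathode at
# -axis). Scaled-variable Legendre series, well conditioned to high order.
# radii_m = c(brain, skull outer, scalp outer) in metres; sigmas matching.
oracle_three_shell_cap <- function(r_m, theta, radii_m, sigmas, I_A, alpha,
                                   L = 400) {
  R1 <- radii_m[1]; R2 <- radii_m[2]; R3 <- radii_m[3]
  sb <- sigmas[1]; sk <- sigmas[2]; sc <- sigmas[3]
  ca <- cos(alpha)
  Acap <- 2 * pi * R3^2 * (1 - ca)
  Pc <- oracle_legendre(L + 1, ca)[1, ]
  A3 <- B3 <- rep(0, L)
  for (l in seq(1, L, 2)) {          # odd terms only (mirror symmetry)
    jl <- (I_A / Acap) * (Pc[l] - Pc[l + 2])  # P_{l-1}(ca) - P_{l+1}(ca)
    q12 <- (R1 / R2)^l; q12b <- (R1 / R2)^(l + 1)
    q23 <- (R2 / R3)^l; q23b <- (R2 / R3)^(l + 1)
    M <- rbind(
      c(1, -q12, -1, 0, 0),
      c(sb * l, -sk * l * q12, sk * (l + 1), 0, 0),
      c(0, 1, q12b, -q23, -1),
      c(0, sk * l, -sk * (l + 1) * q12b, -sc * l * q23, sc * (l + 1)),
      c(0, 0, 0, sc * l, -sc * (l + 1) * q23b))
    sol <- solve(M, c(0, 0, 0, 0, jl * R3))
    A3[l] <- sol[4]; B3[l] <- sol[5]
  }
  P <- oracle_legendre(L, cos(theta))
  V <- numeric(length(r_m))
  for (l in seq(1, L, 2))
    V <- V + (A3[l] * (r_m / R3)^l + B3[l] * (R2 / r_m)^(l + 1)) * P[, l + 1]
  V
}

# Naive exact point-to-triangle distance: candidate = in-plane projection
# (if inside by barycentric test), the three clamped edge projections and
# the three vertices. Different algorithm than the packaged region method.
oracle_point_triangle <- function(p, a, b, c) {
  cands <- rbind(a, b, c)
  for (ed in list(list(a, b), list(b, c), list(c, a))) {
    u <- ed[[2]] - ed[[1]]
    t <- sum((p - ed[[1]]) * u) / sum(u * u)
    t <- min(max(t, 0), 1)
    cands <- rbind(cands, ed[[1]] + t * u)
  }
  n <- pracma_cross(b - a, c - a)
  nn <- sum(n * n)
  if (nn > 0) {
    q <- p - n * sum((p - a) * n) / nn
    # barycentric inside test
    v0 <- b - a; v1 <- c - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) cands <- rbind(cands, q)
  }
  d2 <- rowSums((cands - matrix(p, nrow(cands), 3, byrow = TRUE))^2)
  list(dist = sqrt(min(d2)), point = cands[which.min(d2), ])
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# exhaustive mesh projection via the naive oracle
oracle_closest_point_mesh <- function(pts, surf) {
  V <- surf$vertices; Tr <- surf$triangles
  out_d <- numeric(nrow(pts)); out_p <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) {
    best <- Inf; bp <- NULL
    for (j in seq_len(nrow(Tr))) {
      r <- oracle_point_triangle(pts[i, ], V[Tr[j, 1], ], V[Tr[j, 2], ], V[Tr[j, 3], ])
      if (r$dist < best) { best <- r$dist; bp <- r$point }
    }
    out_d[i] <- best; out_p[i, ] <- bp
  }
  list(dist = out_d, points = out_p)
}

# paired t statistic (for the F = t^2 identity on two conditions)
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}
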