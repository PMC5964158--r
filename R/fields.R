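# Quasi-static volume-conductor solver and montage dosimetry.
#
# The potential obeys div(sigma grad V) = 0 with Neumann (no-flux) walls and
# injected currents at the electrodes. Discretization is a 7-point voxel
# finite-volume stencil with harmonic-mean face conductivities (continuity
# of normal current across tissue boundaries); the Neumann problem's
# constant nullspace is fixed by pinning one node during the solve and
# reporting the zero-mean potential. The linear system is solved by
# Jacobi-preconditioned conjugate gradients to a relative residual <= tol.

#' Tissue conductivities (S/m)
#'
#' Literature values for the seven head compartments plus electrode gel.
#' @return named numeric vector indexed by label order 0..7.
#' @export
tissue_conductivities <- function() {
  c(air = 1e-4, skin = 0.465, fat = 0.025, skull = 1e-2,
    csf = 1.65, gray = 0.276, white = 0.126, gel = 0.3)
}

#' Map tissue labels to a conductivity volume
#'
#' @param labels a `labeled_volume`.
#' @param tissue_model named conductivities in label order (0..7).
#' @return a `conductivity_volume`: `sigma` (3D array S/m), `domain`
#'   (logical array; air is excluded from the solved domain), `affine`.
#' @export
conductivity_from_labels <- function(labels, tissue_model = tissue_conductivities()) {
  lab <- labels$labels
  if (any(lab < 0L) || any(lab > length(tissue_model) - 1L))
    stop_repe("unknown tissue label", "repe_configuration_error")
  if (any(tissue_model[-1] <= 0))
    stop_repe("non-positive tissue conductivity", "repe_configuration_error")
  sigma <- array(tissue_model[lab + 1L], dim(lab))
  structure(list(sigma = sigma, domain = lab > 0L, affine = labels$affine,
                 voxel_size = labels$voxel_size),
            class = "conductivity_volume")
}

# scalp voxels: tissue voxels 6-adjacent to air (array border counts as air)
scalp_voxel_info <- function(labels) {
  lab <- labels$labels
  d <- dim(lab)
  head <- lab > 0L
  interior <- erode6(head, 1L)
  svox <- which(head & !interior)
  pts <- voxel_to_world(labels$affine, lin_to_ijk0(svox, d))
  # outward normal from the smoothed head mask
  G <- gauss_smooth3(head + 0, 1.5)
  gr <- grad3(G)
  N <- -cbind(gr[[1]][svox], gr[[2]][svox], gr[[3]][svox])
  N <- N / pmax(rownorms(N), 1e-12)
  # projected exposed-face area per voxel (mm^2): sum over air-adjacent faces
  # of |face_normal . local_normal| * h^2 -- an accurate partition of the
  # smooth surface area (a raw face count would overestimate by up to 50%)
  h2 <- prod(labels$voxel_size[1:2])
  w <- numeric(length(svox))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  strides <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -(d[1] * d[2]))
  ijk <- lin_to_ijk0(svox, d)
  for (f in 1:6) {
    ax <- ceiling(f / 2)
    step <- if (f %% 2 == 1L) 1L else -1L
    coord <- ijk[, ax] + step
    inb <- coord >= 0L & coord <= d[ax] - 1L
    nb_air <- !inb
    nb_air[inb] <- !head[svox[inb] + strides[f]]
    contrib <- abs(N %*% dirs[f, ]) * h2
    w <- w + ifelse(nb_air, contrib, 0)
  }
  list(vox = svox, pts = pts, normals = N, weights = as.numeric(w))
}

new_patch <- function(vox, weights, pts, normals, polarity, current_mA) {
  structure(list(vox = vox, weights = weights, pts = pts, normals = normals,
                 polarity = polarity, current_mA = current_mA,
                 area_cm2 = sum(weights) / 100),
            class = "electrode_patch")
}

#' @export
print.electrode_patch <- function(x, ...) {
  cat(sprintf("<electrode_patch> %s, %d voxels, %.1f cm^2, %.2f mA\n",
              x$polarity, length(x$vox), x$area_cm2, x$current_mA))
  invisible(x)
}

#' Place the anode band on the scalp
#'
#' `type = "repe"`: a band of scalp voxels following the electrode's scalp
#' footprint (the projected sulcus), `width_mm` wide on the posterior side,
#' shifted `shift_mm` anteriorly. With shift 0 the anterior border of the
#' band lies on the sulcus projection (montage "A"). `type = "strip"`: a
#' straight (constant-y) coronal band of the same nominal size centred on
#' the footprint's mean anterior-posterior position, the non-personalized
#' comparison electrode.
#'
#' @param labels a `labeled_volume`.
#' @param footprint n x 3 scalp footprint polyline of the personalized
#'   electrode (mm).
#' @param type `"repe"` or `"strip"`.
#' @param shift_mm anterior shift: one of 0, 5, 10, 15.
#' @param width_mm,length_mm band dimensions (default 20 x 175 mm = 35 cm^2).
#' @param current_mA injected current (anode positive).
#' @return an `electrode_patch`.
#' @export
place_anode <- function(labels, footprint, type = c("repe", "strip"),
                        shift_mm = 0, width_mm = 20, length_mm = 175,
                        current_mA = 1.5) {
  type <- match.arg(type)
  if (!shift_mm %in% c(0, 5, 10, 15))
    stop_repe("shift_mm must be one of 0, 5, 10, 15", "repe_parameter_error")
  sv <- scalp_voxel_info(labels)
  footprint <- as_points(footprint)
  s_fp <- c(0, cumsum(rownorms(diff(footprint))))
  if (type == "repe") {
    nn <- FNN::get.knnx(footprint, sv$pts, k = 1)
    ni <- nn$nn.index[, 1]
    # local curve tangents (central differences along the polyline)
    n_fp <- nrow(footprint)
    tg <- footprint[pmin(seq_len(n_fp) + 1, n_fp), ] -
          footprint[pmax(seq_len(n_fp) - 1, 1), ]
    tg <- tg / pmax(rownorms(tg), 1e-12)
    # offset from the curve with the along-curve component removed; its
    # anterior (+y) projection gives the signed lateral band coordinate
    e <- sv$pts - footprint[ni, , drop = FALSE]
    along <- rowSums(e * tg[ni, , drop = FALSE])
    perp <- e - along * tg[ni, , drop = FALSE]
    q <- -perp[, 2]   # posterior-positive offset
    arc <- s_fp[ni]
    in_len <- abs(arc - s_fp[length(s_fp)] / 2) <= length_mm / 2
    sel <- in_len & q >= -shift_mm & q <= width_mm - shift_mm &
      nn$nn.dist[, 1] <= width_mm + shift_mm + 10
  } else {
    y_mid <- mean(footprint[, 2])
    y_hi <- y_mid + width_mm / 2 - shift_mm
    in_y <- sv$pts[, 2] <= y_hi & sv$pts[, 2] >= y_hi - width_mm
    # lateral arc position approximated on the coronal section
    r_loc <- sqrt(sv$pts[, 1]^2 + sv$pts[, 3]^2)
    psi <- atan2(sv$pts[, 1], sv$pts[, 3])
    sel <- in_y & abs(psi * r_loc) <= length_mm / 2 & sv$pts[, 3] > 0
  }
  if (!any(sel)) stop_repe("anode selects no scalp voxels", "repe_placement_error")
  new_patch(sv$vox[sel], sv$weights[sel], sv$pts[sel, , drop = FALSE],
            sv$normals[sel, , drop = FALSE], "anode", current_mA)
}

#' Place a return (cathode) electrode
#'
#' Reference types follow the montage study: `"oz"` (occipital pad of
#' `area_cm2` centred at 90% of the N-I midline arc), `"neck"` (band around
#' the neck stub), `"shoulders"` (band at the neck base; the phantom has no
#' shoulders, so this is a labelled approximation), `"ring"` (strip around
#' the head circumference at the ear plane).
#'
#' @param labels a `labeled_volume`.
#' @param surf scalp `scalp_surface` (needed for `"oz"`).
#' @param fid `fiducial_set` (needed for `"oz"`).
#' @param type one of `"oz"`, `"neck"`, `"shoulders"`, `"ring"`.
#' @param area_cm2 pad area for `"oz"` (default 70 cm^2, twice the anode).
#' @param current_mA return current (negative).
#' @return an `electrode_patch`.
#' @export
place_cathode <- function(labels, surf = NULL, fid = NULL,
                          type = c("oz", "neck", "shoulders", "ring"),
                          area_cm2 = 70, current_mA = -1.5) {
  type <- match.arg(type)
  sv <- scalp_voxel_info(labels)
  z <- sv$pts[, 3]
  zmin <- min(z)
  sel <- switch(type,
    oz = {
      if (is.null(surf) || is.null(fid))
        stop_repe("oz reference needs surf and fid", "repe_input_error")
      ml <- scalp_midline(surf, fid)
      ctr <- interp_polyline(ml$points, ml$s, 0.9 * ml$length)
      radius <- sqrt(area_cm2 * 100 / pi)
      rownorms(sv$pts - matrix(ctr, length(sv$vox), 3, byrow = TRUE)) <= radius
    },
    neck = z >= zmin + 20 & z <= zmin + 45,
    shoulders = z <= zmin + 20,
    ring = abs(z - 0) <= 10)
  if (!any(sel)) stop_repe("cathode selects no scalp voxels", "repe_placement_error")
  new_patch(sv$vox[sel], sv$weights[sel], sv$pts[sel, , drop = FALSE],
            sv$normals[sel, , drop = FALSE], "cathode", current_mA)
}

# Add a gel layer over each patch (grown by 6-dilation into air, so it is
# always connected to the head) and return the updated conductivity volume
# plus per-patch injection nodes. The current enters at the skin-electrode
# contact voxels, divided in proportion to each voxel's contact area; the
# gel sits on top as a passive conductor (lateral shunting).
apply_patches <- function(cond, patches, gel_sigma = tissue_conductivities()[["gel"]],
                          gel_voxels = 2L) {
  sigma <- cond$sigma
  domain <- cond$domain
  d <- dim(sigma)
  inject <- vector("list", length(patches))
  for (pi in seq_along(patches)) {
    p <- patches[[pi]]
    if (gel_voxels > 0L) {
      m <- array(FALSE, d)
      m[p$vox] <- TRUE
      for (layer in seq_len(gel_voxels)) {
        grow <- dilate6(m, 1L) & !domain
        sigma[grow] <- gel_sigma
        domain <- domain | grow
        m <- m | grow
      }
    }
    inject[[pi]] <- list(nodes = p$vox, weights = p$weights,
                         current_A = p$current_mA * 1e-3)
  }
  list(cond = structure(list(sigma = sigma, domain = domain, affine = cond$affine,
                             voxel_size = cond$voxel_size),
                        class = "conductivity_volume"),
       inject = inject)
}

#' Solve the quasi-static potential for a montage
#'
#' @param cond a `conductivity_volume` (from [conductivity_from_labels()]).
#' @param electrodes list of `electrode_patch` (currents must sum to 0).
#' @param tol conjugate-gradient relative residual tolerance.
#' @param maxit iteration cap.
#' @param gel_voxels thickness of the passive gel layer grown over each
#'   patch (0 disables gel, e.g. for analytic-oracle comparisons).
#' @return a `field_solution`: `V` (3D array, volts; NA outside domain),
#'   `E_mag` (3D array, V/m), `residual`, `iterations`.
#' @export
solve_potential <- function(cond, electrodes, tol = 1e-6, maxit = 20000L,
                            gel_voxels = 2L) {
  total <- sum(vapply(electrodes, function(p) p$current_mA, numeric(1)))
  if (abs(total) > 1e-9)
    stop_repe("electrode currents must sum to zero", "repe_input_error")
  ap <- apply_patches(cond, electrodes, gel_voxels = gel_voxels)
  sigma <- ap$cond$sigma
  domain <- ap$cond$domain
  d <- dim(sigma)
  h_m <- mean(ap$cond$voxel_size) * 1e-3   # voxel pitch in metres
  idx <- which(domain)
  n <- length(idx)
  pos <- integer(prod(d)); pos[idx] <- seq_len(n)

  ijk <- lin_to_ijk0(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  ii <- jj <- integer(0); gg <- numeric(0)
  for (ax in 1:3) {
    ok <- ijk[, ax] < d[ax] - 1L
    nb <- idx[ok] + strides[ax]
    has <- pos[nb] > 0L
    a_ <- pos[idx[ok]][has]; b_ <- pos[nb][has]
    s1 <- sigma[idx[ok]][has]; s2 <- sigma[nb][has]
    g <- h_m * 2 * s1 * s2 / (s1 + s2)
    ii <- c(ii, a_); jj <- c(jj, b_); gg <- c(gg, g)
  }
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(-gg, -gg),
                            dims = c(n, n))
  Matrix::diag(A) <- -Matrix::rowSums(A)

  b <- numeric(n)
  for (inj in ap$inject) {
    k <- pos[inj$nodes]
    stopifnot(all(k > 0))
    contrib <- inj$current_A * inj$weights / sum(inj$weights)
    b[k] <- b[k] + contrib
  }
  # gauge: pin the domain voxel nearest the grid centre
  ctr <- (d - 1) / 2
  pin <- which.min(rowSums(sweep(ijk, 2, ctr)^2))
  keep <- setdiff(seq_len(n), pin)
  Ar <- A[keep, keep]
  br <- b[keep]

  di <- Matrix::diag(Ar)
  x <- numeric(n - 1L)
  r <- br
  z <- r / di
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(br^2))
  it <- 0L
  repeat {
    it <- it + 1L
    Apv <- as.numeric(Ar %*% p)
    alpha <- rz / sum(p * Apv)
    x <- x + alpha * p
    r <- r - alpha * Apv
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol || it >= maxit) break
    z <- r / di
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (res > tol)
    stop_repe(sprintf("CG did not converge: residual %.2e after %d iterations", res, it),
              "repe_solver_error")
  V <- rep(NA_real_, prod(d))
  V[idx[keep]] <- x
  V[idx[pin]] <- 0
  V[idx] <- V[idx] - mean(V[idx])
  V <- array(V, d)

  E <- field_magnitude(V, array(domain, d), sigma, h_m)
  structure(list(V = V, E_mag = E, residual = res, iterations = it,
                 domain = array(domain, d), affine = ap$cond$affine),
            class = "field_solution")
}

# |E| from face current fluxes: the normal current density J = sigma_face *
# dV/h is continuous across tissue interfaces, so E inside a voxel is
# estimated as J_face / sigma_voxel averaged over its two faces per axis.
# This resolves the field jump at conductivity boundaries that a plain
# central difference of V smears (important for one-voxel-thin gray matter).
field_magnitude <- function(V, dom, sigma, h_m) {
  d <- dim(V)
  Vz <- V; Vz[!dom] <- NA
  Emag2 <- array(0, d)
  for (ax in 1:3) {
    up <- shift_array_na(Vz, -1L, ax)   # neighbour at +ax
    dn <- shift_array_na(Vz, 1L, ax)    # neighbour at -ax
    s_up <- shift_array_na(sigma, -1L, ax)
    s_dn <- shift_array_na(sigma, 1L, ax)
    # current density through the two faces, then E = J / sigma_here
    j_up <- 2 * sigma * s_up / (sigma + s_up) * (Vz - up) / h_m
    j_dn <- 2 * sigma * s_dn / (sigma + s_dn) * (dn - Vz) / h_m
    e_up <- j_up / sigma
    e_dn <- j_dn / sigma
    g <- ifelse(!is.na(e_up) & !is.na(e_dn), (e_up + e_dn) / 2,
                ifelse(!is.na(e_up), e_up, ifelse(!is.na(e_dn), e_dn, 0)))
    g[is.na(g)] <- 0
    Emag2 <- Emag2 + g^2
  }
  E <- sqrt(Emag2)
  E[!dom] <- NA
  E
}

shift_array_na <- function(a, s, ax) {
  out <- shift_array(a, s, ax)
  d <- dim(a)
  idxl <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (s > 0) idxl[[ax]] <- seq_len(s) else idxl[[ax]] <- d[ax] - seq_len(-s) + 1L
  if (s != 0) out[idxl[[1]], idxl[[2]], idxl[[3]]] <- NA
  out
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d domain voxels, CG residual %.1e (%d iterations)\n",
              sum(x$domain), x$residual, x$iterations))
  invisible(x)
}

#' Mean electric field per region of interest
#'
#' @param sol a `field_solution`.
#' @param rois named list of logical arrays (e.g. from [roi_masks()]).
#' @return data.frame with `roi`, `ef_ave` (V/m), `n_vox`; the S1/M1 ratio
#'   (when both present) is in `attr(, "ratio")`.
#' @export
roi_dose <- function(sol, rois) {
  out <- do.call(rbind, lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    vals <- sol$E_mag[m & sol$domain]
    data.frame(roi = nm, ef_ave = mean(vals), n_vox = length(vals))
  }))
  if (all(c("S1", "M1") %in% out$roi))
    attr(out, "ratio") <- out$ef_ave[out$roi == "S1"] / out$ef_ave[out$roi == "M1"]
  out
}

#' Run the montage comparison study
#'
#' Solves every combination of reference electrode and anterior shift for
#' the personalized band (plus optionally the straight strip) at the given
#' current, and tabulates the S1/M1 dose ratio. Sixteen montages for the
#' four references x four shifts.
#'
#' @param labels a `labeled_volume`.
#' @param surf scalp surface, `fid` fiducials, `footprint` the electrode
#'   scalp footprint polyline.
#' @param fid a `fiducial_set`.
#' @param footprint n x 3 matrix (mm).
#' @param rois named ROI mask list (needs `S1` and `M1`).
#' @param references character vector of cathode types.
#' @param shifts_mm numeric vector of anterior shifts.
#' @param anodes anode types to include (`"repe"`, optionally `"strip"`).
#' @param current_mA stimulation current.
#' @param tol solver tolerance.
#' @return data.frame: one row per montage with `anode`, `shift_mm`,
#'   `reference`, `ef_S1`, `ef_M1`, `ratio` and per-section doses.
#' @export
run_montage_study <- function(labels, surf, fid, footprint, rois,
                              references = c("oz", "neck", "shoulders", "ring"),
                              shifts_mm = c(0, 5, 10, 15),
                              anodes = "repe", current_mA = 1.5, tol = 1e-6) {
  cond <- conductivity_from_labels(labels)
  section_names <- grep("^S1_|^M1_", names(rois), value = TRUE)
  rows <- NULL
  for (an in anodes) for (ref in references) for (sh in shifts_mm) {
    if (an == "strip" && sh != 0) next
    anode <- place_anode(labels, footprint, type = an, shift_mm = sh,
                         current_mA = current_mA)
    cathode <- place_cathode(labels, surf, fid, type = ref,
                             current_mA = -current_mA)
    sol <- solve_potential(cond, list(anode, cathode), tol = tol)
    dd <- roi_dose(sol, rois)
    row <- data.frame(anode = an, shift_mm = sh, reference = ref,
                      ef_S1 = dd$ef_ave[dd$roi == "S1"],
                      ef_M1 = dd$ef_ave[dd$roi == "M1"],
                      ratio = attr(dd, "ratio"))
    for (sn in section_names) row[[sn]] <- dd$ef_ave[dd$roi == sn]
    rows <- rbind(rows, row)
  }
  rows
}
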