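# Shape features of a binary VOI at cubic voxel size.
#
# Surface area and mesh volume come from a marching-tetrahedra isosurface:
# the binary mask is first smoothed with an isotropic Gaussian (sigma = 1
# voxel) to suppress the digital staircase (a midpoint mesh of raw binary
# data overestimates a sphere's area by ~10-30%), then each 2x2x2 cell of
# the smoothed field is split into six tetrahedra around the main diagonal
# and the 0.5-isosurface is triangulated with linear edge interpolation.
# Enclosed volume is accumulated from the same closed, outward-oriented
# mesh by the divergence theorem, so mesh volume and area always satisfy
# the isoperimetric inequality and sphericity is <= 1 by construction.

# corners of the unit cube, bit order (x, y, z)
.cube_corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))[
  , c(1, 2, 3)]
# six tetrahedra around the 0-7 diagonal (1-based corner indices)
.tet_corners <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                      c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

# separable Gaussian smoothing with zero-padding boundary
smooth_gaussian3 <- function(arr, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, n)
    for (o in -r:r) {
      w <- k[o + r + 1L]
      src <- max(1L, 1L + o):min(n[ax], n[ax] + o)
      dst <- src - o
      if (ax == 1) out[dst, , ] <- out[dst, , ] + w * arr[src, , ]
      else if (ax == 2) out[, dst, ] <- out[, dst, ] + w * arr[, src, ]
      else out[, , dst] <- out[, , dst] + w * arr[, , src]
    }
    arr <- out
  }
  arr
}

# batched triangles: rowwise area and outward-oriented signed volume.
# inside_pt marks the interior side; normals are flipped to point away
# from it before the divergence-theorem volume term.
tri_batch <- function(p1, p2, p3, inside_pt) {
  u <- p2 - p1; v <- p3 - p1
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  area <- 0.5 * sqrt(nx^2 + ny^2 + nz^2)
  w <- inside_pt - p1
  flip <- (nx * w[, 1] + ny * w[, 2] + nz * w[, 3]) > 0
  # det(p1, p2, p3) / 6 with rows as vectors
  det6 <- (p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
             p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
             p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  list(area = sum(area), vol = sum(ifelse(flip, -det6, det6)))
}

# marching-tetrahedra surface area (mm^2) and enclosed volume (mm^3) of the
# 0.5-isosurface of the Gaussian-smoothed mask
mesh_surface <- function(m, spacing, sigma_vox = 1) {
  n <- dim(m)
  pad <- max(2L, as.integer(ceiling(3 * sigma_vox)) + 1L)
  P <- array(0, n + 2L * pad)
  P[pad + seq_len(n[1]), pad + seq_len(n[2]), pad + seq_len(n[3])] <- m
  F <- smooth_gaussian3(P, sigma_vox)
  np <- dim(F)
  nc <- np - 1L
  cx <- seq_len(nc[1]); cy <- seq_len(nc[2]); cz <- seq_len(nc[3])
  corner_val <- function(i)
    as.vector(F[cx + .cube_corners[i, 1], cy + .cube_corners[i, 2],
                cz + .cube_corners[i, 3], drop = FALSE])
  mn <- NULL; mx <- NULL
  for (i in 1:8) {
    v <- corner_val(i)
    mn <- if (is.null(mn)) v else pmin(mn, v)
    mx <- if (is.null(mx)) v else pmax(mx, v)
  }
  mixed <- which(mn < 0.5 & mx >= 0.5)
  if (length(mixed) == 0L) return(list(area = 0, volume = 0))
  V8 <- vapply(1:8, function(i) corner_val(i)[mixed],
               numeric(length(mixed)))
  if (!is.matrix(V8)) V8 <- matrix(V8, nrow = 1)
  ind <- arrayInd(mixed, nc)
  base <- sweep(ind - 1L, 2, spacing, `*`)
  corner_mm <- sweep(.cube_corners, 2, spacing, `*`)
  area <- 0; vol <- 0
  for (t in 1:6) {
    tc <- .tet_corners[t, ]
    vals <- V8[, tc, drop = FALSE]
    bits <- vals >= 0.5
    caseid <- bits %*% c(1L, 2L, 4L, 8L)
    for (cs in setdiff(unique(as.integer(caseid)), c(0L, 15L))) {
      sel <- which(caseid == cs)
      b <- as.logical(intToBits(cs)[1:4])
      s <- sum(b)
      vprt <- function(r) base[sel, , drop = FALSE] +
        matrix(corner_mm[tc[r], ], length(sel), 3, byrow = TRUE)
      cross_pt <- function(ia, ib) {
        # interpolated 0.5-crossing on edge (tet-local corners ia -> ib)
        va <- vals[sel, ia]; vb <- vals[sel, ib]
        tt <- (0.5 - va) / (vb - va)
        pa <- vprt(ia); pb <- vprt(ib)
        pa + (pb - pa) * tt
      }
      if (s == 1L || s == 3L) {
        apex <- if (s == 1L) which(b) else which(!b)
        rest <- setdiff(1:4, apex)
        m1 <- cross_pt(apex, rest[1])
        m2 <- cross_pt(apex, rest[2])
        m3 <- cross_pt(apex, rest[3])
        inside <- if (s == 1L) vprt(apex) else
          (vprt(rest[1]) + vprt(rest[2]) + vprt(rest[3])) / 3
        r <- tri_batch(m1, m2, m3, inside)
        area <- area + r$area; vol <- vol + r$vol
      } else if (s == 2L) {
        ins <- which(b); outs <- which(!b)
        q11 <- cross_pt(ins[1], outs[1])
        q12 <- cross_pt(ins[1], outs[2])
        q22 <- cross_pt(ins[2], outs[2])
        q21 <- cross_pt(ins[2], outs[1])
        inside <- (vprt(ins[1]) + vprt(ins[2])) / 2
        r1 <- tri_batch(q11, q12, q22, inside)
        r2 <- tri_batch(q11, q22, q21, inside)
        area <- area + r1$area + r2$area
        vol <- vol + r1$vol + r2$vol
      }
    }
  }
  list(area = area, volume = abs(vol))
}

# candidate hull vertices: voxels extreme along all three axis lines
hull_candidates <- function(idx) {
  key_yz <- paste(idx[, 2], idx[, 3])
  key_xz <- paste(idx[, 1], idx[, 3])
  key_xy <- paste(idx[, 1], idx[, 2])
  ext <- function(v, key) {
    lo <- stats::ave(v, key, FUN = min)
    hi <- stats::ave(v, key, FUN = max)
    v == lo | v == hi
  }
  idx[ext(idx[, 1], key_yz) & ext(idx[, 2], key_xz) & ext(idx[, 3], key_xy),
      , drop = FALSE]
}

max_diameter_mm <- function(idx, spacing) {
  if (nrow(idx) < 2) return(0)
  cand <- hull_candidates(idx)
  pts <- sweep(cand, 2, spacing, `*`)
  n <- nrow(pts)
  best <- 0
  block <- 2000L
  for (i0 in seq(1L, n, by = block)) {
    ii <- i0:min(i0 + block - 1L, n)
    d2 <- outer(rowSums(pts[ii, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[ii, , drop = FALSE] %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# fill internal cavities: voxels not reachable from the array border
# through the background (6-connectivity)
fill_holes <- function(m) {
  n <- dim(m)
  P <- array(1L, n + 2L)
  P[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- m
  bg <- P == 0L
  reach <- array(FALSE, dim(P))
  reach[1, 1, 1] <- TRUE
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-dim(P)[1], , ]
    grown[-dim(P)[1], , ] <- grown[-dim(P)[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -dim(P)[2], ]
    grown[, -dim(P)[2], ] <- grown[, -dim(P)[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -dim(P)[3]]
    grown[, , -dim(P)[3]] <- grown[, , -dim(P)[3]] | reach[, , -1]
    grown <- grown & bg
    grown[1, 1, 1] <- TRUE
    if (identical(grown, reach)) break
    reach <- grown
  }
  filled <- P == 1L | !reach
  (filled[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L), drop = FALSE]) + 0L
}

#' Shape features of a VOI
#'
#' Computes the 24 morphological features from a binary mask at cubic voxel
#' spacing (the pipeline uses the 1 mm resample): voxel and mesh volume
#' variants, marching-tetrahedra surface area, sphericity/compactness
#' variants, maximum 3D diameter, principal-axis lengths (4 sqrt(eigenvalue)
#' of the voxel-centre covariance), elongation and flatness, and bounding-box
#' and enclosing-ellipsoid density measures.
#'
#' Degenerate inputs (single voxel, coplanar voxels) give zero axis lengths
#' and are flagged in the `degenerate` attribute rather than returning NaN.
#'
#' @param mask a nonempty [voi_mask()] with cubic spacing.
#' @return named numeric vector of length 24 with attribute `degenerate`.
#' @export
compute_shape <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sp <- mask$spacing
  if (max(abs(sp - sp[1])) > 1e-6)
    stop("compute_shape: mask must be at cubic voxel spacing; resample first")
  m <- mask$data
  nv <- sum(m)
  if (nv == 0L) stop("compute_shape: empty mask")
  vv <- prod(sp)
  idx <- which(m == 1L, arr.ind = TRUE)
  # crop before meshing to keep the scan cheap
  rng <- apply(idx, 2, range)
  mc <- m[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
          drop = FALSE]
  mesh <- mesh_surface(mc, sp)
  filled <- fill_holes(mc)
  v_vox <- nv * vv
  v_filled <- sum(filled) * vv
  A <- mesh$area
  V <- mesh$volume
  pts <- sweep(idx, 2, sp, `*`)
  ctr <- colMeans(pts)
  degenerate <- character(0)
  if (nv > 1) {
    cv <- crossprod(sweep(pts, 2, ctr)) / nv  # population covariance
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  if (ev[1] <= 0) {
    elong <- 0; flat <- 0
    degenerate <- c(degenerate, "elongation", "flatness")
  } else {
    elong <- sqrt(ev[2] / ev[1]); flat <- sqrt(ev[3] / ev[1])
  }
  dmax <- max_diameter_mm(idx, sp)
  r_eq <- (3 * V / (4 * pi))^(1 / 3)
  bb <- (rng[2, ] - rng[1, ] + 1) * sp
  bb_vol <- prod(bb)
  bb_area <- 2 * (bb[1] * bb[2] + bb[1] * bb[3] + bb[2] * bb[3])
  # approximate enclosing ellipsoid: semi-axes 2*sqrt(eigenvalue)
  a <- 2 * sqrt(ev[1]); b <- 2 * sqrt(ev[2]); c_ <- 2 * sqrt(ev[3])
  aee_vol <- 4 / 3 * pi * a * b * c_
  # Thomsen approximation of the ellipsoid surface area (p ~ 1.6075)
  p_ <- 1.6075
  aee_area <- if (a > 0 && b > 0 && c_ > 0)
    4 * pi * (((a * b)^p_ + (a * c_)^p_ + (b * c_)^p_) / 3)^(1 / p_) else 0
  if (aee_vol == 0) degenerate <- c(degenerate, "volume_density_aee",
                                    "area_density_aee")
  out <- c(
    voxel_count = nv,
    volume_mm3 = v_vox,
    mesh_volume_mm3 = V,
    filled_volume_mm3 = v_filled,
    filled_fraction = v_vox / v_filled,
    surface_area_mm2 = A,
    surface_to_volume_ratio = if (V > 0) A / V else 0,
    sphericity = if (A > 0 && V > 0) (36 * pi * V^2)^(1 / 3) / A else 0,
    compactness_1 = if (A > 0) V / (sqrt(pi) * A^1.5) else 0,
    compactness_2 = if (A > 0) 36 * pi * V^2 / A^3 else 0,
    spherical_disproportion = if (V > 0) A / (4 * pi * r_eq^2) else 0,
    asphericity = if (V > 0 && A > 0) (A^3 / (36 * pi * V^2))^(1 / 3) - 1 else 0,
    equivalent_sphere_diameter = 2 * r_eq,
    maximum_3d_diameter = dmax,
    major_axis_length = axes[1],
    minor_axis_length = axes[2],
    least_axis_length = axes[3],
    elongation = elong,
    flatness = flat,
    bounding_box_volume_mm3 = bb_vol,
    volume_density_bbox = v_vox / bb_vol,
    area_density_bbox = if (bb_area > 0) A / bb_area else 0,
    volume_density_aee = if (aee_vol > 0) v_vox / aee_vol else 0)
  out <- c(out, area_density_aee = if (aee_area > 0) A / aee_area else 0)
  stopifnot(length(out) == 24L)
  if (V == 0) degenerate <- c(degenerate, "sphericity", "surface_to_volume_ratio")
  attr(out, "degenerate") <- degenerate
  out
}
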