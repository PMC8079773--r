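# 3D texture matrix construction over a discretized VOI.
#
# All five families are built with 26-connectivity / Chebyshev distance 1:
#  - GLCM: voxel-pair co-occurrences over the 13 unique direction vectors,
#    symmetrized per direction; also merged by summation.
#  - GLRLM: runs of equal grey level along the same 13 directions.
#  - GLSZM: 26-connected zones of equal grey level.
#  - GLDZM: the same zones with their city-block distance to the VOI border.
#  - NGTDM / NGLDM: 26-neighbourhood grey-tone difference and grey-level
#    dependence counts (dependence coarseness alpha = 0: a neighbour is
#    dependent only when its level equals the centre level).
# Voxels outside the mask are NA and never contribute.

# the 13 unique direction vectors of the 26-neighbourhood
unique_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

all_neighbour_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

# crop the level array to the bounding box of the non-NA voxels
crop_to_mask <- function(L) {
  idx <- which(!is.na(L), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("crop_to_mask: no in-mask voxels")
  r <- apply(idx, 2, range)
  L[r[1, 1]:r[2, 1], r[1, 2]:r[2, 2], r[1, 3]:r[2, 3], drop = FALSE]
}

pad_na <- function(L) {
  n <- dim(L)
  P <- array(NA_integer_, n + 2L)
  P[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- L
  P
}

# sub-array of the padded array shifted by d, same dims as the core
shifted_core <- function(P, d) {
  n <- dim(P) - 2L
  P[(2:(n[1] + 1L)) + d[1], (2:(n[2] + 1L)) + d[2], (2:(n[3] + 1L)) + d[3],
    drop = FALSE]
}

glcm_one_direction <- function(L, G, d) {
  n <- dim(L)
  m <- matrix(0, G, G)
  lo <- pmax(1L, 1L - d); hi <- pmin(n, n - d)
  if (any(hi < lo)) return(m)
  sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
  A <- L[sx, sy, sz, drop = FALSE]
  B <- L[sx + d[1], sy + d[2], sz + d[3], drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  if (any(ok)) {
    tab <- tabulate((A[ok] - 1L) * G + B[ok], nbins = G * G)
    m <- t(matrix(tab, nrow = G))  # m[a, b] = count of ordered pair (a, b)
  }
  m + t(m)
}

glrlm_one_direction <- function(L, G, d) {
  n <- dim(L); N <- prod(n)
  co <- arrayInd(seq_len(N), n)
  a <- which(d != 0)[1]
  tt <- co[, a] * sign(d[a])
  B <- 4L * max(n) + 8L
  k1 <- co[, 1] - tt * d[1]
  k2 <- co[, 2] - tt * d[2]
  k3 <- co[, 3] - tt * d[3]
  key <- (k1 + B) + (k2 + B) * (2 * B) + (k3 + B) * (2 * B)^2
  ord <- order(key, tt)
  lv <- as.vector(L)[ord]
  ks <- key[ord]; ts <- tt[ord]
  newrun <- c(TRUE, !(ks[-1] == ks[-N] & ts[-1] == ts[-N] + 1 &
                        !is.na(lv[-1]) & !is.na(lv[-N]) &
                        lv[-1] == lv[-N]))
  grp <- cumsum(newrun)
  len <- tabulate(grp)
  lev <- lv[newrun]
  keep <- !is.na(lev)
  len <- len[keep]; lev <- lev[keep]
  if (length(len) == 0L) return(matrix(0, G, 1))
  Lmax <- max(len)
  t(matrix(tabulate((lev - 1L) * Lmax + len, nbins = G * Lmax), nrow = Lmax))
}

# grey-level zones (26-connected components of equal level) and their
# city-block distance to the VOI border. Returns one row per zone.
label_zones <- function(L) {
  n <- dim(L)
  P <- pad_na(L)
  np <- dim(P)
  core_flat <- which(!is.na(P))
  offs <- all_neighbour_offsets_3d()
  off_flat <- offs[, 1] + offs[, 2] * np[1] + offs[, 3] * np[1] * np[2]
  visited <- logical(length(P))
  Pv <- as.vector(P)
  zones_level <- integer(0); zones_size <- integer(0); zones_dist <- integer(0)
  dist <- voi_border_distance(L)  # same core dims, NA outside
  distP <- pad_na_numeric(dist, np)
  for (s in core_flat) {
    if (visited[s]) next
    lev <- Pv[s]
    visited[s] <- TRUE
    members <- s
    frontier <- s
    while (length(frontier)) {
      nb <- rep(frontier, each = nrow(offs)) + off_flat
      nb <- nb[!is.na(Pv[nb]) & Pv[nb] == lev & !visited[nb]]
      if (length(nb)) {
        nb <- unique(nb)
        visited[nb] <- TRUE
        members <- c(members, nb)
      }
      frontier <- nb
    }
    zones_level <- c(zones_level, lev)
    zones_size <- c(zones_size, length(members))
    zones_dist <- c(zones_dist, as.integer(min(distP[members])))
  }
  data.frame(level = zones_level, size = zones_size, distance = zones_dist)
}

pad_na_numeric <- function(x, np) {
  P <- array(NA_real_, np)
  n <- dim(x)
  P[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- x
  P
}

# city-block (6-connected) distance of each in-mask voxel to the nearest
# out-of-mask voxel; border voxels have distance 1 (IBSI GLDZM convention)
voi_border_distance <- function(L) {
  n <- dim(L)
  P <- pad_na(L)
  np <- dim(P)
  inm <- !is.na(P)
  offs6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  off_flat <- offs6[, 1] + offs6[, 2] * np[1] + offs6[, 3] * np[1] * np[2]
  dist <- array(NA_real_, np)
  inm_flat <- which(inm)
  # border layer: any 6-neighbour outside the mask
  has_out <- vapply(seq_len(6), function(o) !inm[inm_flat + off_flat[o]],
                    logical(length(inm_flat)))
  frontier <- inm_flat[rowSums(matrix(has_out, ncol = 6)) > 0]
  d <- 1
  while (length(frontier)) {
    dist[frontier] <- d
    nb <- unique(rep(frontier, each = 6) + off_flat)
    frontier <- nb[inm[nb] & is.na(dist[nb])]
    d <- d + 1
  }
  dist[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L), drop = FALSE]
}

#' Texture matrices of a discretized VOI
#'
#' Builds the five 3D texture-matrix families (GLCM, GLRLM, GLSZM, GLDZM,
#' NGTDM, NGLDM) from a [discretize_fixed_bin_number()] /
#' [discretize_fixed_bin_size()] output. Co-occurrence and run-length
#' matrices are kept both per direction (13 unique 3D directions at
#' Chebyshev distance 1) and merged by summation.
#'
#' @param dv a `discretized_volume`.
#' @return an object of class `texture_matrices`.
#' @export
compute_texture_matrices <- function(dv) {
  stopifnot(inherits(dv, "discretized_volume"))
  G <- dv$G
  if (G < 1) stop("compute_texture_matrices: G must be >= 1")
  L <- crop_to_mask(dv$levels)
  N_v <- sum(!is.na(L))
  dirs <- unique_directions_3d()
  glcm_dirs <- lapply(seq_len(nrow(dirs)), function(i)
    glcm_one_direction(L, G, dirs[i, ]))
  glcm <- Reduce(`+`, glcm_dirs)
  glrlm_dirs <- lapply(seq_len(nrow(dirs)), function(i)
    glrlm_one_direction(L, G, dirs[i, ]))
  maxL <- max(vapply(glrlm_dirs, ncol, 1L))
  glrlm_dirs <- lapply(glrlm_dirs, function(m) {
    if (ncol(m) < maxL) cbind(m, matrix(0, G, maxL - ncol(m))) else m
  })
  glrlm <- Reduce(`+`, glrlm_dirs)

  zones <- label_zones(L)
  glszm <- matrix(0, G, max(zones$size))
  for (r in seq_len(nrow(zones)))
    glszm[zones$level[r], zones$size[r]] <-
      glszm[zones$level[r], zones$size[r]] + 1
  gldzm <- matrix(0, G, max(zones$distance))
  for (r in seq_len(nrow(zones)))
    gldzm[zones$level[r], zones$distance[r]] <-
      gldzm[zones$level[r], zones$distance[r]] + 1

  # neighbourhood statistics for NGTDM / NGLDM
  P <- pad_na(L)
  offs <- all_neighbour_offsets_3d()
  nbr_sum <- array(0, dim(L)); nbr_cnt <- array(0L, dim(L))
  eq_cnt <- array(0L, dim(L))
  for (i in seq_len(nrow(offs))) {
    S <- shifted_core(P, offs[i, ])
    ok <- !is.na(S)
    nbr_cnt <- nbr_cnt + ok
    nbr_sum <- nbr_sum + ifelse(ok, S, 0L)
    eq_cnt <- eq_cnt + (ok & !is.na(L) & S == L)
  }
  centre <- !is.na(L)
  valid <- centre & nbr_cnt > 0
  abar <- ifelse(valid, nbr_sum / pmax(nbr_cnt, 1L), NA_real_)
  lv <- L[valid]
  ngtdm_n <- tabulate(lv, nbins = G)
  dif <- abs(lv - abar[valid])
  ngtdm_s <- vapply(seq_len(G), function(i) sum(dif[lv == i]), numeric(1))

  jdep <- 1L + eq_cnt[centre]  # dependence count incl. the centre voxel
  ngldm <- t(matrix(tabulate((L[centre] - 1L) * 27L + jdep, nbins = G * 27L),
                    nrow = 27L))

  structure(list(G = G, n_voxels = N_v,
                 glcm = glcm, glcm_dirs = glcm_dirs,
                 glrlm = glrlm, glrlm_dirs = glrlm_dirs,
                 glszm = glszm, gldzm = gldzm,
                 ngtdm = list(n = ngtdm_n, s = ngtdm_s,
                              n_valid = sum(valid)),
                 ngldm = ngldm),
            class = "texture_matrices")
}

#' @export
print.texture_matrices <- function(x, ...) {
  cat("<texture_matrices> G=", x$G, ", N_v=", x$n_voxels,
      ", GLCM pairs=", sum(x$glcm) / 2,
      ", runs=", sum(x$glrlm),
      ", zones=", sum(x$glszm), "\n", sep = "")
  invisible(x)
}
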