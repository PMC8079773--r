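# Independent brute-force reference implementations used as oracles.
# Everything here is written as literal loops over voxels/pairs, straight
# from the defining formulas, deliberately ignoring the package's vectorized
# construction so the two routes stay independent.

oracle_directions <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      out[[length(out) + 1]] <- c(dx, dy, dz)
  }
  out
}

oracle_glcm <- function(L, G, d) {
  n <- dim(L)
  m <- matrix(0, G, G)
  for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
    a <- L[x, y, z]
    if (is.na(a)) next
    xx <- x + d[1]; yy <- y + d[2]; zz <- z + d[3]
    if (xx < 1 || xx > n[1] || yy < 1 || yy > n[2] || zz < 1 || zz > n[3])
      next
    b <- L[xx, yy, zz]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
  }
  m + t(m)
}

oracle_glrlm <- function(L, G, d) {
  n <- dim(L)
  runs <- list()
  for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
    a <- L[x, y, z]
    if (is.na(a)) next
    px <- x - d[1]; py <- y - d[2]; pz <- z - d[3]
    has_pred <- px >= 1 && px <= n[1] && py >= 1 && py <= n[2] &&
      pz >= 1 && pz <= n[3] && !is.na(L[px, py, pz]) && L[px, py, pz] == a
    if (has_pred) next          # not the start of a run
    len <- 1
    cx <- x + d[1]; cy <- y + d[2]; cz <- z + d[3]
    while (cx >= 1 && cx <= n[1] && cy >= 1 && cy <= n[2] &&
           cz >= 1 && cz <= n[3] && !is.na(L[cx, cy, cz]) &&
           L[cx, cy, cz] == a) {
      len <- len + 1
      cx <- cx + d[1]; cy <- cy + d[2]; cz <- cz + d[3]
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  if (!length(runs)) return(matrix(0, G, 1))
  rr <- do.call(rbind, runs)
  m <- matrix(0, G, max(rr[, 2]))
  for (i in seq_len(nrow(rr))) m[rr[i, 1], rr[i, 2]] <- m[rr[i, 1], rr[i, 2]] + 1
  m
}

# 26-connected zones by scalar depth-first search
oracle_zones <- function(L) {
  n <- dim(L)
  lab <- array(0L, n)
  nxt <- 0L
  res <- list()
  for (x0 in seq_len(n[1])) for (y0 in seq_len(n[2])) for (z0 in seq_len(n[3])) {
    if (is.na(L[x0, y0, z0]) || lab[x0, y0, z0] > 0L) next
    nxt <- nxt + 1L
    lev <- L[x0, y0, z0]
    stack <- list(c(x0, y0, z0))
    lab[x0, y0, z0] <- nxt
    size <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xx <- v[1] + dx; yy <- v[2] + dy; zz <- v[3] + dz
        if (xx < 1 || xx > n[1] || yy < 1 || yy > n[2] || zz < 1 ||
            zz > n[3]) next
        if (is.na(L[xx, yy, zz]) || L[xx, yy, zz] != lev ||
            lab[xx, yy, zz] > 0L) next
        lab[xx, yy, zz] <- nxt
        stack[[length(stack) + 1]] <- c(xx, yy, zz)
      }
    }
    res[[nxt]] <- c(lev, size)
  }
  do.call(rbind, res)
}

# city-block distance of each in-mask voxel to outside the mask, by
# fixed-point relaxation
oracle_border_distance <- function(L) {
  n <- dim(L)
  d <- array(NA_real_, n)
  at <- function(x, y, z) {
    if (x < 1 || x > n[1] || y < 1 || y > n[2] || z < 1 || z > n[3])
      return(NA)
    L[x, y, z]
  }
  for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
    if (is.na(L[x, y, z])) next
    nb <- c(at(x - 1, y, z), at(x + 1, y, z), at(x, y - 1, z),
            at(x, y + 1, z), at(x, y, z - 1), at(x, y, z + 1))
    if (any(is.na(nb))) d[x, y, z] <- 1
  }
  repeat {
    changed <- FALSE
    for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
      if (is.na(L[x, y, z]) || !is.na(d[x, y, z])) next
      best <- Inf
      for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
        xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
        if (xx < 1 || xx > n[1] || yy < 1 || yy > n[2] || zz < 1 ||
            zz > n[3]) next
        if (!is.na(d[xx, yy, zz])) best <- min(best, d[xx, yy, zz] + 1)
      }
      if (is.finite(best)) { d[x, y, z] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

oracle_gldzm <- function(L, G) {
  zl <- oracle_zones(L)
  dist <- oracle_border_distance(L)
  # zone distance: minimum over zone voxels; re-walk zones to get members
  n <- dim(L)
  lab <- array(0L, n); nxt <- 0L
  rows <- list()
  for (x0 in seq_len(n[1])) for (y0 in seq_len(n[2])) for (z0 in seq_len(n[3])) {
    if (is.na(L[x0, y0, z0]) || lab[x0, y0, z0] > 0L) next
    nxt <- nxt + 1L
    lev <- L[x0, y0, z0]
    stack <- list(c(x0, y0, z0)); lab[x0, y0, z0] <- nxt
    dmin <- Inf
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      dmin <- min(dmin, dist[v[1], v[2], v[3]])
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xx <- v[1] + dx; yy <- v[2] + dy; zz <- v[3] + dz
        if (xx < 1 || xx > n[1] || yy < 1 || yy > n[2] || zz < 1 ||
            zz > n[3]) next
        if (is.na(L[xx, yy, zz]) || L[xx, yy, zz] != lev ||
            lab[xx, yy, zz] > 0L) next
        lab[xx, yy, zz] <- nxt
        stack[[length(stack) + 1]] <- c(xx, yy, zz)
      }
    }
    rows[[nxt]] <- c(lev, dmin)
  }
  rr <- do.call(rbind, rows)
  m <- matrix(0, G, max(rr[, 2]))
  for (i in seq_len(nrow(rr))) m[rr[i, 1], rr[i, 2]] <- m[rr[i, 1], rr[i, 2]] + 1
  m
}

oracle_ngtdm <- function(L, G) {
  n <- dim(L)
  s <- numeric(G); cnt <- integer(G); n_valid <- 0L
  for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
    a <- L[x, y, z]
    if (is.na(a)) next
    tot <- 0; k <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > n[1] || yy < 1 || yy > n[2] || zz < 1 ||
          zz > n[3]) next
      b <- L[xx, yy, zz]
      if (is.na(b)) next
      tot <- tot + b; k <- k + 1
    }
    if (k == 0) next
    n_valid <- n_valid + 1L
    cnt[a] <- cnt[a] + 1L
    s[a] <- s[a] + abs(a - tot / k)
  }
  list(n = cnt, s = s, n_valid = n_valid)
}

oracle_ngldm <- function(L, G) {
  n <- dim(L)
  m <- matrix(0, G, 27)
  for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
    a <- L[x, y, z]
    if (is.na(a)) next
    j <- 1L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > n[1] || yy < 1 || yy > n[2] || zz < 1 ||
          zz > n[3]) next
      b <- L[xx, yy, zz]
      if (!is.na(b) && b == a) j <- j + 1L
    }
    m[a, j] <- m[a, j] + 1
  }
  m
}

# ---- literal-formula feature oracles (explicit loops over matrix cells) ----

oracle_glcm_features <- function(M) {
  G <- nrow(M)
  p <- if (sum(M) > 0) M / sum(M) else M
  px <- rowSums(p)
  mu <- 0; for (i in 1:G) for (j in 1:G) mu <- mu + i * p[i, j]
  out <- c(joint_maximum = max(p), joint_average = mu)
  jv <- 0; for (i in 1:G) for (j in 1:G) jv <- jv + (i - mu)^2 * p[i, j]
  je <- 0; for (i in 1:G) for (j in 1:G)
    if (p[i, j] > 0) je <- je - p[i, j] * log2(p[i, j])
  pd <- numeric(G); ps <- numeric(2 * G)
  for (i in 1:G) for (j in 1:G) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j] <- ps[i + j] + p[i, j]
  }
  da <- sum((0:(G - 1)) * pd)
  dv <- sum(((0:(G - 1)) - da)^2 * pd)
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  sa <- sum((1:(2 * G)) * ps)
  sv <- sum(((1:(2 * G)) - sa)^2 * ps)
  se <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  en <- sum(p^2)
  ct <- 0; ds <- 0; id <- 0; idn <- 0; idm <- 0; idmn <- 0; ivr <- 0
  ac <- 0; clt <- 0; cls <- 0; clp <- 0
  for (i in 1:G) for (j in 1:G) {
    ct <- ct + (i - j)^2 * p[i, j]
    ds <- ds + abs(i - j) * p[i, j]
    id <- id + p[i, j] / (1 + abs(i - j))
    idn <- idn + p[i, j] / (1 + abs(i - j) / G)
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    idmn <- idmn + p[i, j] / (1 + ((i - j) / G)^2)
    if (i != j) ivr <- ivr + p[i, j] / (i - j)^2
    ac <- ac + i * j * p[i, j]
    clt <- clt + (i + j - 2 * mu)^2 * p[i, j]
    cls <- cls + (i + j - 2 * mu)^3 * p[i, j]
    clp <- clp + (i + j - 2 * mu)^4 * p[i, j]
  }
  corr <- if (jv > 0) (ac - mu^2) / jv else 0
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    q <- px[i] * px[j]
    if (q > 0) {
      hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  ic1 <- if (hx > 0) (je - hxy1) / hx else 0
  ic2 <- sqrt(max(1 - exp(-2 * (hxy2 - je)), 0))
  c(out, joint_variance = jv, joint_entropy = je, difference_average = da,
    difference_variance = dv, difference_entropy = de, sum_average = sa,
    sum_variance = sv, sum_entropy = se, energy = en, contrast = ct,
    dissimilarity = ds, inverse_difference = id,
    inverse_difference_norm = idn, inverse_difference_moment = idm,
    inverse_difference_moment_norm = idmn, inverse_variance = ivr,
    correlation = corr, autocorrelation = ac, cluster_tendency = clt,
    cluster_shade = cls, cluster_prominence = clp,
    information_corr_1 = ic1, information_corr_2 = ic2)[
      names(radiogbm:::glcm_features_one(M))]
}

oracle_rlm_features <- function(M, n_voxels) {
  G <- nrow(M); Lm <- ncol(M)
  Ns <- sum(M)
  p <- if (Ns > 0) M / Ns else M
  sre <- lre <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  mu_i <- mu_l <- 0
  for (i in 1:G) for (l in 1:Lm) {
    sre <- sre + M[i, l] / l^2; lre <- lre + M[i, l] * l^2
    lgl <- lgl + M[i, l] / i^2; hgl <- hgl + M[i, l] * i^2
    srl <- srl + M[i, l] / (i^2 * l^2); srh <- srh + M[i, l] * i^2 / l^2
    lrl <- lrl + M[i, l] * l^2 / i^2; lrh <- lrh + M[i, l] * i^2 * l^2
    mu_i <- mu_i + i * p[i, l]; mu_l <- mu_l + l * p[i, l]
  }
  glv <- rlv <- ent <- 0
  for (i in 1:G) for (l in 1:Lm) {
    glv <- glv + (i - mu_i)^2 * p[i, l]
    rlv <- rlv + (l - mu_l)^2 * p[i, l]
    if (p[i, l] > 0) ent <- ent - p[i, l] * log2(p[i, l])
  }
  ri <- rowSums(M); rl <- colSums(M)
  div0 <- function(a, b) if (b == 0) 0 else a / b
  unname(c(div0(sre, Ns), div0(lre, Ns), div0(lgl, Ns), div0(hgl, Ns),
           div0(srl, Ns), div0(srh, Ns), div0(lrl, Ns), div0(lrh, Ns),
           div0(sum(ri^2), Ns), div0(sum(ri^2), Ns^2),
           div0(sum(rl^2), Ns), div0(sum(rl^2), Ns^2),
           div0(Ns, n_voxels), glv, rlv, ent))
}

oracle_ngtdm_features <- function(n_i, s_i, n_valid) {
  G <- length(n_i)
  p <- if (n_valid > 0) n_i / n_valid else n_i
  pres <- which(p > 0); Ngp <- length(pres)
  den <- 0; for (i in pres) den <- den + p[i] * s_i[i]
  coarseness <- if (den > 0) min(1 / den, 1e6) else 1e6
  contrast <- 0
  if (Ngp > 1 && n_valid > 0) {
    acc <- 0
    for (i in pres) for (j in pres) acc <- acc + p[i] * p[j] * (i - j)^2
    contrast <- acc / (Ngp * (Ngp - 1)) * sum(s_i[pres]) / n_valid
  }
  bden <- 0
  for (i in pres) for (j in pres) bden <- bden + abs(i * p[i] - j * p[j])
  busyness <- if (bden > 0) den / bden else 0
  complexity <- 0
  if (n_valid > 0) for (i in pres) for (j in pres)
    complexity <- complexity +
      abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
  complexity <- complexity / max(n_valid, 1)
  strength <- 0
  if (sum(s_i[pres]) > 0) {
    for (i in pres) for (j in pres)
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    strength <- strength / sum(s_i[pres])
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

oracle_ngldm_features <- function(M, n_voxels) {
  G <- nrow(M); Jm <- ncol(M)
  Ns <- sum(M)
  p <- if (Ns > 0) M / Ns else M
  acc <- stats::setNames(numeric(8), c("lde", "hde", "lgc", "hgc", "ldl",
                                       "ldh", "hdl", "hdh"))
  mu_i <- mu_j <- 0
  for (i in 1:G) for (j in 1:Jm) {
    acc["lde"] <- acc["lde"] + M[i, j] / j^2
    acc["hde"] <- acc["hde"] + M[i, j] * j^2
    acc["lgc"] <- acc["lgc"] + M[i, j] / i^2
    acc["hgc"] <- acc["hgc"] + M[i, j] * i^2
    acc["ldl"] <- acc["ldl"] + M[i, j] / (i^2 * j^2)
    acc["ldh"] <- acc["ldh"] + M[i, j] * i^2 / j^2
    acc["hdl"] <- acc["hdl"] + M[i, j] * j^2 / i^2
    acc["hdh"] <- acc["hdh"] + M[i, j] * i^2 * j^2
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  glv <- dcv <- ent <- enr <- 0
  for (i in 1:G) for (j in 1:Jm) {
    glv <- glv + (i - mu_i)^2 * p[i, j]
    dcv <- dcv + (j - mu_j)^2 * p[i, j]
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
    enr <- enr + p[i, j]^2
  }
  si <- rowSums(M); sj <- colSums(M)
  div0 <- function(a, b) if (b == 0) 0 else a / b
  unname(c(div0(acc["lde"], Ns), div0(acc["hde"], Ns), div0(acc["lgc"], Ns),
           div0(acc["hgc"], Ns), div0(acc["ldl"], Ns), div0(acc["ldh"], Ns),
           div0(acc["hdl"], Ns), div0(acc["hdh"], Ns),
           div0(sum(si^2), Ns), div0(sum(si^2), Ns^2),
           div0(sum(sj^2), Ns), div0(sum(sj^2), Ns^2),
           div0(Ns, n_voxels), glv, dcv, ent, enr, mu_j))
}

# ---- statistic oracles ----

oracle_auc <- function(scores, labels) {
  pos <- scores[labels != 0]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Harrell's C by exhaustive censoring-aware pair enumeration (continuous
# times assumed: no tied event times)
oracle_concordance <- function(lp, time, event) {
  n <- length(lp)
  num <- den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    first <- if (time[i] < time[j]) i else j
    later <- if (time[i] < time[j]) j else i
    if (!event[first]) next      # earlier time censored: not comparable
    den <- den + 1
    if (lp[first] > lp[later]) num <- num + 1
    else if (lp[first] == lp[later]) num <- num + 0.5
  }
  num / den
}

# brute-force anisotropic rim: voxel centres within distance_mm of any
# tumor voxel centre
oracle_rim <- function(tumor_arr, spacing, distance_mm) {
  n <- dim(tumor_arr)
  tv <- which(tumor_arr != 0, arr.ind = TRUE)
  rim <- array(FALSE, n)
  for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
    if (tumor_arr[x, y, z] != 0) next
    d2min <- Inf
    for (r in seq_len(nrow(tv))) {
      d2 <- ((x - tv[r, 1]) * spacing[1])^2 +
        ((y - tv[r, 2]) * spacing[2])^2 +
        ((z - tv[r, 3]) * spacing[3])^2
      if (d2 < d2min) d2min <- d2
    }
    if (d2min <= distance_mm^2) rim[x, y, z] <- TRUE
  }
  rim
}

# random small discretized volume with a random mask
random_dv <- function(dim3, G, p_mask = 0.85) {
  L <- array(sample.int(G, prod(dim3), replace = TRUE), dim3)
  msk <- array(stats::runif(prod(dim3)) < p_mask, dim3)
  if (!any(msk)) msk[1] <- TRUE
  L[!msk] <- NA_integer_
  radiogbm:::new_discretized_volume(L, G, "test", list(), c(1, 1, 1))
}

# run implementation and oracle on one discretized volume and compare all
# matrices and all 137 features
expect_texture_oracle_match <- function(dv, tol = 1e-9) {
  L <- dv$levels; G <- dv$G
  L <- radiogbm:::crop_to_mask(L)
  tm <- compute_texture_matrices(dv)
  dirs <- oracle_directions()
  n_v <- sum(!is.na(L))
  # matrices
  oc_glcm_dirs <- lapply(dirs, function(d) oracle_glcm(L, G, d))
  for (i in seq_along(dirs))
    expect_equal(tm$glcm_dirs[[i]], oc_glcm_dirs[[i]], tolerance = tol)
  expect_equal(tm$glcm, Reduce(`+`, oc_glcm_dirs), tolerance = tol)
  oc_glrlm_dirs <- lapply(dirs, function(d) oracle_glrlm(L, G, d))
  maxL <- max(vapply(oc_glrlm_dirs, ncol, 1L))
  padm <- function(m) if (ncol(m) < maxL)
    cbind(m, matrix(0, nrow(m), maxL - ncol(m))) else m
  oc_glrlm_dirs <- lapply(oc_glrlm_dirs, padm)
  expect_equal(ncol(tm$glrlm), maxL)
  for (i in seq_along(dirs))
    expect_equal(tm$glrlm_dirs[[i]], oc_glrlm_dirs[[i]], tolerance = tol)
  zl <- oracle_zones(L)
  oc_glszm <- matrix(0, G, max(zl[, 2]))
  for (r in seq_len(nrow(zl)))
    oc_glszm[zl[r, 1], zl[r, 2]] <- oc_glszm[zl[r, 1], zl[r, 2]] + 1
  expect_equal(tm$glszm, oc_glszm, tolerance = tol)
  expect_equal(tm$gldzm, oracle_gldzm(L, G), tolerance = tol)
  oc_ngtdm <- oracle_ngtdm(L, G)
  expect_equal(tm$ngtdm$n, oc_ngtdm$n)
  expect_equal(tm$ngtdm$s, oc_ngtdm$s, tolerance = tol)
  expect_equal(tm$ngtdm$n_valid, oc_ngtdm$n_valid)
  expect_equal(tm$ngldm, oracle_ngldm(L, G), tolerance = tol)
  # zone-matrix consistency invariant: sum(size * count) = in-mask voxels
  expect_equal(sum(sweep(tm$glszm, 2, seq_len(ncol(tm$glszm)), `*`)), n_v)
  # features
  f <- compute_texture_features(tm)
  oc <- c(
    stats::setNames(oracle_glcm_features(tm$glcm),
                    paste0("glcm_", names(radiogbm:::glcm_features_one(tm$glcm)))),
    stats::setNames(
      rowMeans(vapply(tm$glcm_dirs, oracle_glcm_features, numeric(25))),
      paste0("glcm_avg_", names(radiogbm:::glcm_features_one(tm$glcm)))),
    stats::setNames(oracle_rlm_features(tm$glrlm, n_v * 13),
                    paste0("glrlm_", radiogbm:::glrlm_feature_names())),
    stats::setNames(
      rowMeans(vapply(tm$glrlm_dirs, oracle_rlm_features, numeric(16),
                      n_voxels = n_v)),
      paste0("glrlm_avg_", radiogbm:::glrlm_feature_names())),
    stats::setNames(oracle_rlm_features(tm$glszm, n_v),
                    paste0("glszm_", radiogbm:::glszm_feature_names())),
    stats::setNames(oracle_rlm_features(tm$gldzm, n_v),
                    paste0("gldzm_", radiogbm:::gldzm_feature_names())),
    stats::setNames(oracle_ngtdm_features(tm$ngtdm$n, tm$ngtdm$s,
                                          tm$ngtdm$n_valid),
                    paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                                       "complexity", "strength"))),
    stats::setNames(oracle_ngldm_features(tm$ngldm, n_v),
                    paste0("ngldm_", names(radiogbm:::ngldm_features_one(
                      tm$ngldm, n_v)))))
  expect_equal(length(f), 137L)
  expect_equal(f[names(oc)], oc, tolerance = tol)
  invisible(TRUE)
}
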