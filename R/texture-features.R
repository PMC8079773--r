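# Texture feature formulas. Every feature is a plain function of its matrix,
# with explicit conventions for degenerate (single-grey-level) inputs so that
# no silent NaN can poison downstream PCA:
#   0/0 ratios -> 0; NGTDM coarseness with zero denominator -> 1e6 (cap);
#   entropies of a one-cell distribution -> 0; GLCM correlation with zero
#   marginal variance -> 0. Logarithms are base 2 throughout.

xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

safe_div <- function(num, den, default = 0) {
  if (!is.finite(den) || den == 0) default else num / den
}

glcm_features_one <- function(M) {
  G <- nrow(M)
  tot <- sum(M)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  if (tot == 0) p <- matrix(0, G, G) else p <- M / tot
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  dif <- abs(i - j)
  pd <- vapply(0:(G - 1), function(k) sum(p[dif == k]), numeric(1))
  kd <- 0:(G - 1)
  da <- sum(kd * pd)
  sm <- i + j
  ps <- vapply(2:(2 * G), function(k) sum(p[sm == k]), numeric(1))
  ks <- 2:(2 * G)
  sa <- sum(ks * ps)
  hxy <- -sum(p * xlog2(p))
  pxy <- outer(px, px)
  hxy1 <- -sum(p * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))
  hx <- -sum(px * xlog2(px))
  ic2arg <- 1 - exp(-2 * (hxy2 - hxy))
  c(joint_maximum = max(p),
    joint_average = mu,
    joint_variance = sig2,
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum((kd - da)^2 * pd),
    difference_entropy = -sum(pd * xlog2(pd)),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * ps),
    sum_entropy = -sum(ps * xlog2(ps)),
    energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(dif * p),
    inverse_difference = sum(p / (1 + dif)),
    inverse_difference_norm = sum(p / (1 + dif / G)),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inverse_difference_moment_norm = sum(p / (1 + ((i - j) / G)^2)),
    inverse_variance = sum(ifelse(dif > 0, p / dif^2, 0)),
    correlation = safe_div(sum(i * j * p) - mu^2, sig2),
    autocorrelation = sum(i * j * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    information_corr_1 = safe_div(hxy - hxy1, hx),
    information_corr_2 = sqrt(max(ic2arg, 0)))
}

rlm_style_features <- function(M, n_voxels, axis_names) {
  # shared formula set for GLRLM (axis = run length), GLSZM (zone size)
  # and GLDZM (zone distance)
  G <- nrow(M); Lm <- ncol(M)
  Ns <- sum(M)
  i <- matrix(seq_len(G), G, Lm)
  l <- t(matrix(seq_len(Lm), Lm, G))
  if (Ns == 0) p <- M else p <- M / Ns
  ri <- rowSums(M); rl <- colSums(M)
  iv <- seq_len(G); lv <- seq_len(Lm)
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  f <- c(
    safe_div(sum(rl / lv^2), Ns),
    safe_div(sum(rl * lv^2), Ns),
    safe_div(sum(ri / iv^2), Ns),
    safe_div(sum(ri * iv^2), Ns),
    safe_div(sum(M / (i^2 * l^2)), Ns),
    safe_div(sum(M * i^2 / l^2), Ns),
    safe_div(sum(M * l^2 / i^2), Ns),
    safe_div(sum(M * i^2 * l^2), Ns),
    safe_div(sum(ri^2), Ns),
    safe_div(sum(ri^2), Ns^2),
    safe_div(sum(rl^2), Ns),
    safe_div(sum(rl^2), Ns^2),
    safe_div(Ns, n_voxels),
    sum((i - mu_i)^2 * p),
    sum((l - mu_l)^2 * p),
    -sum(p * xlog2(p)))
  names(f) <- axis_names
  f
}

glrlm_feature_names <- function() {
  c("short_run_emphasis", "long_run_emphasis",
    "low_grey_run_emphasis", "high_grey_run_emphasis",
    "short_run_low_grey_emphasis", "short_run_high_grey_emphasis",
    "long_run_low_grey_emphasis", "long_run_high_grey_emphasis",
    "grey_level_nonuniformity", "grey_level_nonuniformity_norm",
    "run_length_nonuniformity", "run_length_nonuniformity_norm",
    "run_percentage", "grey_level_variance", "run_length_variance",
    "run_entropy")
}

glszm_feature_names <- function() {
  c("small_zone_emphasis", "large_zone_emphasis",
    "low_grey_zone_emphasis", "high_grey_zone_emphasis",
    "small_zone_low_grey_emphasis", "small_zone_high_grey_emphasis",
    "large_zone_low_grey_emphasis", "large_zone_high_grey_emphasis",
    "grey_level_nonuniformity", "grey_level_nonuniformity_norm",
    "zone_size_nonuniformity", "zone_size_nonuniformity_norm",
    "zone_percentage", "grey_level_variance", "zone_size_variance",
    "zone_size_entropy")
}

gldzm_feature_names <- function() {
  c("small_distance_emphasis", "large_distance_emphasis",
    "low_grey_zone_emphasis", "high_grey_zone_emphasis",
    "small_distance_low_grey_emphasis", "small_distance_high_grey_emphasis",
    "large_distance_low_grey_emphasis", "large_distance_high_grey_emphasis",
    "grey_level_nonuniformity", "grey_level_nonuniformity_norm",
    "zone_distance_nonuniformity", "zone_distance_nonuniformity_norm",
    "zone_percentage", "grey_level_variance", "zone_distance_variance",
    "zone_distance_entropy")
}

ngtdm_features_one <- function(n_i, s_i, n_valid) {
  G <- length(n_i)
  p <- if (n_valid > 0) n_i / n_valid else n_i
  present <- which(p > 0)
  Ngp <- length(present)
  ii <- matrix(present, Ngp, Ngp); jj <- t(ii)
  pi_ <- p[present]; si_ <- s_i[present]
  coarse_den <- sum(pi_ * si_)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  contrast <- if (Ngp > 1 && n_valid > 0) {
    sum(outer(pi_, pi_) * (ii - jj)^2) / (Ngp * (Ngp - 1)) * sum(si_) / n_valid
  } else 0
  busy_den <- sum(abs(outer(present * pi_, present * pi_, `-`)))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  complexity <- if (n_valid > 0 && Ngp > 0) {
    pm <- outer(pi_, pi_, `+`)
    sm <- outer(pi_ * si_, pi_ * si_, `+`)
    sum(abs(ii - jj) * sm / pm) / n_valid
  } else 0
  strength <- if (sum(si_) > 0) {
    sum(outer(pi_, pi_, `+`) * (ii - jj)^2) / sum(si_)
  } else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

ngldm_features_one <- function(M, n_voxels) {
  G <- nrow(M); Jm <- ncol(M)
  Ns <- sum(M)
  i <- matrix(seq_len(G), G, Jm)
  j <- t(matrix(seq_len(Jm), Jm, G))
  p <- if (Ns > 0) M / Ns else M
  si <- rowSums(M); sj <- colSums(M)
  iv <- seq_len(G); jv <- seq_len(Jm)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(low_dependence_emphasis = safe_div(sum(sj / jv^2), Ns),
    high_dependence_emphasis = safe_div(sum(sj * jv^2), Ns),
    low_grey_count_emphasis = safe_div(sum(si / iv^2), Ns),
    high_grey_count_emphasis = safe_div(sum(si * iv^2), Ns),
    low_dependence_low_grey_emphasis = safe_div(sum(M / (i^2 * j^2)), Ns),
    low_dependence_high_grey_emphasis = safe_div(sum(M * i^2 / j^2), Ns),
    high_dependence_low_grey_emphasis = safe_div(sum(M * j^2 / i^2), Ns),
    high_dependence_high_grey_emphasis = safe_div(sum(M * i^2 * j^2), Ns),
    grey_level_nonuniformity = safe_div(sum(si^2), Ns),
    grey_level_nonuniformity_norm = safe_div(sum(si^2), Ns^2),
    dependence_count_nonuniformity = safe_div(sum(sj^2), Ns),
    dependence_count_nonuniformity_norm = safe_div(sum(sj^2), Ns^2),
    dependence_count_percentage = safe_div(Ns, n_voxels),
    grey_level_variance = sum((i - mu_i)^2 * p),
    dependence_count_variance = sum((j - mu_j)^2 * p),
    dependence_count_entropy = -sum(p * xlog2(p)),
    dependence_count_energy = sum(p^2),
    mean_dependence_count = mu_j)
}

#' Texture features from texture matrices
#'
#' Computes the 137-feature texture set: 25 co-occurrence features twice
#' (once from the direction-merged matrix, once averaged over the 13
#' per-direction matrices), 16 run-length features twice (same two
#' aggregations), 16 size-zone, 16 distance-zone, 5 neighbourhood grey-tone
#' difference and 18 neighbourhood grey-level dependence features.
#'
#' @param tm a [compute_texture_matrices()] result.
#' @return named numeric vector of length 137.
#' @export
compute_texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrices"))
  glcm_m <- glcm_features_one(tm$glcm)
  glcm_a <- rowMeans(vapply(tm$glcm_dirs, glcm_features_one,
                            numeric(length(glcm_m))))
  glrlm_m <- rlm_style_features(tm$glrlm, tm$n_voxels * 13,
                                glrlm_feature_names())
  glrlm_a <- rowMeans(vapply(tm$glrlm_dirs, rlm_style_features,
                             numeric(16), n_voxels = tm$n_voxels,
                             axis_names = glrlm_feature_names()))
  glszm <- rlm_style_features(tm$glszm, tm$n_voxels, glszm_feature_names())
  gldzm <- rlm_style_features(tm$gldzm, tm$n_voxels, gldzm_feature_names())
  ngtdm <- ngtdm_features_one(tm$ngtdm$n, tm$ngtdm$s, tm$ngtdm$n_valid)
  ngldm <- ngldm_features_one(tm$ngldm, tm$n_voxels)
  out <- c(stats::setNames(glcm_m, paste0("glcm_", names(glcm_m))),
           stats::setNames(glcm_a, paste0("glcm_avg_", names(glcm_m))),
           stats::setNames(glrlm_m, paste0("glrlm_", names(glrlm_m))),
           stats::setNames(glrlm_a, paste0("glrlm_avg_", names(glrlm_m))),
           stats::setNames(glszm, paste0("glszm_", names(glszm))),
           stats::setNames(gldzm, paste0("gldzm_", names(gldzm))),
           stats::setNames(ngtdm, paste0("ngtdm_", names(ngtdm))),
           stats::setNames(ngldm, paste0("ngldm_", names(ngldm))))
  stopifnot(length(out) == 137L)
  out
}
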