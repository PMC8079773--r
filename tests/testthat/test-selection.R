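sim_table <- function(n, p, seed = 1) {
  with_seed <- radiogbm:::with_seed
  X <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  rownames(X) <- sprintf("P%03d", seq_len(n))
  feature_table(X)
}

test_that("scaling centres and unit-scales training columns exactly", {
  tbl <- sim_table(40, 6, seed = 2)
  tbl$values[, 3] <- tbl$values[, 3] * 50 + 200
  tbl$values[, 5] <- 4            # constant column
  sc <- scale_features(tbl)
  expect_identical(sc$dropped, "f05")
  expect_true(all(abs(colMeans(sc$train$values)) < 1e-10))
  expect_true(all(abs(apply(sc$train$values, 2, stats::var) - 1) < 1e-10))
})

test_that("the training transform is applied verbatim to validation data", {
  tr <- sim_table(30, 4, seed = 3)
  va <- sim_table(20, 4, seed = 4)
  va$values[, 2] <- tr$values[seq_len(20), 2]   # shared column values
  sc <- scale_features(tr, va)
  expect_equal(sc$apply_to$values[, 2], sc$train$values[seq_len(20), 2])
  # a feature missing from the validation table is an error
  va2 <- feature_table(va$values[, 1:3])
  expect_error(scale_features(tr, va2), "missing from apply_to")
})

test_that("Horn retention rejects noise and finds planted factors", {
  # pure noise: no component should survive the 95th-percentile bar
  nq <- horn_null_quantiles(60, 40, n_sim = 300, seed = 5)
  hits <- 0L
  for (s in 1:25) {
    tbl <- sim_table(60, 40, seed = 100 + s)
    k <- horn_retain(tbl, null_quantiles = nq)
    if (k == 0L) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.9 - 1e-9)

  # two planted orthogonal factors, each explaining ~30% of total variance
  nq2 <- horn_null_quantiles(200, 40, n_sim = 300, seed = 6)
  ok <- 0L
  for (s in 1:20) {
    Z <- radiogbm:::with_seed(300 + s, {
      f1 <- stats::rnorm(200); f2 <- stats::rnorm(200)
      E <- matrix(stats::rnorm(200 * 40), 200, 40)
      a <- sqrt(12 / 14)
      X <- sqrt(1 - a^2) * E
      X[, 1:14] <- a * f1 + X[, 1:14]
      X[, 15:28] <- a * f2 + X[, 15:28]
      X
    })
    colnames(Z) <- sprintf("f%02d", 1:40)
    if (horn_retain(feature_table(Z), null_quantiles = nq2) == 2L)
      ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.95 - 1e-9)

  # fixed seed: deterministic
  tbl <- sim_table(50, 10, seed = 9)
  expect_identical(horn_retain(tbl, n_sim = 150, seed = 4),
                   horn_retain(tbl, n_sim = 150, seed = 4))
})

test_that("features go to their greatest-contribution component", {
  L <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.5))
  rownames(L) <- c("a", "b", "c")
  gr <- assign_to_components(k = 2, loadings = L)
  expect_equal(unname(gr$assignment), c(1L, 2L, 1L))  # tie -> lowest index
  expect_equal(sum(gr$group_sizes), 3)
  expect_error(assign_to_components(k = 0, loadings = L), "k = 0")
})

test_that("block-diagonal structure is recovered by the grouping", {
  # blocks of distinct strength: with equal within-block correlations the
  # leading eigenvalues tie and the eigenvectors are free to rotate inside
  # their subspace, so exact recovery is only identifiable with distinct
  # block eigenvalues
  X <- radiogbm:::with_seed(12, {
    n <- 300
    rho <- c(0.85, 0.7, 0.55)
    Z <- matrix(stats::rnorm(n * 3), n, 3)
    out <- matrix(stats::rnorm(n * 24), n, 24)
    for (g in 1:3) {
      cols <- (g - 1) * 8 + 1:8
      out[, cols] <- sqrt(rho[g]) * Z[, g] +
        sqrt(1 - rho[g]) * out[, cols]
    }
    out
  })
  colnames(X) <- sprintf("f%02d", 1:24)
  rownames(X) <- sprintf("P%03d", 1:300)
  sc <- scale_features(feature_table(X))
  gr <- assign_to_components(sc$train, 3)
  truth <- rep(1:3, each = 8)
  # groups are recovered up to relabelling for >= 95% of features
  tab <- table(truth, gr$assignment)
  recovered <- sum(apply(tab, 1, max)) / 24
  expect_gte(recovered, 0.95)
})

test_that("screening selects the best significant feature per group", {
  set.seed(33)
  n <- 120
  y <- rep(0:1, each = n / 2)
  X <- cbind(strong = y + stats::rnorm(n, sd = 0.35),
             weak = y + stats::rnorm(n, sd = 1.2),
             noise = stats::rnorm(n))
  rownames(X) <- sprintf("P%03d", 1:n)
  tbl <- feature_table(X)
  sc <- scale_features(tbl)
  gr <- structure(list(k = 2L,
                       assignment = c(strong = 1L, weak = 1L, noise = 2L),
                       group_sizes = c(2L, 1L)), class = "pc_grouping")
  res <- screen_univariable(sc$train, gr, list(type = "binary", label = y))
  expect_equal(unname(res$selected["1"]), "strong")
  expect_false("2" %in% names(res$selected) &&
                 res$table$p[res$table$feature == "noise"] >= 0.05)
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
  # at most one selection per group
  expect_lte(max(table(res$table$group[res$table$selected])), 1)
})

test_that("a near-perfect predictor is selected with AUC ~ 1", {
  set.seed(44)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(oracle_like = y + stats::rnorm(n, sd = 0.01),
             noise = stats::rnorm(n))
  rownames(X) <- sprintf("P%03d", 1:n)
  sc <- scale_features(feature_table(X))
  gr <- structure(list(k = 1L,
                       assignment = c(oracle_like = 1L, noise = 1L),
                       group_sizes = 2L), class = "pc_grouping")
  res <- screen_univariable(sc$train, gr, list(type = "binary", label = y))
  expect_equal(unname(res$selected["1"]), "oracle_like")
  expect_gt(res$table$metric[res$table$feature == "oracle_like"], 0.99)
})

test_that("all-noise groups are usually left empty at n = 50", {
  gr <- structure(list(k = 1L, assignment = c(a = 1L, b = 1L, c = 1L),
                       group_sizes = 3L), class = "pc_grouping")
  empty <- 0L
  for (s in 1:30) {
    X <- radiogbm:::with_seed(500 + s, {
      m <- matrix(stats::rnorm(50 * 3), 50, 3)
      colnames(m) <- c("a", "b", "c"); rownames(m) <- sprintf("P%02d", 1:50)
      m
    })
    y <- rep(0:1, each = 25)
    sc <- scale_features(feature_table(X))
    res <- screen_univariable(sc$train, gr,
                              list(type = "binary", label = y))
    if (length(res$selected) == 0L) empty <- empty + 1L
  }
  # pre-chosen per-feature level 0.05, three tries: group stays empty most
  # of the time
  expect_gte(empty / 30, 0.7)
})

test_that("Cox screening ranks by model concordance", {
  sim <- simulate_cohort(cohort_spec(n_train = 150, n_validation = 10,
                                     n_groups = 2, features_per_group = 2,
                                     rho = 0.8,
                                     logistic_effects = c(0, 0),
                                     pfs2_effects = c(1.2, 0),
                                     os_effects = c(0, 0), seed = 77))
  idx <- sim$clinical$cohort == "training"
  sc <- scale_features(feature_table(sim$features$values[idx, ]))
  gr <- assign_to_components(sc$train, 2)
  res <- screen_univariable(sc$train, gr, list(
    type = "survival", time = sim$clinical$pfs2_months[idx],
    event = sim$clinical$pfs2_event[idx]))
  sel_groups <- gr$assignment[unname(res$selected)]
  informative <- unique(gr$assignment[grep("^feature_g1_", names(gr$assignment))])
  expect_true(informative %in% sel_groups)
  expect_true(all(res$table$metric >= 0.5 - 1e-9))
})
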