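test_that("phantoms are reproducible and geometrically faithful", {
  sp <- phantom_spec(seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$post$data, b$post$data)
  expect_identical(a$masks$tumoral$data, b$masks$tumoral$data)

  # analytic ellipsoid volume: (4/3) pi 13.4^3 ~ 10.08 ml
  v <- voi_volume_ml(a$masks$tumoral)
  v_true <- 4 / 3 * pi * 13.4^3 / 1000
  expect_lt(abs(v - v_true) / v_true, 0.03)

  # enhancing rim is elevated over brain by the rim contrast (before noise)
  sp0 <- phantom_spec(noise_sd = 0)
  p0 <- generate_phantom(sp0)
  rimvox <- p0$masks$tumoral$data == 1 & !p0$necrotic_core
  expect_true(all(p0$post$data[rimvox] - p0$pre$data[rimvox] ==
                    sp0$rim_contrast))
  # noiseless reference region is exactly constant
  expect_equal(stats::sd(p0$post$data[p0$masks$wm_reference$data == 1]), 0)
})

test_that("overlapping phantom ROIs are rejected with the pair named", {
  sp <- phantom_spec(wm_box_mm = rbind(c(45, 35, 50), c(70, 60, 70)))
  expect_error(generate_phantom(sp), "tumoral and wm_reference")
})

test_that("phantom spec validates semi-axes, noise and necrotic fraction", {
  expect_error(phantom_spec(tumor_semiaxes_mm = c(0, 5, 5)), "semi-axes")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(necrotic_fraction = 1), "necrotic_fraction")
})

test_that("cohort simulation validates its spec", {
  expect_error(cohort_spec(n_train = 4, n_validation = 2), "n must be >= 10")
  expect_error(cohort_spec(rho = 1), "rho")
  expect_error(cohort_spec(censoring_target = 1), "censoring_target")
  expect_error(cohort_spec(logistic_effects = c(1, 2)), "logistic_effects")
})

test_that("simulated cohorts honour their generative law", {
  # large cohort for Monte-Carlo checks
  spec <- cohort_spec(n_train = 1500, n_validation = 500, n_groups = 3,
                      features_per_group = 4, rho = 0.6,
                      logistic_effects = c(0, 0, 0),
                      pfs2_effects = c(0, 0, 0), os_effects = c(0, 0, 0),
                      censoring_target = 0.3, seed = 101)
  sim <- simulate_cohort(spec)
  X <- sim$features$values
  y <- as.integer(sim$clinical$mgmt == "methylated")

  # no signal: every feature discriminates at chance level
  aucs <- apply(X, 2, auc_mann_whitney, labels = y)
  expect_true(all(abs(aucs - 0.5) < 0.06))

  # within-group correlation matches rho within 0.05
  for (g in 1:3) {
    cols <- grep(paste0("^feature_g", g, "_"), colnames(X))
    cm <- stats::cor(X[, cols])
    off <- cm[upper.tri(cm)]
    expect_lt(max(abs(off - 0.6)), 0.05)
  }

  # censoring tuned to the target rate
  expect_lt(abs(mean(!sim$clinical$pfs2_event) - 0.3), 0.05)
  expect_lt(abs(mean(!sim$clinical$os_event) - 0.3), 0.05)

  # survival independent of features under zero effects
  cc <- evaluate_survival(X[, 1], sim$clinical$os_months,
                          sim$clinical$os_event)
  expect_lt(abs(cc$concordance - 0.5), 0.03)

  # reproducibility
  sim2 <- simulate_cohort(spec)
  expect_identical(sim$features$values, sim2$features$values)
  expect_identical(sim$clinical$pfs2_months, sim2$clinical$pfs2_months)
})

test_that("a very strong planted effect yields near-perfect latent AUC", {
  spec <- cohort_spec(n_train = 1500, n_validation = 500, n_groups = 2,
                      features_per_group = 3,
                      logistic_effects = c(5, 0),
                      pfs2_effects = c(0, 0), os_effects = c(0, 0),
                      seed = 7)
  sim <- simulate_cohort(spec)
  y <- as.integer(sim$clinical$mgmt == "methylated")
  expect_gt(auc_mann_whitney(sim$latent[, 1], y), 0.95)
})

test_that("effect calibration matches the simulator at scale", {
  beta <- calibrate_logistic_effect(0.67, rho = 0.7)
  spec <- cohort_spec(n_train = 4000, n_validation = 10, n_groups = 2,
                      features_per_group = 2, rho = 0.7,
                      logistic_effects = c(beta, 0),
                      pfs2_effects = c(0, 0), os_effects = c(0, 0),
                      seed = 31)
  sim <- simulate_cohort(spec)
  y <- as.integer(sim$clinical$mgmt == "methylated")
  a <- auc_mann_whitney(sim$features$values[, 1], y)
  expect_lt(abs(a - 0.67), 0.03)
  # concordance calibration against the proportional-hazards quadrature
  gam <- calibrate_cox_effect(0.6)
  spec2 <- cohort_spec(n_train = 4000, n_validation = 10, n_groups = 1,
                       features_per_group = 1, rho = 0.9,
                       logistic_effects = 0, pfs2_effects = gam,
                       os_effects = 0, censoring_target = 0, seed = 32)
  sim2 <- simulate_cohort(spec2)
  cc <- evaluate_survival(sim2$latent[, 1], sim2$clinical$pfs2_months,
                          sim2$clinical$pfs2_event)
  expect_lt(abs(cc$concordance - 0.6), 0.02)
})
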