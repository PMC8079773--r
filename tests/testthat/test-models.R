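test_that("AUC equals exhaustive pair counting (n <= 12) and examples", {
  expect_equal(evaluate_binary(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc,
               0.75)
  expect_equal(evaluate_binary(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_error(evaluate_binary(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(60)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(stats::rnorm(n), 1)            # provoke ties
    expect_equal(evaluate_binary(s, y)$auc, oracle_auc(s, y),
                 tolerance = 1e-12)
    # independent library cross-check of the rank statistic
    expect_equal(evaluate_binary(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                                direction = "<",
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("DeLong intervals are ordered, bounded and cover null AUCs", {
  set.seed(61)
  cover <- 0L
  for (i in 1:60) {
    y <- rep(0:1, each = 30)
    s <- stats::rnorm(60)
    ev <- evaluate_binary(s, y)
    expect_lte(ev$ci[1], ev$ci[2])
    if (ev$ci[1] <= 0.5 && 0.5 <= ev$ci[2]) cover <- cover + 1L
  }
  expect_gte(cover / 60, 0.85)
})

test_that("concordance equals censoring-aware enumeration (n <= 12)", {
  # 3 subjects, times (1,2,3), all events, predictors (3,1,2): 2/3
  ev <- evaluate_survival(c(3, 1, 2), c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(ev$concordance, 2 / 3)
  # predictor = -time: perfect ranking
  tt <- c(2.3, 0.7, 5.1, 3.3, 1.2)
  expect_equal(evaluate_survival(-tt, tt, rep(TRUE, 5))$concordance, 1)
  set.seed(62)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    tt <- stats::rexp(n)
    ee <- stats::runif(n) < 0.7
    if (sum(ee) < 2) ee[1:2] <- TRUE
    lp <- round(stats::rnorm(n), 1)
    expect_equal(evaluate_survival(lp, tt, ee)$concordance,
                 oracle_concordance(lp, tt, ee), tolerance = 1e-12)
  }
  # rank invariance: adding a constant to the linear predictor changes nothing
  expect_equal(evaluate_survival(c(1, 2, 3) + 100, c(3, 2, 1),
                                 rep(TRUE, 3))$concordance,
               evaluate_survival(c(1, 2, 3), c(3, 2, 1),
                                 rep(TRUE, 3))$concordance)
})

test_that("backward selection drops noise, keeps signal, never raises AIC", {
  kept_info <- 0L; few_noise <- 0L
  for (s in 1:15) {
    dat <- radiogbm:::with_seed(700 + s, {
      X <- matrix(stats::rnorm(400 * 6), 400, 6)
      colnames(X) <- c("info", paste0("noise", 1:5))
      rownames(X) <- sprintf("P%03d", 1:400)
      y <- stats::rbinom(400, 1, stats::plogis(1.5 * X[, "info"]))
      list(X = X, y = y)
    })
    tbl <- feature_table(dat$X)
    sc <- scale_features(tbl)
    m <- fit_multivariable(sc$train, colnames(dat$X),
                           list(type = "binary", label = dat$y))
    full <- stats::glm(dat$y ~ ., data = as.data.frame(sc$train$values),
                       family = stats::binomial())
    expect_lte(m$aic, stats::AIC(full) + 1e-9)
    if ("info" %in% m$features) kept_info <- kept_info + 1L
    if (sum(grepl("^noise", m$features)) <= 2) few_noise <- few_noise + 1L
  }
  expect_gte(kept_info / 15, 0.9)
  # AIC backward selection keeps each pure-noise variable with probability
  # P(chisq_1 > 2) ~ 0.16, so two or fewer of five should survive in ~97%
  # of runs
  expect_gte(few_noise / 15, 0.9)
})

test_that("a single uninformative candidate can yield the empty model", {
  dat <- radiogbm:::with_seed(9, {
    X <- matrix(stats::rnorm(200), 200, 1,
                dimnames = list(sprintf("P%03d", 1:200), "x"))
    list(X = X, y = rep(0:1, 100))
  })
  sc <- scale_features(feature_table(dat$X))
  m <- fit_multivariable(sc$train, "x", list(type = "binary", label = dat$y))
  expect_true(m$no_model)
  expect_error(predict(m, dat$X), "empty model")
})

test_that("Wald coverage of a known logistic coefficient is ~95%", {
  cover <- 0L
  for (s in 1:40) {
    dat <- radiogbm:::with_seed(1000 + s, {
      x <- stats::rnorm(1000)
      y <- stats::rbinom(1000, 1, stats::plogis(1.0 * x))
      list(x = x, y = y)
    })
    fit <- stats::glm(dat$y ~ dat$x, family = stats::binomial())
    ci <- suppressMessages(stats::confint.default(fit))["dat$x", ]
    if (ci[1] <= 1 && 1 <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover / 40, 0.85)
})

test_that("prediction reproduces the published worked example", {
  m <- new_radiomic_model("logistic", "ngldm_low_dependence_emphasis",
                          coefficients = 5.77, intercept = -2.46)
  p0 <- predict(m, c(ngldm_low_dependence_emphasis = 0))
  expect_equal(p0, 1 / (1 + exp(2.46)), tolerance = 1e-12)
  expect_equal(p0, 0.079, tolerance = 0.01)
  expect_equal(predict(m, c(ngldm_low_dependence_emphasis = 2.46 / 5.77)),
               0.5, tolerance = 1e-12)
  expect_error(predict(m, c(other = 1)), "missing feature")
})

test_that("model JSON serialization round-trips", {
  m <- new_radiomic_model("logistic", c("a", "b"), c(1.5, -2),
                          intercept = 0.25, center = c(a = 1, b = 2),
                          scale = c(a = 3, b = 4), aic = 12.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  X <- matrix(c(1.2, 0.4), 1, dimnames = list("P1", c("a", "b")))
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$coefficients, m$coefficients)
})

test_that("median-threshold stratification splits and tests as specified", {
  set.seed(63)
  tr_scores <- stats::rnorm(70)
  st <- stratify_logrank(tr_scores, tr_scores, stats::rexp(70),
                         rep(TRUE, 70))
  expect_lte(abs(sum(st$group == "high") - sum(st$group == "low")), 1)

  # power: hazard ratio 3 between groups, n = 100 per group
  sig <- 0L
  for (s in 1:20) {
    d <- radiogbm:::with_seed(1200 + s, {
      grp_scores <- c(stats::rnorm(100, -2), stats::rnorm(100, 2))
      tt <- c(stats::rexp(100, 1), stats::rexp(100, 3))
      list(sc = grp_scores, tt = tt)
    })
    st <- stratify_logrank(d$sc, d$sc, d$tt, rep(TRUE, 200))
    if (!is.null(st$p) && !is.na(st$p) && st$p < 0.05) sig <- sig + 1L
  }
  expect_gte(sig / 20, 0.9)

  # degenerate: all validation scores on one side of the threshold
  st2 <- stratify_logrank(c(1, 2, 3), c(10, 11, 12), c(1, 2, 3),
                          rep(TRUE, 3))
  expect_identical(st2$flag, "empty_group")
  expect_true(is.na(st2$p))
})

test_that("5-fold CV partitions correctly and is seed-stable", {
  sim <- simulate_cohort(cohort_spec(n_train = 60, n_validation = 10,
                                     n_groups = 2, features_per_group = 3,
                                     seed = 14))
  idx <- sim$clinical$cohort == "training"
  tbl <- feature_table(sim$features$values[idx, ])
  ep <- list(type = "binary",
             label = as.integer(sim$clinical$mgmt[idx] == "methylated"))
  cv <- suppressWarnings(cross_validate_5fold(tbl, ep, seed = 3,
                                              horn_n_sim = 120))
  expect_equal(sort(unique(cv$fold_of)), 1:5)
  expect_lte(diff(range(tabulate(cv$fold_of, 5))), 1)
  expect_equal(length(cv$fold_of), 60)
  cv2 <- suppressWarnings(cross_validate_5fold(tbl, ep, seed = 3,
                                               horn_n_sim = 120))
  expect_identical(cv$fold_of, cv2$fold_of)
  expect_equal(cv$folds, cv2$folds)
})

test_that("validation data cannot influence scaling or the trained model", {
  sim <- simulate_cohort(cohort_spec(n_train = 50, n_validation = 30,
                                     n_groups = 2, features_per_group = 4,
                                     seed = 15))
  idx <- sim$clinical$cohort == "training"
  tr <- feature_table(sim$features$values[idx, ])
  va <- feature_table(sim$features$values[!idx, ])
  va_poisoned <- feature_table(sim$features$values[!idx, ] * 1e6 + 4711)

  # scaling parameters and the scaled training table are identical no
  # matter what the validation cohort contains
  sc1 <- scale_features(tr, va)
  sc2 <- scale_features(tr, va_poisoned)
  expect_identical(sc1$center, sc2$center)
  expect_identical(sc1$scale, sc2$scale)
  expect_identical(sc1$train$values, sc2$train$values)

  # the fitted signature never sees validation data at all; its stored
  # transform applied to a clean validation row is reproducible bitwise
  ep <- list(type = "binary",
             label = as.integer(sim$clinical$mgmt[idx] == "methylated"))
  sig1 <- fit_radiomic_signature(tr, ep, horn_n_sim = 150, seed = 4)
  sig2 <- fit_radiomic_signature(tr, ep, horn_n_sim = 150, seed = 4)
  expect_identical(sig1$status, sig2$status)
  if (!is.null(sig1$model)) {
    expect_identical(sig1$model$coefficients, sig2$model$coefficients)
    expect_identical(predict(sig1$model, va$values),
                     predict(sig2$model, va$values))
  }
})
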