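#' Multivariable model with AIC backward selection
#'
#' Starting from the model containing all screened candidate features, the
#' variable whose removal lowers the Akaike information criterion the most
#' is dropped, repeatedly, until no removal lowers the AIC (greedy backward
#' selection, [stats::step()] with the intercept-only/null lower scope).
#' Binary endpoints use logistic regression, survival endpoints Cox
#' proportional hazards. Selection may legitimately reach the empty model;
#' the result is then flagged `no_model` rather than treated as an error.
#'
#' @param scaled scaled training [feature_table()].
#' @param candidates character vector of candidate feature names (the
#'   per-group screening representatives).
#' @param endpoint `list(type = "binary", label = ...)` or
#'   `list(type = "survival", time = ..., event = ...)`.
#' @param scaling optional result of [scale_features()]; its center/scale
#'   for the selected features are stored so the model can be applied to raw
#'   validation tables.
#' @return object of class `radiomic_model`.
#' @export
fit_multivariable <- function(scaled, candidates, endpoint, scaling = NULL) {
  stopifnot(length(candidates) >= 1)
  X <- scaled$values
  missing <- setdiff(candidates, colnames(X))
  if (length(missing))
    stop("fit_multivariable: candidate(s) not in table: ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(X[, candidates, drop = FALSE])
  type <- match.arg(endpoint$type, c("binary", "survival"))
  if (type == "binary") {
    df$.y <- endpoint$label
    full <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    if (!full$converged)
      stop("fit_multivariable: logistic fit did not converge for {",
           paste(candidates, collapse = ", "), "}")
    fin <- stats::step(full, direction = "backward",
                       scope = list(lower = ~1), trace = 0)
    cf <- stats::coef(fin)
    feats <- setdiff(names(cf), "(Intercept)")
    intercept <- unname(cf["(Intercept)"])
  } else {
    if (sum(endpoint$event) < 10)
      warning("fit_multivariable: fewer than 10 events for Cox fit")
    df$.time <- endpoint$time; df$.event <- endpoint$event
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", candidates), collapse = " + ")))
    full <- survival::coxph(fml, data = df, model = TRUE)
    fin <- stats::step(full, direction = "backward",
                       scope = list(lower = ~1), trace = 0)
    cf <- stats::coef(fin)
    feats <- names(cf)
    intercept <- 0
  }
  if (any(!is.finite(cf)))
    stop("fit_multivariable: non-finite coefficient(s) in final model for {",
         paste(names(cf), collapse = ", "), "}")
  new_radiomic_model(
    type = type, features = feats,
    coefficients = if (length(feats)) cf[feats] else numeric(0),
    intercept = intercept,
    center = if (!is.null(scaling)) scaling$center[feats] else NULL,
    scale = if (!is.null(scaling)) scaling$scale[feats] else NULL,
    aic = stats::AIC(fin), candidates = candidates)
}

#' @rdname fit_multivariable
#' @param type,features,coefficients,intercept,center,scale,aic model
#'   components (see fields of the returned object).
#' @export
new_radiomic_model <- function(type, features, coefficients, intercept = 0,
                               center = NULL, scale = NULL, aic = NA_real_,
                               candidates = features) {
  stopifnot(type %in% c("logistic", "cox", "binary", "survival"))
  type <- c(binary = "logistic", survival = "cox",
            logistic = "logistic", cox = "cox")[[type]]
  structure(list(type = type, features = features,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                features),
                 intercept = intercept, center = center, scale = scale,
                 aic = aic, candidates = candidates,
                 no_model = length(features) == 0L),
            class = "radiomic_model")
}

#' @export
print.radiomic_model <- function(x, ...) {
  if (x$no_model) {
    cat("<radiomic_model> ", x$type, ": no model (backward selection ",
        "reached the empty model)\n", sep = "")
  } else {
    cat("<radiomic_model> ", x$type, ", AIC ", signif(x$aic, 5), "\n",
        sep = "")
    if (x$type == "logistic")
      cat("  intercept: ", signif(x$intercept, 5), "\n", sep = "")
    for (f in x$features)
      cat("  ", f, ": ", signif(x$coefficients[f], 5), "\n", sep = "")
  }
  invisible(x)
}

#' Risk prediction from a fitted model
#'
#' Logistic models return the event probability; Cox models return the
#' linear predictor (log relative hazard). When the model stores training
#' scaling parameters they are applied to the supplied features first, so
#' validation tables enter on the raw scale.
#'
#' @param object a `radiomic_model`.
#' @param features [feature_table()], matrix, or named list/vector of
#'   feature values.
#' @param ... unused.
#' @return numeric vector of risk scores.
#' @export
predict.radiomic_model <- function(object, features, ...) {
  if (object$no_model)
    stop("predict.radiomic_model: empty model cannot predict")
  X <- if (inherits(features, "feature_table")) features$values
  else if (is.matrix(features)) features
  else matrix(unlist(features), nrow = 1,
              dimnames = list(NULL, names(features)))
  missing <- setdiff(object$features, colnames(X))
  if (length(missing))
    stop("predict.radiomic_model: missing feature(s): ",
         paste(missing, collapse = ", "))
  V <- X[, object$features, drop = FALSE]
  if (!is.null(object$center))
    V <- scale(V, center = object$center[object$features],
               scale = object$scale[object$features])
  lp <- drop(V %*% object$coefficients) + object$intercept
  if (object$type == "logistic") stats::plogis(lp) else unname(lp)
}

# Mann-Whitney AUC with half credit for ties (rank formula)
auc_mann_whitney <- function(scores, labels) {
  y <- as.integer(labels != 0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("auc_mann_whitney: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary-model evaluation: AUC with DeLong interval
#'
#' AUC is the Mann-Whitney statistic of the risk scores (ties get half
#' credit); the 95% confidence interval uses the DeLong variance method.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 (or logical) outcome; both classes must be present.
#' @param conf_level confidence level (default 0.95).
#' @return list: `auc`, `ci` (length-2), `n`.
#' @export
evaluate_binary <- function(scores, labels, conf_level = 0.95) {
  y <- as.integer(labels != 0)
  if (length(unique(y)) < 2)
    stop("evaluate_binary: both classes must be present")
  a <- auc_mann_whitney(scores, y)
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  # perfectly separated scores give a degenerate (point) interval; pROC
  # warns about it but the value is correct
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(
    roc, conf.level = conf_level, method = "delong")))[c(1, 3)]
  list(auc = a, ci = ci, n = length(y))
}

#' Survival-model evaluation: Harrell concordance with interval
#'
#' Harrell's C over the censoring-aware comparable pairs (higher risk score
#' should predict shorter survival); the interval uses the asymptotic
#' variance of the concordance estimator.
#'
#' @param lp linear predictors (log relative hazard; higher = higher risk).
#' @param time,event survival times (months) and event flags.
#' @param conf_level confidence level (default 0.95).
#' @return list: `concordance`, `ci`, `n`, `comparable` (pair count).
#' @export
evaluate_survival <- function(lp, time, event, conf_level = 0.95) {
  cc <- survival::concordance(survival::Surv(time, event) ~ lp,
                              reverse = TRUE)
  pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (pairs < 2)
    stop("evaluate_survival: fewer than 2 comparable pairs")
  se <- sqrt(cc$var)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(concordance = unname(cc$concordance),
       ci = unname(cc$concordance + c(-1, 1) * z * se),
       n = length(lp), comparable = unname(pairs))
}

#' Median-threshold risk stratification with log-rank test
#'
#' The risk threshold is the median prediction in the training cohort; the
#' cohort under evaluation is split into high-risk (score strictly greater
#' than the threshold) and low-risk groups, compared with the two-group
#' log-rank test.
#'
#' @param train_scores training-cohort predictions (define the threshold).
#' @param scores predictions of the cohort to stratify.
#' @param time,event survival data of that cohort.
#' @return list: `threshold`, `group` (factor low/high), `logrank_chisq`,
#'   `p`, `flag` (NULL or "empty_group").
#' @export
stratify_logrank <- function(train_scores, scores, time, event) {
  if (length(train_scores) == 0)
    stop("stratify_logrank: empty training scores")
  thr <- stats::median(train_scores)
  grp <- factor(ifelse(scores > thr, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0))
    return(list(threshold = thr, group = grp, logrank_chisq = NA_real_,
                p = NA_real_, flag = "empty_group"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(threshold = thr, group = grp, logrank_chisq = unname(sd_$chisq),
       p = p, flag = NULL)
}

#' Signature fitting pipeline (scale, group, screen, fit)
#'
#' The training-cohort sequence used for every endpoint branch: scale
#' features, retain components by Horn's method, group features by greatest
#' squared loading, screen univariably within groups, and fit the
#' multivariable model with AIC backward selection on the group
#' representatives. If Horn retains no component, all features form a single
#' group (fallback). If no feature passes screening the branch reports
#' "no model".
#'
#' @param train raw training [feature_table()].
#' @param endpoint endpoint list (see [fit_multivariable()]).
#' @param horn_n_sim,horn_percentile,seed Horn parallel-analysis settings.
#' @param alpha univariable screening level.
#' @param null_quantiles optional precomputed Horn null quantiles.
#' @return list of class `radiomic_signature`: `model` (or NULL),
#'   `scaling`, `grouping`, `screening`, `status`
#'   ("ok"/"no_significant_features").
#' @export
fit_radiomic_signature <- function(train, endpoint, horn_n_sim = 1000,
                                   horn_percentile = 0.95, seed = 1L,
                                   alpha = 0.05, null_quantiles = NULL) {
  sc <- scale_features(train)
  k <- horn_retain(sc$train, n_sim = horn_n_sim,
                   percentile = horn_percentile, seed = seed,
                   null_quantiles = null_quantiles)
  if (k < 1) k <- 1  # single-group fallback on pure-noise spectra
  grouping <- assign_to_components(sc$train, k)
  screening <- screen_univariable(sc$train, grouping, endpoint, alpha)
  if (length(screening$selected) == 0L)
    return(structure(list(model = NULL, scaling = sc, grouping = grouping,
                          screening = screening,
                          status = "no_significant_features"),
                     class = "radiomic_signature"))
  model <- fit_multivariable(sc$train, unname(screening$selected), endpoint,
                             scaling = sc)
  status <- if (model$no_model) "no_model" else "ok"
  structure(list(model = model, scaling = sc, grouping = grouping,
                 screening = screening, status = status),
            class = "radiomic_signature")
}

#' @export
print.radiomic_signature <- function(x, ...) {
  cat("<radiomic_signature> status=", x$status, ", groups=", x$grouping$k,
      "\n", sep = "")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

#' Stratified 5-fold cross validation of the full pipeline
#'
#' Folds are stratified by the endpoint (class for binary, event flag for
#' survival); scaling, Horn retention, grouping, screening and model fitting
#' are re-run inside every training fold, and the held-out fold is scored
#' with the fold's own model. Folds whose test part loses a class or all
#' events, or whose training part finds no model, are skipped with a
#' warning.
#'
#' @param tbl raw [feature_table()].
#' @param endpoint endpoint list.
#' @param seed fold-assignment seed.
#' @param n_folds number of folds (default 5).
#' @param ... passed to [fit_radiomic_signature()].
#' @return list: `folds` (per-fold metric), `mean_metric`, `n_used`.
#' @export
cross_validate_5fold <- function(tbl, endpoint, seed = 1L, n_folds = 5, ...) {
  n <- nrow(tbl$values)
  if (n < 10) stop("cross_validate_5fold: need n >= 10")
  strata <- if (endpoint$type == "binary") as.integer(endpoint$label != 0)
  else as.integer(endpoint$event != 0)
  fold <- integer(n)
  fold_of <- with_seed(seed, {
    offset <- 0L  # continue round-robin across strata: global sizes differ <= 1
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
    fold
  })
  metrics <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold_of != f; te <- !tr
    ep_tr <- subset_endpoint(endpoint, tr)
    ep_te <- subset_endpoint(endpoint, te)
    if (endpoint$type == "binary" && length(unique(ep_te$label)) < 2) {
      warning("fold ", f, ": test part lost a class; skipped"); next
    }
    if (endpoint$type == "survival" && sum(ep_te$event) == 0) {
      warning("fold ", f, ": test part has no events; skipped"); next
    }
    tr_tbl <- feature_table(tbl$values[tr, , drop = FALSE], tbl$family,
                            tbl$voi, tbl$provenance)
    sig <- fit_radiomic_signature(tr_tbl, ep_tr, ...)
    if (is.null(sig$model) || sig$model$no_model) {
      warning("fold ", f, ": no model; skipped"); next
    }
    sc <- predict(sig$model, tbl$values[te, , drop = FALSE])
    metrics[f] <- if (endpoint$type == "binary")
      auc_mann_whitney(sc, ep_te$label)
    else evaluate_survival(sc, ep_te$time, ep_te$event)$concordance
  }
  list(folds = metrics, mean_metric = mean(metrics, na.rm = TRUE),
       n_used = sum(!is.na(metrics)), fold_of = fold_of)
}

subset_endpoint <- function(endpoint, idx) {
  out <- endpoint
  for (f in intersect(names(endpoint), c("label", "time", "event")))
    out[[f]] <- endpoint[[f]][idx]
  out
}
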