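#' Feature scaling with training-derived parameters
#'
#' Centres and scales every training column to mean 0 / variance 1 and
#' applies the *training-derived* transform to the second table, preserving
#' external-validation discipline (no statistic of the validation cohort may
#' influence any trained component). Constant training columns cannot be
#' scaled; they are dropped from both tables and recorded.
#'
#' @param train training [feature_table()].
#' @param apply_to optional second `feature_table` (e.g. the validation
#'   cohort) transformed with the training parameters.
#' @return list with `train`, `apply_to` (scaled tables), `center`, `scale`
#'   (named vectors) and `dropped` (constant features).
#' @export
scale_features <- function(train, apply_to = NULL) {
  stopifnot(inherits(train, "feature_table"))
  X <- train$values
  if (nrow(X) < 2) stop("scale_features: need >= 2 training rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[!is.finite(scl) | scl == 0]
  keep <- setdiff(colnames(X), dropped)
  if (length(keep) == 0L) stop("scale_features: all features constant")
  Xs <- scale(X[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  out_train <- feature_table(Xs, train$family[keep], train$voi,
                             train$provenance)
  out_apply <- NULL
  if (!is.null(apply_to)) {
    Y <- apply_to$values
    missing <- setdiff(keep, colnames(Y))
    if (length(missing))
      stop("scale_features: features missing from apply_to table: ",
           paste(utils::head(missing, 5), collapse = ", "))
    Ys <- scale(Y[, keep, drop = FALSE], center = ctr[keep],
                scale = scl[keep])
    out_apply <- feature_table(Ys, apply_to$family[keep], apply_to$voi,
                               apply_to$provenance)
  }
  list(train = out_train, apply_to = out_apply,
       center = ctr[keep], scale = scl[keep], dropped = dropped)
}

#' Horn's parallel analysis for component retention
#'
#' Retains the leading principal components of the feature correlation
#' matrix whose eigenvalues exceed the corresponding per-rank `percentile`
#' of eigenvalues obtained from `n_sim` standard-normal datasets of the same
#' shape. Counting stops at the first component that fails its threshold.
#' Because the analysis is correlation-based it is invariant to any
#' rescaling of individual features.
#'
#' @param scaled a scaled [feature_table()] or numeric matrix.
#' @param n_sim number of null simulations (>= 100).
#' @param percentile null eigenvalue percentile (default 0.95).
#' @param seed integer seed for the null simulations.
#' @param null_quantiles optional precomputed [horn_null_quantiles()] result
#'   for this data shape, to amortize the null simulation across calls.
#' @return integer: number of retained components.
#' @export
horn_retain <- function(scaled, n_sim = 1000, percentile = 0.95, seed = 1L,
                        null_quantiles = NULL) {
  X <- if (inherits(scaled, "feature_table")) scaled$values else scaled
  n <- nrow(X); p <- ncol(X)
  ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  if (is.null(null_quantiles))
    null_quantiles <- horn_null_quantiles(n, p, n_sim, percentile, seed)
  stopifnot(length(null_quantiles) == p)
  exceeds <- ev > null_quantiles
  k <- if (all(exceeds)) p else which(!exceeds)[1] - 1L
  as.integer(k)
}

#' @rdname horn_retain
#' @param n,p data shape (rows, columns).
#' @export
horn_null_quantiles <- function(n, p, n_sim = 1000, percentile = 0.95,
                                seed = 1L) {
  if (n_sim < 100) stop("horn_null_quantiles: n_sim must be >= 100")
  with_seed(seed, {
    evs <- matrix(0, n_sim, p)
    for (s in seq_len(n_sim)) {
      Z <- matrix(stats::rnorm(n * p), n, p)
      evs[s, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                        only.values = TRUE)$values
    }
    apply(evs, 2, stats::quantile, probs = percentile, names = FALSE)
  })
}

#' Assignment of features to retained components
#'
#' Assigns every feature to the retained principal component on which its
#' contribution — the squared loading, i.e. the feature's share of the
#' component's variance — is greatest. Exact ties go to the lowest component
#' index. Each retained component then defines one group of correlated
#' features.
#'
#' @param scaled scaled [feature_table()] or matrix (used to compute
#'   loadings), or a loading matrix directly via `loadings =`.
#' @param k number of retained components (>= 1).
#' @param loadings optional features x components loading matrix; computed
#'   from `scaled` by PCA of the correlation matrix when absent.
#' @return object of class `pc_grouping`: list with `k`, `assignment`
#'   (named integer vector), `loadings`, `group_sizes`.
#' @export
assign_to_components <- function(scaled = NULL, k, loadings = NULL) {
  if (k < 1)
    stop("assign_to_components: no components retained (k = 0); fall back ",
         "to a single feature group or skip grouping")
  if (is.null(loadings)) {
    X <- if (inherits(scaled, "feature_table")) scaled$values else scaled
    eg <- eigen(stats::cor(X), symmetric = TRUE)
    loadings <- eg$vectors
    rownames(loadings) <- colnames(X)
  }
  k <- min(as.integer(k), ncol(loadings))
  L2 <- loadings[, seq_len(k), drop = FALSE]^2
  assignment <- apply(L2, 1, which.max)  # which.max: lowest index on ties
  sizes <- tabulate(assignment, nbins = k)
  structure(list(k = k, assignment = assignment,
                 loadings = loadings[, seq_len(k), drop = FALSE],
                 group_sizes = sizes),
            class = "pc_grouping")
}

#' @export
print.pc_grouping <- function(x, ...) {
  cat("<pc_grouping> ", x$k, " groups, sizes: ",
      paste(x$group_sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Univariable screening within feature groups
#'
#' Fits one univariable model per feature (logistic regression for a binary
#' endpoint, Cox proportional hazards for a survival endpoint), records the
#' Wald p-value and the discrimination metric (AUC of the fitted score for
#' binary endpoints, Harrell concordance for survival), and selects per
#' group the feature with the best metric among those with p < `alpha` — or
#' none. Metric ties break by smaller p-value, then feature name. Complete
#' separation in a logistic fit keeps the feature with metric 1 and a
#' separation flag.
#'
#' @param scaled scaled training [feature_table()].
#' @param grouping a [assign_to_components()] result.
#' @param endpoint list: either `list(type = "binary", label = <0/1>)` or
#'   `list(type = "survival", time = <months>, event = <logical>)`.
#' @param alpha significance level for inclusion (default 0.05).
#' @return object of class `screening_result`: data.frame `table` (feature,
#'   group, p, metric, separation, selected) and `selected` (named character
#'   vector, one feature per group that had a significant candidate).
#' @export
screen_univariable <- function(scaled, grouping, endpoint, alpha = 0.05) {
  X <- scaled$values
  feats <- colnames(X)
  stopifnot(all(feats %in% names(grouping$assignment)))
  type <- match.arg(endpoint$type, c("binary", "survival"))
  p <- metric <- sep <- numeric(length(feats))
  for (i in seq_along(feats)) {
    x <- X[, i]
    if (type == "binary") {
      y <- endpoint$label
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      separated <- !fit$converged ||
        max(abs(fit$coefficients), na.rm = TRUE) > 20
      if (separated) {
        p[i] <- 0; metric[i] <- 1; sep[i] <- 1
      } else {
        cf <- summary(fit)$coefficients
        p[i] <- cf["x", 4]
        metric[i] <- auc_mann_whitney(stats::fitted(fit), y)
      }
    } else {
      srv <- survival::Surv(endpoint$time, endpoint$event)
      fit <- survival::coxph(srv ~ x)
      p[i] <- summary(fit)$coefficients["x", 5]
      cidx <- survival::concordance(fit)
      metric[i] <- cidx$concordance
    }
  }
  tab <- data.frame(feature = feats,
                    group = grouping$assignment[feats],
                    p = p, metric = metric, separation = as.logical(sep),
                    stringsAsFactors = FALSE)
  selected <- character(0)
  for (g in seq_len(grouping$k)) {
    cand <- tab[tab$group == g & tab$p < alpha, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ord <- order(-cand$metric, cand$p, cand$feature)
    selected[as.character(g)] <- cand$feature[ord[1]]
  }
  tab$selected <- tab$feature %in% selected
  structure(list(table = tab, selected = selected, type = type,
                 alpha = alpha),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", nrow(x$table), " features screened (",
      x$type, "), ", length(x$selected), " group representative(s): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}
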