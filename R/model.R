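#' Log-cosh objective: gradient and hessian
#'
#' The model trains with the log-cosh loss `L(r) = log cosh r`, a smooth
#' approximation to absolute loss: near 0 it behaves like `r^2 / 2` and for
#' large `|r|` like `|r| - log 2`.  Its gradient is `tanh(r)` and hessian
#' `1 - tanh(r)^2`, both numerically stable for arbitrarily large residuals.
#'
#' @param residuals predicted-minus-true residuals (ug/m^3).
#' @return List with `grad` and `hess`, elementwise.
#' @examples
#' logcosh_objective(c(0, 1))  # grad 0, 0.7616; hess 1, 0.4200
#' @export
logcosh_objective <- function(residuals) {
  stopifnot(all(is.finite(residuals)))
  t <- tanh(residuals)
  list(grad = t, hess = 1 - t^2)
}

#' Log-cosh loss, numerically stable
#'
#' Computes `log(cosh(r))` without overflow via
#' `|r| + log1p(exp(-2|r|)) - log 2`.
#' @param r numeric residuals.
#' @return `log(cosh(r))`, elementwise.
#' @export
logcosh_loss <- function(r) {
  a <- abs(r)
  a + log1p(exp(-2 * a)) - log(2)
}

# Hyperparameter domains of the boosted-tree residual learner.
.hp_trees <- c(10L, 25L, 50L, 100L)
.hp_depth <- c(3L, 6L, 9L)
.hp_eta <- c(0.01, 0.5)
.hp_lam <- c(2^-10, 2^10)

validate_hp <- function(hp, allow_zero_trees = FALSE) {
  hp <- as.list(hp)
  stopifnot(all(c("n_trees", "max_depth", "eta", "lam") %in% names(hp)))
  ok_trees <- hp$n_trees %in% .hp_trees ||
    (allow_zero_trees && hp$n_trees == 0L)
  if (!ok_trees) stop("n_trees outside {10, 25, 50, 100}")
  if (!hp$max_depth %in% .hp_depth) stop("max_depth outside {3, 6, 9}")
  if (hp$eta < .hp_eta[1] || hp$eta > .hp_eta[2]) stop("eta outside [0.01, 0.5]")
  if (hp$lam < .hp_lam[1] || hp$lam > .hp_lam[2]) {
    stop("lam outside [2^-10, 2^10]")
  }
  hp
}

#' Maximin Latin-hypercube hyperparameter sample
#'
#' Draws `n` hyperparameter vectors from the tuning space with a maximin
#' Latin-hypercube design (via [lhs::maximinLHS()]) on the 4-D unit cube,
#' mapped to the domains: number of trees in `{10, 25, 50, 100}` and max
#' depth in `{3, 6, 9}` by equal-width binning of the unit interval, and the
#' learning rate `eta` in `[0.01, 0.5]` and ridge penalty `lam` in
#' `[2^-10, 2^10]` on the log scale.
#'
#' @param n number of vectors (>= 2; the tuning default is 25).
#' @param seed integer seed; the design is deterministic given it.
#' @return Tibble with columns `n_trees`, `max_depth`, `eta`, `lam` and an
#'   attribute `"unit_design"` holding the raw unit-cube coordinates.
#' @export
sample_hyperparameters <- function(n = 25, seed = 1) {
  stopifnot(n >= 2)
  u <- with_seed(seed, lhs::maximinLHS(n, 4))
  bin <- function(x, k) pmin(pmax(ceiling(x * k), 1L), k)
  out <- tibble::tibble(
    n_trees = .hp_trees[bin(u[, 1], 4L)],
    max_depth = .hp_depth[bin(u[, 2], 3L)],
    eta = exp(log(.hp_eta[1]) + u[, 3] * diff(log(.hp_eta))),
    lam = 2^(-10 + u[, 4] * 20)
  )
  attr(out, "unit_design") <- u
  out
}

#' Fit the IDW-residualized boosted-tree exposure model
#'
#' Trains an xgboost ensemble with the log-cosh objective on the residual
#' `observed - idw_baseline`; predictions later add the baseline back.  The
#' baseline is also available to the trees as one of the 14 predictors.
#' Training is single-threaded with exact tree growth by default so that
#' fits are bit-reproducible; pass `nthread > 1` to trade that for speed.
#'
#' With `n_trees = 0` (an ablation switch outside the tuning domain) no
#' ensemble is trained and predictions equal the IDW baseline exactly.
#'
#' @param features feature table from [training_features()] (or any table
#'   with [feature_columns()]); every row must have a finite
#'   `idw_baseline`.
#' @param targets observed concentrations (ug/m^3); defaults to
#'   `features$observed`.
#' @param hp hyperparameter vector: list/one-row tibble with `n_trees`,
#'   `max_depth`, `eta`, `lam`.
#' @param target_kind `"mean"` or `"max"`, recorded in the model.
#' @param seed integer seed passed to xgboost.
#' @param nthread xgboost thread count.
#' @return Object of class `exposure_model`.
#' @export
fit_exposure_model <- function(features, targets = features$observed, hp,
                               target_kind = c("mean", "max"), seed = 0,
                               nthread = 1) {
  target_kind <- match.arg(target_kind)
  hp <- validate_hp(hp, allow_zero_trees = TRUE)
  X <- feature_matrix(features)
  if (nrow(X) == 0) stop("empty training set")
  if (is.null(targets) || any(!is.finite(targets))) {
    stop("targets must be finite")
  }
  if (any(!is.finite(X[, "idw_baseline"]))) {
    stop("every training row needs a finite idw_baseline")
  }
  booster <- NULL
  if (hp$n_trees > 0) {
    resid <- targets - X[, "idw_baseline"]
    dtrain <- xgboost::xgb.DMatrix(X, label = resid, nthread = nthread)
    booster <- xgboost::xgb.train(
      params = list(max_depth = hp$max_depth, eta = hp$eta, lambda = hp$lam,
                    base_score = 0, tree_method = "exact",
                    nthread = nthread, seed = as.integer(seed)),
      data = dtrain, nrounds = hp$n_trees, verbose = 0,
      objective = function(preds, dtrain) {
        logcosh_objective(preds - xgboost::getinfo(dtrain, "label"))
      })
  }
  structure(list(booster = booster, hp = hp, target_kind = target_kind,
                 feature_names = colnames(X), seed = as.integer(seed),
                 n_rows = nrow(X)),
            class = "exposure_model")
}

#' Predict from a fitted exposure model
#'
#' Prediction is `idw_baseline + ensemble output`; rows are independent, so
#' permuting them permutes predictions identically.
#'
#' @param object an `exposure_model`.
#' @param newdata feature table whose columns match the training contract.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (ug/m^3).
#' @export
predict.exposure_model <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  if (!identical(colnames(X), object$feature_names)) {
    stop("feature columns do not match the model's training contract")
  }
  ens <- if (is.null(object$booster)) {
    rep(0, nrow(X))
  } else {
    predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  }
  X[, "idw_baseline"] + ens
}

#' Raw ensemble output (residual scale)
#'
#' The tree-ensemble component of a prediction, i.e. `predict() -
#' idw_baseline`.  Exposed for residualization-consistency checks.
#' @inheritParams predict.exposure_model
#' @return Numeric vector (ug/m^3, residual scale).
#' @export
ensemble_output <- function(object, newdata) {
  predict(object, newdata) - feature_matrix(newdata)[, "idw_baseline"]
}

#' @export
print.exposure_model <- function(x, ...) {
  cat("<exposure_model> target ", x$target_kind, ", ",
      if (is.null(x$booster)) "IDW-only (no ensemble)" else
        sprintf("%d trees, depth %d, eta %.3g, lambda %.3g",
                x$hp$n_trees, x$hp$max_depth, x$hp$eta, x$hp$lam),
      ", trained on ", x$n_rows, " rows\n", sep = "")
  invisible(x)
}

#' Tune hyperparameters by twofold station-wise cross-validation
#'
#' Stations are split at random (under `seed`) into two folds.  Each
#' candidate is fitted on one fold's station-days and scored on the other,
#' in both directions, and the candidate with the smallest pooled mean
#' absolute error wins (ties break toward the earlier candidate).  IDW
#' baselines are recomputed inside each direction from the training fold's
#' stations only — the predicted fold's observations never enter the
#' baseline, mirroring the leakage rule of the outer cross-validation.
#'
#' @param features training feature table from [training_features()]
#'   (needs `station_id`, `date`, `observed`, coordinates).
#' @param candidates tibble of hyperparameter vectors, e.g. from
#'   [sample_hyperparameters()].
#' @param seed integer seed for the station split and the fits.
#' @param nthread xgboost thread count.
#' @param idw_exponent IDW distance exponent.
#' @return The winning candidate (one-row tibble) with attributes
#'   `"scores"` (pooled MAE per candidate) and `"folds"` (the station
#'   split).
#' @export
tune_hyperparameters <- function(features, candidates, seed = 1, nthread = 1,
                                 idw_exponent = 2) {
  stations <- unique(features$station_id)
  if (length(stations) < 2) stop("tuning needs at least 2 distinct stations")
  perm <- with_seed(seed, sample(stations))
  fold_a <- perm[seq_len(floor(length(stations) / 2))]
  fold_b <- setdiff(perm, fold_a)
  if (length(intersect(fold_a, fold_b)) > 0) {
    stop("a station appears in both tuning folds")
  }
  sources <- tibble::tibble(station_id = features$station_id,
                            x = features$x, y = features$y,
                            date = features$date, value = features$observed)

  direction <- function(train_st, test_st) {
    src <- sources[sources$station_id %in% train_st, ]
    tr <- features[features$station_id %in% train_st, ]
    te <- features[features$station_id %in% test_st, ]
    tr$idw_baseline <- idw_from_station_days(tr, src, exponent = idw_exponent,
                                             exclude_self = TRUE)
    te$idw_baseline <- idw_from_station_days(te, src, exponent = idw_exponent,
                                             exclude_self = FALSE)
    tr <- tr[is.finite(tr$idw_baseline), ]
    te <- te[is.finite(te$idw_baseline), ]
    list(tr = tr, te = te)
  }
  dirs <- list(direction(fold_a, fold_b), direction(fold_b, fold_a))
  # a one-station training fold has no defined IDW baselines at all: that
  # direction cannot be scored
  dirs <- Filter(function(d) nrow(d$tr) > 0 && nrow(d$te) > 0, dirs)

  scores <- if (length(dirs) == 0) {
    warning("no scoreable tuning direction (single-station folds); ",
            "returning the first candidate")
    rep(NA_real_, nrow(candidates))
  } else {
    vapply(seq_len(nrow(candidates)), function(i) {
      hp <- candidates[i, ]
      abs_err <- unlist(lapply(dirs, function(d) {
        m <- fit_exposure_model(d$tr, hp = hp, seed = seed,
                                nthread = nthread)
        abs(predict(m, d$te) - d$te$observed)
      }))
      mean(abs_err)
    }, numeric(1))
  }

  best <- if (all(is.na(scores))) 1L else which.min(scores)  # first on ties
  out <- candidates[best, ]
  attr(out, "scores") <- scores
  attr(out, "folds") <- list(fold_a = fold_a, fold_b = fold_b)
  out
}
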