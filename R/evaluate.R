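#' Absolute-loss-first prediction metrics
#'
#' Computes the evaluation row used throughout: MAE (mean absolute error of
#' predictions), MAD (mean absolute deviation of the observations from
#' their median — the absolute-loss baseline spread), RMSE, SD, and
#' `R^2 = 1 - MSE / variance(observed)`.  Variance and SD use the
#' population (divide-by-n) convention, which keeps the R^2 identity
#' self-consistent; the median uses the midpoint convention on even n.
#'
#' @param observed,predicted equal-length finite numeric vectors (ug/m^3).
#' @return One-row tibble: `n_obs`, `R2`, `SD`, `RMSE`, `MAD`, `MAE`.  `R2`
#'   is `NA` when the observations have zero variance.
#' @examples
#' compute_metrics(c(1, 2, 3, 6), c(2, 2, 2, 2))
#' @export
compute_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0,
            all(is.finite(observed)), all(is.finite(predicted)))
  mse <- mean((observed - predicted)^2)
  v <- pop_var(observed)
  tibble::tibble(
    n_obs = length(observed),
    R2 = if (v > 0) 1 - mse / v else NA_real_,
    SD = sqrt(v),
    RMSE = sqrt(mse),
    MAD = mean(abs(observed - median(observed))),
    MAE = mean(abs(observed - predicted))
  )
}

# Build the per-fold train/test tables for one leave-one-station-out fold.
# IDW baselines on both sides are recomputed from the source set minus the
# held-out station (training rows additionally exclude their own station).
# `include_held_out_in_idw = TRUE` deliberately breaks the leakage rule by
# keeping the held-out station among the training-side sources; it exists so
# that validation can demonstrate the leakage the design avoids.
loso_fold <- function(shell, sources, held_out, idw_exponent = 2,
                      include_held_out_in_idw = FALSE) {
  src_train <- if (include_held_out_in_idw) {
    sources
  } else {
    sources[sources$station_id != held_out, ]
  }
  src_test <- sources[sources$station_id != held_out, ]
  train <- shell[shell$station_id != held_out, ]
  test <- shell[shell$station_id == held_out, ]
  train$idw_baseline <- idw_from_station_days(train, src_train,
                                              exponent = idw_exponent,
                                              exclude_self = TRUE)
  test$idw_baseline <- idw_from_station_days(test, src_test,
                                             exponent = idw_exponent,
                                             exclude_self = TRUE)
  list(train = train[is.finite(train$idw_baseline), ],
       test = test[is.finite(test$idw_baseline), ])
}

#' Leave-one-station-out cross-validation
#'
#' One fold per station: the station's days are the test set, all other
#' stations train.  To avoid leakage, every IDW baseline in the fold — for
#' training rows and test rows alike — is recomputed from same-day
#' observations excluding the held-out station.  Hyperparameter tuning
#' ([tune_hyperparameters()]) runs nested inside each fold on the training
#' stations only.
#'
#' @param fixture a [make_region_fixture()] object.
#' @param station_days tibble from [aggregate_station_days()].
#' @param predictors a [simulate_predictors()] object.
#' @param target `"mean"` or `"max"`.
#' @param candidates hyperparameter candidates for the nested tuning.
#' @param seed integer seed; nested tuning in fold `k` uses `seed + k`.
#' @param nthread xgboost thread count.
#' @param idw_exponent IDW distance exponent.
#' @param include_held_out_in_idw deliberately leaky IDW variant (training
#'   sources keep the held-out station); for leakage demonstrations only.
#' @return Object of class `loso_cv`: list with `folds` (per station:
#'   `held_out`, `predictions` tibble of `date`, `observed`, `predicted`,
#'   `idw_baseline`, and the tuned `hp`), pooled `predictions`, `target`,
#'   `seed`.
#' @export
loso_cv <- function(fixture, station_days, predictors,
                    target = c("mean", "max"), candidates, seed = 1,
                    nthread = 1, idw_exponent = 2,
                    include_held_out_in_idw = FALSE) {
  target <- match.arg(target)
  stations <- sort(unique(station_days$station_id))
  if (length(stations) < 3) stop("leave-one-station-out needs >= 3 stations")
  shell <- suppressMessages(
    training_features(fixture, station_days, predictors, target,
                      idw_exponent = idw_exponent))
  sources <- station_day_sources(fixture, station_days, target)

  folds <- lapply(seq_along(stations), function(k) {
    s <- stations[k]
    fd <- loso_fold(shell, sources, s, idw_exponent = idw_exponent,
                    include_held_out_in_idw = include_held_out_in_idw)
    if (length(unique(fd$train$station_id)) < 2) {
      stop("fewer than 2 training stations in fold ", s)
    }
    hp <- tune_hyperparameters(fd$train, candidates, seed = seed + k,
                               nthread = nthread,
                               idw_exponent = idw_exponent)
    model <- fit_exposure_model(fd$train, hp = hp, target_kind = target,
                                seed = seed + k, nthread = nthread)
    list(held_out = s,
         predictions = tibble::tibble(
           station_id = s, date = fd$test$date,
           observed = fd$test$observed,
           predicted = predict(model, fd$test),
           idw_baseline = fd$test$idw_baseline),
         hp = hp)
  })
  structure(list(folds = folds,
                 predictions = dplyr::bind_rows(
                   lapply(folds, `[[`, "predictions")),
                 target = target, seed = as.integer(seed)),
            class = "loso_cv")
}

#' @export
print.loso_cv <- function(x, ...) {
  m <- compute_metrics(x$predictions$observed, x$predictions$predicted)
  cat("<loso_cv> target ", x$target, ", ", length(x$folds), " folds, ",
      m$n_obs, " held-out station-days, MAE ", round(m$MAE, 2),
      " (MAD ", round(m$MAD, 2), ") ug/m3\n", sep = "")
  invisible(x)
}

#' Stratified cross-validation metrics
#'
#' Pools the held-out predictions of a [loso_cv()] run and reports
#' [compute_metrics()] rows overall and, optionally, per calendar year or
#' per season.  Seasonal strata pool across years.  Metrics within a
#' stratum use that stratum's own observations (within-stratum variance for
#' R^2).
#'
#' @param cv a `loso_cv` object (or its `predictions` tibble with a
#'   `station_id` column).
#' @param by `"overall"`, `"year"`, or `"season"`.
#' @return Tibble with columns `stratum`, `n_stations`, `n_obs`, `R2`,
#'   `SD`, `RMSE`, `MAD`, `MAE`.
#' @export
stratify_metrics <- function(cv, by = c("overall", "year", "season")) {
  by <- match.arg(by)
  preds <- if (inherits(cv, "loso_cv")) cv$predictions else cv
  stopifnot(nrow(preds) > 0)
  preds$stratum <- switch(by,
    overall = "overall",
    year = as.character(year_of(preds$date)),
    season = assign_season(preds$date))
  preds |>
    dplyr::group_by(.data$stratum) |>
    dplyr::reframe(n_stations = dplyr::n_distinct(.data$station_id),
                   compute_metrics(.data$observed, .data$predicted)) |>
    dplyr::relocate("stratum", "n_stations", "n_obs") |>
    dplyr::arrange(.data$stratum)
}
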