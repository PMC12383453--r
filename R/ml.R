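#' Hybrid time-series / stratified data split
#'
#' Rows are ordered by treatment date (ties by `arc_id`); the most recent
#' `test_frac` of rows form the test set, emulating prospective deployment.
#' The remaining oldest rows are split into training and validation sets by
#' stratified sampling on binned measured GPR, so both carry the same
#' outcome distribution. Validation rows are apportioned across bins by
#' largest remainder, which keeps every bin within one row of `val_frac`
#' and reproduces the overall validation size exactly.
#'
#' @param table data.frame with columns `arc_id`, `treatment_date`,
#'   `measured_gpr`.
#' @param test_frac fraction of rows in the (most recent) test set.
#' @param val_frac fraction of the remainder in the validation set.
#' @param n_bins number of GPR quantile bins for stratification; bins with
#'   fewer than 2 rows are merged with their neighbor.
#' @param seed integer seed for the within-bin sampling.
#' @return object of class `data_split`: list of integer row indices
#'   `train`, `validation`, `test` plus `meta`.
#' @export
hybrid_split <- function(table, test_frac = 0.2, val_frac = 0.2,
                         n_bins = 10, seed = 1) {
  if (is.null(table$treatment_date) || any(is.na(table$treatment_date)))
    stop("treatment dates are required for the time-series split")
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to split")
  round_half_up <- function(x) floor(x + 0.5)
  ord <- order(table$treatment_date, table$arc_id)
  n_test <- round_half_up(test_frac * n)
  test <- ord[seq.int(n - n_test + 1L, n)]
  rest <- ord[seq_len(n - n_test)]
  gpr <- table$measured_gpr[rest]
  if (any(is.na(gpr))) stop("measured GPR required for stratification")
  probs <- seq(0, 1, length.out = n_bins + 1)
  br <- unique(stats::quantile(gpr, probs, type = 7, names = FALSE))
  bins <- if (length(br) > 2)
    cut(gpr, br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(gpr))
  # merge undersized bins with the neighbor below (or above for the first)
  repeat {
    tab <- table(bins)
    small <- as.integer(names(tab))[tab < 2]
    if (!length(small) || length(tab) == 1) break
    b <- small[1]
    lv <- sort(unique(bins))
    target <- if (b == lv[1]) lv[2] else lv[max(which(lv < b))]
    bins[bins == b] <- target
  }
  m <- length(rest)
  n_val <- round_half_up(val_frac * m)
  lv <- sort(unique(bins))
  quota <- val_frac * as.numeric(table(factor(bins, levels = lv)))
  take <- floor(quota)
  extra <- n_val - sum(take)
  if (extra > 0) {
    o <- order(quota - take, decreasing = TRUE)
    take[o[seq_len(extra)]] <- take[o[seq_len(extra)]] + 1L
  } else if (extra < 0) {
    o <- order(quota - take)
    k <- 0L
    for (i in o) {
      if (k == -extra) break
      if (take[i] > 0) { take[i] <- take[i] - 1L; k <- k + 1L }
    }
  }
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  validation <- integer(0)
  for (i in seq_along(lv)) {
    members <- rest[bins == lv[i]]
    if (take[i] > 0)
      validation <- c(validation, sample(members, take[i]))
  }
  train <- setdiff(rest, validation)
  structure(list(train = sort(train), validation = sort(validation),
                 test = sort(test),
                 meta = list(test_frac = test_frac, val_frac = val_frac,
                             n_bins = n_bins, seed = seed, n = n)),
            class = "data_split")
}

#' Training sample weights emphasizing low GPR
#'
#' `w_i = 10^(k (a - GPR_i))` with GPR as a fraction of 1. The defaults
#' (`k = 1`, `a = 0.1`) give the literal published weighting
#' `w = 10^(0.1 - GPR)`; `k` tunes the effective strength.
#'
#' @param gpr numeric vector of GPR values as fractions in \[0, 1\].
#' @param k weighting strength.
#' @param a offset.
#' @return positive weights, strictly decreasing in GPR.
#' @export
sample_weights <- function(gpr, k = 1, a = 0.1) {
  if (any(gpr < 0 | gpr > 1)) stop("gpr must be a fraction in [0, 1]")
  10^(k * (a - gpr))
}

#' Robust percentile scaler
#'
#' `fit_scaler` records the 25th/50th/75th percentiles of each feature on
#' the fitting partition only; `apply_scaler` maps
#' `f -> (f - f50) / (f75 - f25)`. A zero-IQR feature scales to 0 with a
#' warning. Fitting per training fold (never on held-out rows) is what keeps
#' cross-validation leakage-free.
#'
#' @param rows data.frame of the fitting partition.
#' @param features character vector of feature columns.
#' @return `fit_scaler`: object of class `scaler_stats` (data.frame with
#'   `feature`, `q25`, `q50`, `q75`); `apply_scaler`: data.frame of scaled
#'   features.
#' @export
fit_scaler <- function(rows, features) {
  if (nrow(rows) < 4) stop("need at least 4 rows to fit the scaler")
  q <- vapply(features, function(f)
    stats::quantile(rows[[f]], c(0.25, 0.5, 0.75), type = 7, names = FALSE),
    numeric(3))
  structure(data.frame(feature = features, q25 = q[1, ], q50 = q[2, ],
                       q75 = q[3, ], stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("scaler_stats", "data.frame"))
}

#' @rdname fit_scaler
#' @param stats_ a `scaler_stats` object.
#' @export
apply_scaler <- function(stats_, rows) {
  out <- rows[, stats_$feature, drop = FALSE]
  for (i in seq_len(nrow(stats_))) {
    f <- stats_$feature[i]
    iqr <- stats_$q75[i] - stats_$q25[i]
    if (iqr <= 0) {
      warning("feature ", f, " has zero IQR on the fitting partition; ",
              "scaled values set to 0")
      out[[f]] <- rep(0, nrow(rows))
    } else {
      out[[f]] <- (rows[[f]] - stats_$q50[i]) / iqr
    }
  }
  out
}

#' Default randomized-search space for the forest
#'
#' @return a list describing the hyperparameter distributions: number of
#'   trees 100-1000, depth unbounded or 5-30, minimum samples per leaf 1-20,
#'   minimum samples to split 2-20, and feature subsampling sqrt, log2, or a
#'   fraction in 0.3-1.0.
#' @export
default_search_space <- function() {
  list(n_trees = c(100L, 1000L),
       max_depth = list("none", c(5L, 30L)),
       min_leaf = c(1L, 20L),
       min_split = c(2L, 20L),
       max_features = list("sqrt", "log2", c(0.3, 1.0)))
}

draw_params <- function(space) {
  rint <- function(r) if (r[1] == r[2]) as.integer(r[1]) else
    sample(seq.int(r[1], r[2]), 1)
  pick1 <- function(opts) opts[[if (length(opts) == 1) 1 else
    sample(length(opts), 1)]]
  depth_opt <- pick1(space$max_depth)
  md <- if (identical(depth_opt, "none")) 0L else rint(depth_opt)
  mf_opt <- pick1(space$max_features)
  mf <- if (is.character(mf_opt)) mf_opt
  else if (length(mf_opt) == 1 || mf_opt[1] == mf_opt[2]) mf_opt[1]
  else stats::runif(1, mf_opt[1], mf_opt[2])
  list(n_trees = rint(space$n_trees), max_depth = md,
       min_leaf = rint(space$min_leaf), min_split = rint(space$min_split),
       max_features = mf)
}

resolve_mtry <- function(max_features, p) {
  m <- if (identical(max_features, "sqrt")) sqrt(p)
  else if (identical(max_features, "log2")) log2(p)
  else as.numeric(max_features) * p
  max(1L, min(p, as.integer(ceiling(m))))
}

#' Randomized hyperparameter search with leakage-safe cross-validation
#'
#' Samples `n_iter` hyperparameter draws from `space` and scores each by
#' `k_folds`-fold cross-validated MAE on the training rows. Within every
#' fold the percentile scaler is fitted on that fold's training part only
#' and applied to its held-out part, and sample weights are computed from
#' the fold-training GPR, so no held-out information leaks into fitting.
#'
#' @param train data.frame of training rows with `measured_gpr` (%).
#' @param features feature columns to use.
#' @param n_iter number of random draws.
#' @param k_folds number of CV folds.
#' @param seed integer seed (fold assignment, draws, forest fits).
#' @param space search space, see [default_search_space()].
#' @param weight_k,weight_a arguments of [sample_weights()].
#' @return list with `best_params`, `cv_mae` (mean), `cv_mae_sd`, `draws`
#'   (data.frame of all draws), `fold_scalers` (per-fold `scaler_stats` of
#'   the best draw, exposed for the no-leakage audit), `seed`.
#' @export
randomized_search <- function(train, features, n_iter = 1000, k_folds = 5,
                              seed = 1, space = default_search_space(),
                              weight_k = 1, weight_a = 0.1) {
  if (nrow(train) < 50) stop("need at least 50 training rows")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  n <- nrow(train)
  fold <- sample(rep_len(seq_len(k_folds), n))
  y <- train$measured_gpr
  draws <- vector("list", n_iter)
  best <- NULL
  for (it in seq_len(n_iter)) {
    par <- draw_params(space)
    mtry <- resolve_mtry(par$max_features, length(features))
    maes <- numeric(k_folds)
    scalers <- vector("list", k_folds)
    for (kf in seq_len(k_folds)) {
      tr <- which(fold != kf); ho <- which(fold == kf)
      sc <- fit_scaler(train[tr, ], features)
      scalers[[kf]] <- sc
      xtr <- as.matrix(apply_scaler(sc, train[tr, ]))
      xho <- as.matrix(apply_scaler(sc, train[ho, ]))
      w <- sample_weights(y[tr] / 100, k = weight_k, a = weight_a)
      trees <- .rf_fit_cpp(xtr, y[tr], w, par$n_trees, mtry,
                           par$max_depth, par$min_split, par$min_leaf,
                           seed + it * 131L + kf, TRUE)
      pred <- pmin(100, pmax(0, .rf_predict_cpp(trees, xho)))
      maes[kf] <- mean(abs(pred - y[ho]))
    }
    rec <- data.frame(iter = it, n_trees = par$n_trees,
                      max_depth = par$max_depth, min_leaf = par$min_leaf,
                      min_split = par$min_split,
                      max_features = as.character(par$max_features),
                      cv_mae = mean(maes), cv_mae_sd = stats::sd(maes),
                      stringsAsFactors = FALSE)
    draws[[it]] <- rec
    if (is.null(best) || rec$cv_mae < best$cv_mae)
      best <- list(params = par, cv_mae = rec$cv_mae,
                   cv_mae_sd = rec$cv_mae_sd, fold_scalers = scalers)
  }
  list(best_params = best$params, cv_mae = best$cv_mae,
       cv_mae_sd = best$cv_mae_sd, draws = do.call(rbind, draws),
       fold_scalers = best$fold_scalers, seed = seed)
}

#' Train the final weighted forest on the full training set
#'
#' @param train data.frame of training rows with `measured_gpr` (%).
#' @param params hyperparameter list as returned in
#'   `randomized_search()$best_params`.
#' @param features feature columns.
#' @param seed integer seed for the forest.
#' @param weight_k,weight_a arguments of [sample_weights()].
#' @return object of class `model_bundle`: selected features, fitted
#'   `scaler_stats`, the forest, `params`, `seed`, and (once calibrated)
#'   the threshold limit `tl`.
#' @export
train_model <- function(train, params, features, seed = 1,
                        weight_k = 1, weight_a = 0.1) {
  sc <- fit_scaler(train, features)
  x <- as.matrix(apply_scaler(sc, train))
  y <- train$measured_gpr
  w <- sample_weights(y / 100, k = weight_k, a = weight_a)
  mtry <- resolve_mtry(params$max_features, length(features))
  trees <- .rf_fit_cpp(x, y, w, params$n_trees, mtry, params$max_depth,
                       params$min_split, params$min_leaf, seed, TRUE)
  structure(list(features = features, scaler = sc, trees = trees,
                 params = params, seed = seed, tl = NULL,
                 weight_k = weight_k, weight_a = weight_a),
            class = "model_bundle")
}

#' Predict GPR for new rows
#'
#' @param bundle a [train_model()] bundle.
#' @param rows data.frame containing the bundle's feature columns.
#' @return predicted GPR, percent, clipped to \[0, 100\].
#' @export
predict_gpr <- function(bundle, rows) {
  missing <- setdiff(bundle$features, names(rows))
  if (length(missing))
    stop("rows are missing feature column(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(apply_scaler(bundle$scaler, rows))
  pmin(100, pmax(0, .rf_predict_cpp(bundle$trees, x)))
}

#' Calibrate the pass/fail threshold limit on validation predictions
#'
#' An arc is flagged "fail" when its predicted GPR falls below the threshold
#' limit TL. Candidate thresholds are all midpoints between consecutive
#' distinct predictions (plus sentinels beyond both ends); among candidates
#' with sensitivity >= `sens_min` and specificity >= `spec_min`, the one
#' with maximum specificity is returned (ties resolved toward the lower TL).
#' If no candidate meets both constraints, the best-specificity candidate
#' among those meeting the sensitivity constraint is returned and flagged
#' infeasible.
#'
#' @param predicted predicted GPR on the validation set, percent.
#' @param measured measured GPR on the validation set, percent.
#' @param action_limit measured GPR below this is a true failure.
#' @param sens_min,spec_min operating constraints.
#' @return list with `tl` (%), `sensitivity`, `specificity`, `feasible`.
#' @export
calibrate_threshold <- function(predicted, measured, action_limit = 95,
                                sens_min = 0.90, spec_min = 0.50) {
  fail <- measured < action_limit
  if (!any(fail) || all(fail))
    stop("validation set must contain both pass and fail arcs")
  u <- sort(unique(predicted))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  stats_at <- function(tl) {
    flag <- predicted < tl
    c(sens = sum(flag & fail) / sum(fail),
      spec = sum(!flag & !fail) / sum(!fail))
  }
  s <- t(vapply(cand, stats_at, numeric(2)))
  ok_sens <- s[, "sens"] >= sens_min
  feasible <- ok_sens & s[, "spec"] >= spec_min
  pool <- if (any(feasible)) which(feasible) else which(ok_sens)
  if (!length(pool)) pool <- seq_along(cand)  # sens unattainable: take all
  best_spec <- max(s[pool, "spec"])
  at <- pool[s[pool, "spec"] == best_spec]
  i <- at[which.min(cand[at])]
  list(tl = cand[i], sensitivity = unname(s[i, "sens"]),
       specificity = unname(s[i, "spec"]), feasible = any(feasible))
}

#' Serialize / restore a model bundle as JSON
#'
#' The archive holds the selected features, scaler statistics, forest
#' (node tables), hyperparameters, weighting constants, and TL.
#'
#' @param bundle a `model_bundle`.
#' @param path file path.
#' @return `load_model_bundle` returns the restored `model_bundle`.
#' @export
save_model_bundle <- function(bundle, path) {
  payload <- list(version = 1L,
                  features = bundle$features,
                  scaler = bundle$scaler,
                  params = bundle$params,
                  seed = bundle$seed,
                  tl = bundle$tl,
                  weight_k = bundle$weight_k,
                  weight_a = bundle$weight_a,
                  trees = lapply(bundle$trees, function(m)
                    as.data.frame(m)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- p$scaler
  class(sc) <- c("scaler_stats", "data.frame")
  params <- p$params
  if (!is.null(params$max_features) && is.character(params$max_features) &&
      !params$max_features %in% c("sqrt", "log2"))
    params$max_features <- as.numeric(params$max_features)
  structure(list(features = p$features, scaler = sc,
                 trees = lapply(p$trees, as.matrix),
                 params = params, seed = p$seed, tl = p$tl,
                 weight_k = p$weight_k, weight_a = p$weight_a),
            class = "model_bundle")
}
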