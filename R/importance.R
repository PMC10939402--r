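# Resolve a model (ensemble or plain function) into a prediction closure.
as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "hardiness_ensemble"))
    return(function(x) stats::predict(model, x))
  stop_schema("model must be a hardiness_ensemble or a function(x) -> numeric")
}

#' Permutation feature importance
#'
#' Importance of a feature is the drop in model performance when its values
#' are randomly shuffled across rows: the mean, over `num_shuffle_sets`
#' shuffles, of `RMSE(shuffled) - RMSE(baseline)` on a row subsample.
#' Reported in RMSE units (degrees C); a feature the model never uses scores
#' exactly zero up to the shuffle noise, and a constant column scores
#' exactly zero identically.
#'
#' @param model A `hardiness_ensemble` or a `function(x) -> numeric`.
#' @param test A [hardiness_dataset()] to perturb.
#' @param num_shuffle_sets Number of independent shuffles per feature.
#' @param subsample_size Rows drawn (without replacement) for scoring;
#'   capped at the number of test rows.
#' @param features Optional subset of feature names to score (default all).
#' @param seed Integer seed for the subsample and the shuffles.
#' @return Data frame with one row per feature: `feature`, `importance`
#'   (mean RMSE increase, degrees C), `sd` (across shuffles), sorted by
#'   decreasing importance.
#' @export
permutation_importance <- function(model, test, num_shuffle_sets = 100L,
                                   subsample_size = 1000L, features = NULL,
                                   seed = 1L) {
  predict_fun <- as_predict_fun(model)
  stopifnot(inherits(test, "hardiness_dataset"))
  if (subsample_size < 2L) stop_validation("subsample_size must be >= 2")
  if (nrow(test$features) < 2L) stop_validation("need at least 2 test rows")
  features <- features %||% colnames(test$features)
  bad <- setdiff(features, colnames(test$features))
  if (length(bad)) stop_schema("unknown feature(s): %s", paste(bad, collapse = ", "))

  n <- nrow(test$features)
  take <- min(subsample_size, n)
  rows <- withr::with_seed(derive_seed(seed, "subsample"),
                           sort(sample.int(n, take)))
  x <- test$features[rows, , drop = FALSE]
  y <- test$lt50[rows]
  base_rmse <- rmse(predict_fun(x), y)

  perms <- withr::with_seed(derive_seed(seed, "shuffles"),
                            replicate(num_shuffle_sets, sample.int(take),
                                      simplify = FALSE))
  res <- lapply(features, function(f) {
    drops <- vapply(perms, function(p) {
      xp <- x
      xp[, f] <- x[p, f]
      rmse(predict_fun(xp), y) - base_rmse
    }, numeric(1))
    c(importance = mean(drops), sd = stats::sd(drops))
  })
  out <- data.frame(feature = features,
                    importance = vapply(res, `[[`, numeric(1), "importance"),
                    sd = vapply(res, `[[`, numeric(1), "sd"))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_rmse") <- base_rmse
  attr(out, "n_rows") <- take
  out
}

#' Monte-Carlo Shapley values
#'
#' Estimates per-sample, per-feature Shapley values by sampling feature
#' permutations with an interventional (background-marginal) value
#' function: walking each permutation, features switch one by one from
#' background values to the instance's values, and a feature's contribution
#' is the mean change in prediction over the background rows. The telescoping
#' sum makes local accuracy exact for every sampled permutation:
#' `base_value + sum(shapley values) = prediction` for each instance.
#'
#' @param model A `hardiness_ensemble` or a `function(x) -> numeric`.
#' @param instances Feature matrix of samples to explain.
#' @param background Feature matrix of reference rows (e.g. up to 100
#'   training rows); the expectation baseline.
#' @param n_permutations Sampled feature permutations per instance.
#' @param seed Integer seed.
#' @return A `shapley_result` list: `values` (instances x features matrix,
#'   degrees C), `base_value` (mean background prediction), `predictions`.
#' @export
shapley_values <- function(model, instances, background,
                           n_permutations = 20L, seed = 1L) {
  predict_fun <- as_predict_fun(model)
  instances <- as.matrix(instances)
  background <- as.matrix(background)
  if (nrow(background) < 1L) stop_validation("background must be non-empty")
  if (n_permutations < 1L) stop_validation("n_permutations must be >= 1")
  if (!identical(colnames(instances), colnames(background)))
    stop_schema("instances and background must share identical columns")
  p <- ncol(instances)
  m <- nrow(background)
  base_preds <- predict_fun(background)
  base_value <- mean(base_preds)

  perms <- withr::with_seed(derive_seed(seed, "shap"),
                            replicate(n_permutations, sample.int(p),
                                      simplify = FALSE))
  values <- matrix(0, nrow = nrow(instances), ncol = p,
                   dimnames = list(NULL, colnames(instances)))
  for (i in seq_len(nrow(instances))) {
    phi <- numeric(p)
    for (perm in perms) {
      z <- background
      prev <- base_preds
      for (j in perm) {
        z[, j] <- instances[i, j]
        cur <- predict_fun(z)
        phi[j] <- phi[j] + mean(cur - prev)
        prev <- cur
      }
    }
    values[i, ] <- phi / n_permutations
  }
  structure(list(values = values, base_value = base_value,
                 predictions = as.numeric(predict_fun(instances))),
            class = "shapley_result")
}

#' Rank features by mean absolute Shapley value
#'
#' @param shapley A `shapley_result` (or a plain instances x features
#'   matrix of Shapley values).
#' @return Data frame `feature`, `mean_abs_shap` sorted descending; ties
#'   keep the input column order (stable).
#' @export
rank_features <- function(shapley) {
  values <- if (inherits(shapley, "shapley_result")) shapley$values else as.matrix(shapley)
  score <- colMeans(abs(values))
  ord <- order(-score)  # stable: ties keep column order
  data.frame(feature = colnames(values)[ord],
             mean_abs_shap = as.numeric(score[ord]),
             row.names = NULL)
}
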