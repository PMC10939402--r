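#' Construct a labelled hardiness dataset
#'
#' Bundles a feature matrix with observed bud LT50 labels and per-row
#' metadata (date, site, cultivar, ...).
#'
#' @param features Numeric matrix (rows = samples) with column names.
#' @param lt50 Numeric vector of observed LT50 (degrees C, typically <= 0).
#' @param meta Optional data frame of per-row metadata.
#' @return A `hardiness_dataset` list with elements `features`, `lt50`,
#'   `meta`.
#' @export
hardiness_dataset <- function(features, lt50, meta = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    stop_schema("feature matrix must have column names")
  if (length(lt50) != nrow(features))
    stop_schema("labels (%d) and feature rows (%d) differ",
                length(lt50), nrow(features))
  if (anyNA(lt50) || any(!is.finite(lt50)))
    stop_validation("missing or non-finite LT50 labels")
  if (is.null(meta)) meta <- data.frame(row = seq_len(nrow(features)))
  if (nrow(meta) != nrow(features))
    stop_schema("metadata rows (%d) and feature rows (%d) differ",
                nrow(meta), nrow(features))
  structure(list(features = features, lt50 = as.numeric(lt50), meta = meta),
            class = "hardiness_dataset")
}

#' @export
print.hardiness_dataset <- function(x, ...) {
  cat(sprintf("<hardiness_dataset> %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

subset_dataset <- function(data, idx) {
  hardiness_dataset(data$features[idx, , drop = FALSE],
                    data$lt50[idx],
                    data$meta[idx, , drop = FALSE])
}

#' Randomized train/test split
#'
#' Shuffles rows with a seeded uniform permutation (no stratification) and
#' holds out `round(K * test_fraction)` rows for internal testing.
#'
#' @param data A [hardiness_dataset()].
#' @param test_fraction Held-out proportion, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with `train` and `test` datasets (disjoint row partition).
#' @export
#' @examples
#' \dontrun{
#' parts <- split_train_test(data, test_fraction = 0.1, seed = 1)
#' }
split_train_test <- function(data, test_fraction = 0.1, seed = 1) {
  stopifnot(inherits(data, "hardiness_dataset"))
  if (!is_scalar_number(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop_validation("test_fraction must be in (0, 1)")
  k <- nrow(data$features)
  if (k < 10L) stop_validation("need at least 10 rows to split (have %d)", k)
  n_test <- round(k * test_fraction)
  if (n_test < 1L || n_test >= k)
    stop_validation("degenerate split: %d test rows out of %d", n_test, k)
  perm <- withr::with_seed(derive_seed(seed, "split"), sample.int(k))
  list(train = subset_dataset(data, sort(perm[-seq_len(n_test)])),
       test = subset_dataset(data, sort(perm[seq_len(n_test)])))
}

# --- base learners ----------------------------------------------------------

#' Define a base learner
#'
#' @param name Short identifier.
#' @param fit `function(x, y, seed)` returning a fitted model.
#' @param predict `function(model, x)` returning numeric predictions.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "learner_spec")
}

#' Default base-learner menu
#'
#' A small fixed zoo of standard tabular regressors: gradient-boosted trees
#' (xgboost), random forest (ranger), ridge regression (glmnet) and
#' k-nearest neighbours (caret). All run single-threaded and take their
#' randomness from the seed passed by the trainer.
#'
#' @return Named list of [learner_spec()] objects.
#' @export
default_learners <- function() {
  list(
    gbt = learner_spec(
      "gbt",
      fit = function(x, y, seed) {
        xgboost::xgboost(x = x, y = y, nrounds = 200, max_depth = 6,
                         learning_rate = 0.1, subsample = 0.9,
                         colsample_bytree = 0.8, nthreads = 1,
                         verbosity = 0, seed = seed)
      },
      predict = function(model, x) as.numeric(stats::predict(model, x))
    ),
    rf = learner_spec(
      "rf",
      fit = function(x, y, seed) {
        ranger::ranger(x = x, y = y, num.trees = 300, num.threads = 1,
                       seed = seed)
      },
      predict = function(model, x) {
        as.numeric(stats::predict(model, data = x,
                                  num.threads = 1)$predictions)
      }
    ),
    ridge = learner_spec(
      "ridge",
      fit = function(x, y, seed) {
        withr::with_seed(seed,
          glmnet::cv.glmnet(x, y, alpha = 0, nfolds = 5))
      },
      predict = function(model, x) {
        as.numeric(stats::predict(model, x, s = "lambda.min"))
      }
    ),
    knn = learner_spec(
      "knn",
      fit = function(x, y, seed) {
        caret::knnreg(x, y, k = min(10L, max(1L, nrow(x) - 1L)))
      },
      predict = function(model, x) as.numeric(stats::predict(model, x))
    )
  )
}

# Fit one learner, falling back to a constant model on degenerate labels.
fit_learner <- function(spec, x, y, seed) {
  if (stats::sd(y) < 1e-10) {
    return(structure(list(value = mean(y)), class = "constant_model"))
  }
  spec$fit(x, y, seed)
}

predict_learner <- function(spec, model, x) {
  if (inherits(model, "constant_model")) return(rep(model$value, nrow(x)))
  p <- spec$predict(model, x)
  if (length(p) != nrow(x) || any(!is.finite(p)))
    stop_compute("learner '%s' returned invalid predictions", spec$name)
  p
}

# --- greedy weighted ensembling --------------------------------------------

# Forward selection with replacement over member out-of-fold predictions,
# initialized at the single best member (so the ensemble never validates
# worse than its best member). Weights are selection frequencies.
greedy_weighted_ensemble <- function(pred, y, max_iter = 50L) {
  m <- ncol(pred)
  member_rmse <- apply(pred, 2, rmse, observed = y)
  sel <- integer(max_iter)
  sel[1] <- which.min(member_rmse)
  running <- pred[, sel[1]]
  traj <- numeric(max_iter)
  traj[1] <- member_rmse[sel[1]]
  for (i in seq_len(max_iter)[-1]) {
    cand <- vapply(seq_len(m), function(j)
      rmse((running * (i - 1) + pred[, j]) / i, y), numeric(1))
    sel[i] <- which.min(cand)
    running <- (running * (i - 1) + pred[, sel[i]]) / i
    traj[i] <- cand[sel[i]]
  }
  best_len <- which.min(traj)
  counts <- tabulate(sel[seq_len(best_len)], nbins = m)
  weights <- counts / best_len
  names(weights) <- colnames(pred)
  list(weights = weights, rmse = traj[best_len],
       member_rmse = stats::setNames(member_rmse, colnames(pred)))
}

# --- training ---------------------------------------------------------------

#' Train a bagged, stacked, weighted-ensemble LT50 regressor
#'
#' Level-1 base learners are trained with k-fold bagging: each learner is
#' fitted on k-1 folds and predicts the held-out fold, yielding leak-free
#' out-of-fold (OOF) predictions that double as validation scores and as
#' stack features. Learners at level l > 1 see the original features plus
#' the level l-1 OOF predictions. Every level closes with a greedy weighted
#' ensemble over its members (nonnegative weights summing to one), and the
#' final model is chosen by [select_model()]: the least complex (lowest)
#' stack level whose validation RMSE is within `tolerance` of the global
#' best.
#'
#' @param data Training [hardiness_dataset()].
#' @param num_bag_folds Bagging folds per learner (>= 2; default 10).
#' @param num_stack_levels Number of stack levels (default 5).
#' @param learners Named list of [learner_spec()]s (>= 2).
#' @param tolerance Degrees C slack for least-complexity selection.
#' @param seed Integer master seed; all folds and learner seeds derive from
#'   it, so a fixed seed reproduces the model exactly.
#' @param ensemble_iter Greedy-selection iterations per level.
#' @return A `hardiness_ensemble` with one record per stack level (members,
#'   OOF predictions, validation RMSEs, ensemble weights) and a `selected`
#'   pointer.
#' @export
train_ensemble <- function(data, num_bag_folds = 10L, num_stack_levels = 5L,
                           learners = default_learners(), tolerance = 0.01,
                           seed = 1L, ensemble_iter = 50L) {
  stopifnot(inherits(data, "hardiness_dataset"))
  if (num_bag_folds < 2L) stop_validation("num_bag_folds must be >= 2")
  if (num_stack_levels < 1L) stop_validation("num_stack_levels must be >= 1")
  if (length(learners) < 2L) stop_validation("need at least 2 base learners")
  x <- data$features
  y <- data$lt50
  if (any(!is.finite(x))) stop_validation("non-finite feature values")
  k <- nrow(x)
  if (k < 2L * num_bag_folds)
    stop_validation("a bag fold would hold fewer than 2 rows (%d rows, %d folds)",
                    k, num_bag_folds)
  fold_id <- withr::with_seed(derive_seed(seed, "folds"),
                              sample(rep(seq_len(num_bag_folds),
                                         length.out = k)))

  levels <- vector("list", num_stack_levels)
  x_lvl <- x
  for (lvl in seq_len(num_stack_levels)) {
    oof <- matrix(NA_real_, nrow = k, ncol = length(learners),
                  dimnames = list(NULL, names(learners)))
    members <- list()
    for (ln in names(learners)) {
      spec <- learners[[ln]]
      models <- vector("list", num_bag_folds)
      for (f in seq_len(num_bag_folds)) {
        in_fold <- fold_id == f
        fit_seed <- derive_seed(seed, "fit", lvl, ln, f)
        models[[f]] <- fit_learner(spec, x_lvl[!in_fold, , drop = FALSE],
                                   y[!in_fold], fit_seed)
        oof[in_fold, ln] <- predict_learner(spec, models[[f]],
                                            x_lvl[in_fold, , drop = FALSE])
      }
      members[[ln]] <- list(name = ln, models = models,
                            rmse = rmse(oof[, ln], y))
    }
    ens <- greedy_weighted_ensemble(oof, y, max_iter = ensemble_iter)
    levels[[lvl]] <- list(members = members, oof = oof, ensemble = ens,
                          feature_names = colnames(x_lvl))
    if (lvl < num_stack_levels) {
      stack <- oof
      colnames(stack) <- paste0("stack_", colnames(oof), "_L", lvl)
      x_lvl <- cbind(x, stack)
    }
  }

  obj <- structure(list(
    levels = levels,
    feature_names = colnames(x),
    learner_specs = learners,
    num_bag_folds = num_bag_folds,
    num_stack_levels = num_stack_levels,
    tolerance = tolerance,
    seed = seed,
    feature_hash = attr(data$features, "config_hash")
  ), class = "hardiness_ensemble")
  obj$selected <- select_model(obj, tolerance)
  obj
}

#' Least-complexity model selection
#'
#' Among the per-level weighted ensembles whose validation RMSE is within
#' `tolerance` of the global best, returns the one at the lowest stack
#' level; ties at a level are broken toward fewer ensemble members.
#'
#' @param ensemble A `hardiness_ensemble`.
#' @param tolerance Degrees C slack around the best validation RMSE.
#' @return List with `level`, `name`, `rmse`, `n_members`.
#' @export
select_model <- function(ensemble, tolerance = 0.01) {
  stopifnot(inherits(ensemble, "hardiness_ensemble"))
  if (!length(ensemble$levels)) stop_validation("ensemble has no stack levels")
  rmses <- vapply(ensemble$levels, function(l) l$ensemble$rmse, numeric(1))
  n_members <- vapply(ensemble$levels,
                      function(l) sum(l$ensemble$weights > 0), numeric(1))
  eligible <- which(rmses <= min(rmses) + tolerance)
  lvl <- eligible[order(eligible, n_members[eligible])][1]
  list(level = lvl, name = paste0("weighted_ensemble_L", lvl),
       rmse = rmses[lvl], n_members = n_members[lvl])
}

#' @export
print.hardiness_ensemble <- function(x, ...) {
  cat(sprintf("<hardiness_ensemble> %d stack level(s), %d-fold bagging\n",
              length(x$levels), x$num_bag_folds))
  for (i in seq_along(x$levels)) {
    l <- x$levels[[i]]
    cat(sprintf("  L%d: members [%s]; ensemble OOF RMSE %.3f C\n", i,
                paste(sprintf("%s %.3f", names(l$members),
                              vapply(l$members, `[[`, numeric(1), "rmse")),
                      collapse = ", "),
                l$ensemble$rmse))
  }
  cat(sprintf("  selected: %s (RMSE %.3f C)\n",
              x$selected$name, x$selected$rmse))
  invisible(x)
}

#' Predict LT50 for new samples
#'
#' Pushes a feature matrix through the stacked ensemble: each level's base
#' learners predict as the average of their bag-fold fits, lower-level
#' predictions are appended as stack features, and the target level's
#' weighted ensemble combines its members.
#'
#' @param object A `hardiness_ensemble`.
#' @param newdata Feature matrix (or [hardiness_dataset()]) whose columns
#'   match the training features.
#' @param level Stack level to predict from; defaults to the selected model.
#' @param ... Unused.
#' @return Numeric vector of predicted LT50 (degrees C).
#' @export
predict.hardiness_ensemble <- function(object, newdata, level = NULL, ...) {
  if (inherits(newdata, "hardiness_dataset")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  extra_cols <- setdiff(colnames(newdata), object$feature_names)
  if (length(missing_cols) || length(extra_cols))
    stop_schema("feature columns do not match training config; missing: [%s]; extra: [%s]",
                paste(missing_cols, collapse = ", "),
                paste(extra_cols, collapse = ", "))
  x <- newdata[, object$feature_names, drop = FALSE]
  target <- level %||% object$selected$level
  if (target < 1L || target > length(object$levels))
    stop_validation("no stack level %s in this ensemble", target)

  x_lvl <- x
  for (lvl in seq_len(target)) {
    rec <- object$levels[[lvl]]
    base <- matrix(NA_real_, nrow = nrow(x), ncol = length(rec$members),
                   dimnames = list(NULL, names(rec$members)))
    for (ln in names(rec$members)) {
      spec <- object$learner_specs[[ln]]
      fold_preds <- vapply(rec$members[[ln]]$models, function(m)
        predict_learner(spec, m, x_lvl), numeric(nrow(x)))
      base[, ln] <- if (nrow(x) == 1L) mean(fold_preds) else rowMeans(fold_preds)
    }
    if (lvl == target) {
      w <- object$levels[[lvl]]$ensemble$weights
      return(as.numeric(base %*% w))
    }
    colnames(base) <- paste0("stack_", colnames(base), "_L", lvl)
    x_lvl <- cbind(x, base)
  }
}

#' Root-mean-square error
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`, degrees C.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_schema("predicted (%d) and observed (%d) lengths differ",
                length(predicted), length(observed))
  sqrt(mean((predicted - observed)^2))
}

#' Evaluate a trained model on a test set
#'
#' Computes overall and per-group RMSE plus signed per-row prediction
#' errors, `predicted - observed`: negative errors mean the model predicted
#' the buds hardier (more negative LT50) than observed.
#'
#' @param model A `hardiness_ensemble` (or any object with a `predict`
#'   method over feature matrices).
#' @param test A [hardiness_dataset()].
#' @param group_keys Metadata columns to stratify RMSE by (e.g. `"site"`,
#'   `"cultivar"`).
#' @param level Optional stack level override.
#' @return An `eval_report` list: `overall_rmse`, `by_group` (named list of
#'   data frames with n and RMSE per group), `predictions`, `errors`.
#' @export
evaluate_model <- function(model, test, group_keys = NULL, level = NULL) {
  stopifnot(inherits(test, "hardiness_dataset"))
  pred <- if (inherits(model, "hardiness_ensemble"))
    stats::predict(model, test, level = level)
  else as_predict_fun(model)(test$features)
  errors <- pred - test$lt50
  by_group <- list()
  for (key in group_keys) {
    if (!key %in% names(test$meta))
      stop_schema("group key '%s' not in test metadata", key)
    g <- as.character(test$meta[[key]])
    by_group[[key]] <- do.call(rbind, lapply(split(seq_along(g), g), function(ix)
      data.frame(group = g[ix[1]], n = length(ix),
                 rmse = rmse(pred[ix], test$lt50[ix]))))
    rownames(by_group[[key]]) <- NULL
  }
  structure(list(overall_rmse = rmse(pred, test$lt50), by_group = by_group,
                 predictions = pred, errors = errors),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall RMSE %.3f C over %d rows\n",
              x$overall_rmse, length(x$errors)))
  for (key in names(x$by_group)) {
    cat(" by", key, ":\n")
    print(x$by_group[[key]], row.names = FALSE)
  }
  invisible(x)
}

# --- persistence ------------------------------------------------------------

#' Save / load a trained ensemble
#'
#' The artifact is a directory holding the serialized model plus a JSON
#' manifest (seed, bagging/stacking configuration, per-level member names,
#' weights and validation RMSEs, selected model) for provenance.
#'
#' @param ensemble A `hardiness_ensemble`.
#' @param dir Artifact directory (created if needed).
#' @return `save_ensemble` returns `dir` invisibly; `load_ensemble` returns
#'   the restored `hardiness_ensemble`.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "hardiness_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  manifest <- list(
    package = "hardivine",
    seed = ensemble$seed,
    num_bag_folds = ensemble$num_bag_folds,
    num_stack_levels = ensemble$num_stack_levels,
    feature_hash = ensemble$feature_hash,
    n_features = length(ensemble$feature_names),
    levels = lapply(seq_along(ensemble$levels), function(i) {
      l <- ensemble$levels[[i]]
      list(level = i,
           members = names(l$members),
           member_rmse = vapply(l$members, `[[`, numeric(1), "rmse"),
           weights = as.list(l$ensemble$weights),
           ensemble_rmse = l$ensemble$rmse)
    }),
    selected = ensemble$selected
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  path <- file.path(dir, "ensemble.rds")
  if (!file.exists(path)) stop_schema("no ensemble artifact at '%s'", dir)
  readRDS(path)
}
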