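test_that("90/10 split arithmetic matches the study sample sizes", {
  make_k <- function(k) hardiness_dataset(
    matrix(seq_len(k), ncol = 1, dimnames = list(NULL, "f1")), rep(-10, k))
  p1 <- split_train_test(make_k(10157), 0.10, seed = 4)
  expect_equal(nrow(p1$test$features), 1016L)
  expect_equal(nrow(p1$train$features), 9141L)
  p2 <- split_train_test(make_k(9698), 0.10, seed = 4)
  expect_equal(nrow(p2$test$features), 970L)
  expect_equal(nrow(p2$train$features), 8728L)

  # disjoint partition, deterministic under a fixed seed
  ids <- c(p1$train$features[, 1], p1$test$features[, 1])
  expect_setequal(ids, seq_len(10157))
  p1b <- split_train_test(make_k(10157), 0.10, seed = 4)
  expect_identical(p1$test$features, p1b$test$features)
  p1c <- split_train_test(make_k(10157), 0.10, seed = 5)
  expect_false(identical(p1$test$features, p1c$test$features))

  expect_error(split_train_test(make_k(5), 0.1), class = "hardivine_validation_error")
})

test_that("rmse follows its definition", {
  expect_equal(rmse(c(-10, -12), c(-10, -12)), 0)
  expect_equal(rmse(-10, -12), 2)
  expect_equal(rmse(c(-10, -10), c(-11, -13)), sqrt(5))
  expect_error(rmse(1:3, 1:2), class = "hardivine_schema_error")
})

test_that("training recovers a noiseless linear signal", {
  data <- linear_dataset(n = 150, noise_sd = 0, seed = 2)
  m <- train_ensemble(data, num_bag_folds = 4, num_stack_levels = 1,
                      learners = fast_learners(), seed = 3)
  expect_length(m$levels, 1L)
  expect_lt(m$selected$rmse, stats::sd(data$lt50) / 10)
})

test_that("weighted ensemble never validates worse than its best member", {
  b <- small_benchmark()
  m <- train_ensemble(b$data, num_bag_folds = 3, num_stack_levels = 2,
                      learners = fast_learners(), seed = 6)
  for (lvl in m$levels) {
    member_best <- min(vapply(lvl$members, `[[`, numeric(1), "rmse"))
    expect_lte(lvl$ensemble$rmse, member_best + 1e-12)
    w <- lvl$ensemble$weights
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1)
  }
})

test_that("least-complexity selection picks the lowest near-optimal level", {
  stub <- function(rmses) {
    lvls <- lapply(rmses, function(r) {
      list(ensemble = list(rmse = r, weights = c(0.5, 0.5, 0)))
    })
    structure(list(levels = lvls), class = "hardiness_ensemble")
  }
  sel <- select_model(stub(c(1.40, 1.35, 1.35, 1.35)), tolerance = 0.005)
  expect_equal(sel$level, 2L)
  expect_equal(sel$name, "weighted_ensemble_L2")
  expect_equal(select_model(stub(1.2))$level, 1L)
  expect_equal(select_model(stub(c(1.31, 1.30, 1.33)), tolerance = 0)$level, 2L)
  expect_error(select_model(structure(list(levels = list()),
                                      class = "hardiness_ensemble")),
               class = "hardivine_validation_error")
})

test_that("prediction is deterministic, order-equivariant and column-checked", {
  data <- linear_dataset(n = 100, noise_sd = 0.2, seed = 9)
  m <- train_ensemble(data, num_bag_folds = 3, num_stack_levels = 1,
                      learners = fast_learners(), seed = 1)
  p <- predict(m, data$features)
  expect_length(p, 100L)
  expect_true(all(is.finite(p)))
  perm <- sample(100)
  expect_equal(predict(m, data$features[perm, ]), p[perm])

  bad <- data$features[, 1:3]
  expect_error(predict(m, bad), "f4", class = "hardivine_schema_error")
  extra <- cbind(data$features, zz = 1)
  expect_error(predict(m, extra), "zz", class = "hardivine_schema_error")
})

test_that("a model trained on constant labels predicts that constant", {
  x <- matrix(rnorm(200), 50, dimnames = list(NULL, paste0("f", 1:4)))
  data <- hardiness_dataset(x, rep(-15, 50))
  m <- train_ensemble(data, num_bag_folds = 3, num_stack_levels = 1,
                      learners = fast_learners(), seed = 2)
  expect_equal(predict(m, x), rep(-15, 50), tolerance = 1e-8)
})

test_that("stack features respect out-of-fold discipline (no leakage)", {
  data <- linear_dataset(n = 120, noise_sd = 0.5, seed = 12)
  seed <- 21
  k <- 4L
  m1 <- train_ensemble(data, num_bag_folds = k, num_stack_levels = 1,
                       learners = fast_learners(), seed = seed)
  # recreate the trainer's fold assignment and perturb labels inside fold 1
  fold_id <- withr::with_seed(hardivine:::derive_seed(seed, "folds"),
                              sample(rep(seq_len(k), length.out = 120)))
  y2 <- data$lt50
  in_f1 <- which(fold_id == 1L)
  y2[in_f1] <- y2[rev(in_f1)]
  data2 <- hardiness_dataset(data$features, y2, data$meta)
  m2 <- train_ensemble(data2, num_bag_folds = k, num_stack_levels = 1,
                       learners = fast_learners(), seed = seed)
  # fold-1 rows' out-of-fold predictions come from models fitted on the
  # untouched folds, so they must be unchanged
  expect_equal(m1$levels[[1]]$oof[in_f1, ], m2$levels[[1]]$oof[in_f1, ])
  # while other folds' predictions do change (their training data changed)
  expect_false(isTRUE(all.equal(m1$levels[[1]]$oof[-in_f1, ],
                                m2$levels[[1]]$oof[-in_f1, ])))
})

test_that("training is reproducible from a single seed", {
  data <- linear_dataset(n = 100, noise_sd = 0.3, seed = 4)
  m1 <- train_ensemble(data, num_bag_folds = 3, num_stack_levels = 2,
                       learners = fast_learners(), seed = 11)
  m2 <- train_ensemble(data, num_bag_folds = 3, num_stack_levels = 2,
                       learners = fast_learners(), seed = 11)
  expect_identical(m1$selected, m2$selected)
  expect_equal(predict(m1, data$features), predict(m2, data$features))
})

test_that("evaluation reports signed errors and group-decomposable RMSE", {
  data <- linear_dataset(n = 80, noise_sd = 0.5, seed = 7)
  identity_model <- function(x) data$lt50  # perfect predictions
  ev <- evaluate_model(identity_model, data, group_keys = "site")
  expect_equal(ev$overall_rmse, 0)
  expect_equal(ev$errors, rep(0, 80))

  shifted <- function(x) as.numeric(x %*% c(2, -1, 0.5, 0, 0))
  ev2 <- evaluate_model(shifted, data, group_keys = "site")
  expect_equal(ev2$errors, shifted(data$features) - data$lt50)
  # overall MSE is the weighted mean of group MSEs
  g <- ev2$by_group$site
  expect_equal(ev2$overall_rmse^2,
               sum(g$n * g$rmse^2) / sum(g$n))
  # single-row test: |error| equals RMSE
  one <- hardivine:::subset_dataset(data, 1)
  ev3 <- evaluate_model(shifted, one)
  expect_equal(abs(ev3$errors), ev3$overall_rmse, ignore_attr = TRUE)

  expect_error(evaluate_model(shifted, data, group_keys = "region"),
               class = "hardivine_schema_error")
})

test_that("ensemble artifacts round-trip through save/load with a manifest", {
  data <- linear_dataset(n = 60, noise_sd = 0.2, seed = 5)
  m <- train_ensemble(data, num_bag_folds = 3, num_stack_levels = 1,
                      learners = fast_learners(), seed = 8)
  dir <- withr::local_tempdir()
  save_ensemble(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$selected$name, m$selected$name)
  m2 <- load_ensemble(dir)
  expect_equal(predict(m2, data$features), predict(m, data$features))
})
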