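# Shapley axioms, the exact enumerator, and the tree-path explainer.

test_that("exact Shapley honours dummy, efficiency and symmetry axioms", {
  set.seed(2)
  bg <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  # dummy: f ignores feature d entirely
  f <- function(M) M[, 1] + 2 * M[, 2] * M[, 3]
  x <- c(a = 1, b = 0.5, c = -1, d = 3)
  ex <- exact_shapley(f, x, bg)
  expect_equal(unname(ex$phi["d"]), 0)
  expect_equal(ex$base_value + sum(ex$phi), ex$prediction, tolerance = 1e-12)
  # symmetry: interchangeable features (same role in the model, same
  # background marginal, same explained value) get equal phi
  fs <- function(M) 3 * M[, 1] + 3 * M[, 2] + M[, 4]
  bgs <- bg; bgs[, 2] <- bgs[, 1]
  xs <- c(a = 0.7, b = 0.7, c = 0, d = -1)
  exs <- exact_shapley(fs, xs, bgs)
  expect_equal(unname(exs$phi["a"]), unname(exs$phi["b"]), tolerance = 1e-10)
  # enumeration bound
  expect_error(exact_shapley(f, rnorm(25), matrix(rnorm(50), 2)), "bound")
})

test_that("exact Shapley matches the linear-model closed form", {
  set.seed(3)
  M <- 6
  w <- rnorm(M)
  bg <- matrix(rnorm(50 * M), 50, M)
  f <- function(X) as.numeric(X %*% w)
  x <- rnorm(M)
  ex <- exact_shapley(f, x, bg)
  expect_equal(unname(ex$phi), w * (x - colMeans(bg)), tolerance = 1e-10)
})

test_that("tree-path attribution equals exact enumeration on toy ensembles", {
  worst <- 0
  for (seed in 1:3) {
    tm <- toy_tree_model(n_features = 7, n_rows = 150, n_background = 32,
                         seed = seed)
    sm <- tree_shap_matrix(tm$booster, tm$X[1:3, , drop = FALSE],
                          tm$background, scale = "margin")
    for (i in 1:3) {
      ex <- exact_shapley(tm$predict_fun, tm$X[i, ], tm$background)
      worst <- max(worst, max(abs(ex$phi - sm$phi[i, ])))
      expect_equal(sm$base_value + sum(sm$phi[i, ]), sm$predictions[i],
                   tolerance = 1e-6)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("a stump attributes only to its split feature", {
  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X[, 2] > 0)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = 1, eta = 1,
                  nthread = 1L),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
    nrounds = 1, verbose = 0)
  sm <- tree_shap_matrix(booster, X[1:5, ], X[6:60, ], scale = "margin")
  expect_equal(unname(sm$phi[, "a"]), rep(0, 5))
  expect_equal(unname(sm$phi[, "c"]), rep(0, 5))
  expect_false(all(sm$phi[, "b"] == 0))
})

test_that("probability-scale attributions stay additive and pipeline-ready", {
  tab <- make_separable_table(n = 150)
  fit <- train_model(tab, model_spec("gradient_boosting",
                                     list(nrounds = 25, max_depth = 3)),
                     seed = 2)
  sm <- tree_shap_matrix(fit, fit$X, scale = "probability", seed = 4)
  expect_equal(unname(sm$base_value + rowSums(sm$phi)),
               unname(sm$predictions), tolerance = 1e-10)
  expect_true(all(sm$predictions >= 0 & sm$predictions <= 1))
  # rejects non-tree learners
  lr <- train_model(tab, model_spec("logistic_regression"), seed = 2)
  expect_error(tree_shap_matrix(lr, lr$X), "tree ensemble")
})

test_that("global importance is the mean |phi| in stable descending order", {
  phi <- rbind(c(0.2, 0, 0.1), c(-0.4, 0, -0.1))
  colnames(phi) <- c("A", "zero", "B")
  sm <- structure(list(phi = phi, base_value = 0, predictions = c(0, 0),
                       X = phi * 0, feature_names = colnames(phi),
                       scale = "margin"), class = "shap_matrix")
  gi <- global_importance(sm)
  expect_equal(gi$feature, c("A", "B", "zero"))
  expect_equal(gi$importance, c(0.3, 0.1, 0))
  # row order invariance
  sm2 <- sm; sm2$phi <- phi[2:1, ]
  expect_equal(global_importance(sm2), gi)
})

test_that("summary data carries values, percentiles and missing flags", {
  phi <- matrix(c(0.5, -0.2, 0.1, 0, 0.3, 0), 3, 2,
                dimnames = list(NULL, c("f1", "f2")))
  X <- matrix(c(1, 2, 3, 5, NA, 7), 3, 2, dimnames = list(NULL, c("f1", "f2")))
  sm <- structure(list(phi = phi, base_value = 0, predictions = rep(0, 3),
                       X = X, feature_names = c("f1", "f2"),
                       scale = "margin"), class = "shap_matrix")
  sd_ <- summary_data(sm)
  expect_equal(names(sd_), c("f1", "f2"))
  expect_equal(nrow(sd_$f1), 3)
  expect_equal(sd_$f1$value_percentile[3], 1)  # column maximum
  expect_true(sd_$f2$missing[2])
  expect_true(is.na(sd_$f2$value_percentile[2]))
})

test_that("dependence data finds the sign-change cutoff when one exists", {
  x <- seq(0, 4, length.out = 60)
  phi <- sign(x - 2) * 0.3
  sm <- structure(list(phi = cbind(g = phi), base_value = 0,
                       predictions = rep(0, 60), X = cbind(g = x),
                       feature_names = "g", scale = "margin"),
                  class = "shap_matrix")
  dd <- dependence_data(sm, "g")
  expect_equal(nrow(dd$data), 60)
  expect_lt(abs(dd$cutoff - 2), 0.1)
  # all-positive phi has no cutoff
  sm$phi <- cbind(g = abs(phi) + 0.1)
  expect_true(is.na(dependence_data(sm, "g")$cutoff))
  expect_error(dependence_data(sm, "nope"), "unknown feature")
})

test_that("local profiles truncate, aggregate and reproduce the prediction", {
  phi <- c(a = 0.4, b = -0.3, c = 0.05, d = 0.01, e = -0.02)
  expl <- structure(list(phi = phi, base_value = 0.5,
                         prediction = 0.5 + sum(phi),
                         feature_values = c(a = 1, b = 2, c = 3, d = 4, e = 5)),
                    class = "shap_explanation")
  lp <- local_profile(expl, top_n = 2)
  expect_equal(lp$feature, c("a", "b", "(other)"))
  expect_equal(sum(lp$phi) + attr(lp, "base_value"), attr(lp, "prediction"))
  full <- local_profile(expl, top_n = 10)
  expect_equal(nrow(full), 5)
  expect_equal(sum(full$phi) + 0.5, expl$prediction)
})
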