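# Model zoo and repeated stratified cross-validation.
#
# Five families: logistic regression, k-nearest neighbours, random
# forest, gradient boosting, multi-layer perceptron. Each family carries
# a default preprocessing policy (see cleaning.R): winsorize + min-max +
# impute 1 for the distance/gradient learners, winsorize + impute -99999
# for the random forest, winsorize + native missing handling for
# gradient boosting. All preprocessing statistics are fitted on the
# training split of each fold only.

MODEL_FAMILIES <- c("logistic_regression", "knn", "random_forest",
                    "gradient_boosting", "mlp")

#' Cross-validation specification
#'
#' @param k number of folds (>= 2).
#' @param repeats number of repetitions, each with a fresh randomization.
#' @param seed base seed; repetition `r` uses `seed + r - 1` for both the
#'   fold assignment and any randomized learner.
#' @export
cv_spec <- function(k = 10, repeats = 10, seed = 42) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(scheme = "kfold_stratified", k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_spec")
}

#' Model specification
#'
#' @param family one of `r paste(MODEL_FAMILIES, collapse=", ")`.
#' @param hyperparams named list overriding family defaults
#'   (`nrounds`, `max_depth`, `eta` for gradient boosting; `num_trees`
#'   for the random forest; `k` for knn; `hidden`, `epochs`,
#'   `batch_size`, `learning_rate` for the MLP).
#' @param preprocess a [preprocess_policy()]; family default when `NULL`.
#' @export
model_spec <- function(family = MODEL_FAMILIES, hyperparams = list(),
                       preprocess = NULL) {
  family <- match.arg(family)
  structure(list(family = family, hyperparams = hyperparams,
                 preprocess = preprocess %||% default_policy(family)),
            class = "model_spec")
}

#' Stratified fold assignment
#'
#' Partitions indices into `k` folds preserving the class proportions:
#' within each class, fold sizes differ by at most one.
#'
#' @param targets 0/1 vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k) aligned to `targets`.
#' @export
stratified_fold_indices <- function(targets, k, seed) {
  classes <- unique(targets)
  if (any(table(targets) < k)) {
    stopf("every class needs at least k = %d members", k)
  }
  folds <- integer(length(targets))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(targets == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# ---- family fit / predict ---------------------------------------------

fit_family <- function(spec, X, y, seed) {
  hp <- spec$hyperparams
  fit <- switch(spec$family,
    logistic_regression = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    knn = list(X = X, y = y, k = hp$k %||% 5L),
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hp$num_trees %||% 500L, seed = seed, num.threads = 1L),
    gradient_boosting = {
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth %||% 6L,
                      eta = hp$eta %||% 0.1,
                      nthread = 1L),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
        nrounds = hp$nrounds %||% 100L, verbose = 0))
    },
    mlp = mlp_fit(X, y, hidden = hp$hidden %||% c(100L, 100L),
                  epochs = hp$epochs %||% 60L,
                  batch_size = hp$batch_size %||% 32L,
                  learning_rate = hp$learning_rate %||% 1e-3, seed = seed))
  list(family = spec$family, fit = fit)
}

predict_family <- function(model, X) {
  switch(model$family,
    logistic_regression = {
      df <- as.data.frame(X)
      names(df) <- colnames(X)
      suppressWarnings(unname(stats::predict(model$fit, newdata = df,
                                             type = "response")))
    },
    knn = {
      pr <- class::knn(model$fit$X, X, factor(model$fit$y, levels = c(0, 1)),
                       k = model$fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    random_forest = stats::predict(model$fit, data = X,
                                   num.threads = 1L)$predictions[, "1"],
    gradient_boosting = stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1L)),
    mlp = stats::predict(model$fit, X))
}

#' Fit one model on a full feature table
#'
#' Fits the family's preprocessing on all rows, then the learner; used
#' for the final model after selection (cross-validated estimates come
#' from [run_cv()]).
#'
#' @param table a cleaned [feature_table()].
#' @param spec a [model_spec()].
#' @param seed learner seed.
#' @return object of class `taste_model` with the preprocessing fit, the
#'   learner and the training matrix in model space.
#' @export
train_model <- function(table, spec, seed = 42) {
  prep <- fit_preprocess(table$values, spec$preprocess)
  X <- apply_preprocess(prep, table$values)
  model <- fit_family(spec, X, table$target, seed)
  structure(list(spec = spec, prep = prep, model = model, X = X,
                 y = table$target, feature_names = colnames(X)),
            class = "taste_model")
}

#' @rdname train_model
#' @param object a `taste_model`.
#' @param newdata a [feature_table()] or numeric matrix on the same
#'   descriptor columns (raw scale; preprocessing is applied here).
#' @param ... unused.
#' @return probability of sweet (class 1) per row.
#' @export
predict.taste_model <- function(object, newdata, ...) {
  V <- if (inherits(newdata, "feature_table")) newdata$values else newdata
  V <- V[, object$feature_names, drop = FALSE]
  predict_family(object$model, apply_preprocess(object$prep, V))
}

#' Run repeated stratified cross-validation
#'
#' For every repetition and fold: fit preprocessing on the training
#' split, apply to both splits, train the learner, score the held-out
#' split. Records per-fold AUROC / AUPRC / F1 / precision / recall and
#' the out-of-fold probability of every compound per repetition.
#'
#' @param table a cleaned [feature_table()].
#' @param model a [model_spec()].
#' @param cv a [cv_spec()].
#' @return object of class `cv_result`.
#' @export
run_cv <- function(table, model, cv) {
  stopifnot(inherits(table, "feature_table"), inherits(model, "model_spec"),
            inherits(cv, "cv_spec"))
  n <- nrow(table$values)
  per_fold <- vector("list", cv$k * cv$repeats)
  oof <- matrix(NA_real_, n, cv$repeats,
                dimnames = list(table$row_ids, NULL))
  fold_assignments <- vector("list", cv$repeats)
  row_i <- 0L
  for (r in seq_len(cv$repeats)) {
    rep_seed <- cv$seed + r - 1L
    folds <- stratified_fold_indices(table$target, cv$k, rep_seed)
    fold_assignments[[r]] <- folds
    for (f in seq_len(cv$k)) {
      test <- folds == f
      prep <- fit_preprocess(table$values[!test, , drop = FALSE],
                             model$preprocess)
      Xtr <- apply_preprocess(prep, table$values[!test, , drop = FALSE])
      Xte <- apply_preprocess(prep, table$values[test, , drop = FALSE])
      fit <- fit_family(model, Xtr, table$target[!test], rep_seed)
      p <- predict_family(fit, Xte)
      oof[test, r] <- p
      y <- table$target[test]
      tm <- suppressWarnings(threshold_metrics(p, y))
      row_i <- row_i + 1L
      per_fold[[row_i]] <- data.frame(
        repetition = r, fold = f, auroc = auroc(p, y), auprc = auprc(p, y),
        f1 = tm[["f1"]], precision = tm[["precision"]], recall = tm[["recall"]])
    }
  }
  structure(list(per_fold = do.call(rbind, per_fold), oof_predictions = oof,
                 folds = fold_assignments, spec = model, cv = cv),
            class = "cv_result")
}

#' Summarize a cross-validation result
#'
#' Mean over all k x repeats folds with a normal-approximation 95%
#' confidence interval per metric.
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @export
summary.cv_result <- function(object, ...) {
  metrics <- c("auroc", "auprc", "f1", "precision", "recall")
  out <- do.call(rbind, lapply(metrics, function(m) {
    x <- object$per_fold[[m]]
    mu <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    data.frame(metric = m, mean = mu, sd = stats::sd(x),
               ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se)
  }))
  rownames(out) <- NULL
  out
}

#' Write a cross-validation result
#'
#' Per-fold metrics as CSV and (optionally) the summary as JSON.
#'
#' @param result a `cv_result`.
#' @param csv_path per-fold metric CSV.
#' @param json_path optional JSON summary.
#' @export
write_cv_result <- function(result, csv_path, json_path = NULL) {
  utils::write.csv(result$per_fold, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- summary(result)
    jsonlite::write_json(list(family = result$spec$family,
                              cv = unclass(result$cv), summary = s),
                         json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}

#' Write a trained model's manifest
#'
#' Family, hyperparameters, preprocessing constants and feature names as
#' JSON — enough to audit or re-fit the model from the feature table.
#'
#' @param model a `taste_model`.
#' @param path JSON path.
#' @export
write_model_manifest <- function(model, path) {
  jsonlite::write_json(list(
    family = model$spec$family,
    hyperparams = model$spec$hyperparams,
    preprocess = unclass(model$spec$preprocess),
    winsorize_bounds = as.data.frame(t(model$prep$bounds)),
    feature_names = model$feature_names), path, auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cv_result <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<cv_result> %s, %dx%d-fold CV\n", x$spec$family,
              x$cv$repeats, x$cv$k))
  print(s, digits = 3)
  invisible(x)
}
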