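# Shapley-value attribution.
#
# Two routes, one contract:
#   * exact_shapley(): brute-force enumeration of all feature subsets
#     with the interventional expectation over a background sample —
#     exponential, usable up to ~20 features, the reference oracle.
#   * tree_shap_matrix(): polynomial-time interventional attribution for
#     tree ensembles, computed per background row from the leaf-path
#     structure of the parsed trees. For any (row, background row) pair
#     a leaf is reached by coalition S iff every path feature on which
#     the row and the background row take different branches is "on"
#     (in S, following the row) or "off" (following the background row)
#     as the path requires; the Shapley weight of each leaf then has a
#     closed combinatorial form.
# Both compute phi such that base + sum(phi) = prediction (additivity).
# The sign convention follows the label encoding: phi > 0 pushes toward
# sweet (1), phi < 0 toward bitter (0).

#' Exact Shapley values by subset enumeration
#'
#' The conditional expectation is implemented as the interventional
#' (marginal) expectation: features in the coalition are fixed to the
#' explained row, the rest are drawn from the background rows, and model
#' outputs are averaged. The baseline is the mean model output over the
#' background.
#'
#' @param f prediction function mapping a numeric matrix (columns = the
#'   M features) to a numeric vector.
#' @param x the explained row (numeric vector of length M).
#' @param background numeric matrix of reference rows (same columns).
#' @param max_features enumeration bound (default 20); more features is
#'   an error directing to the tree-based path.
#' @return list with `phi` (named like `x` if named), `base_value` and
#'   `prediction`, satisfying `base_value + sum(phi) == prediction`.
#' @export
exact_shapley <- function(f, x, background, max_features = 20) {
  x <- as.numeric(x)
  background <- as.matrix(background)
  M <- length(x)
  stopifnot(ncol(background) == M, nrow(background) >= 1)
  if (M > max_features) {
    stopf("%d features exceed the enumeration bound (%d); use tree_shap_matrix()",
          M, max_features)
  }
  n_mask <- bitwShiftL(1L, M)
  masks <- 0:(n_mask - 1)
  popcount <- integer(n_mask)
  for (j in seq_len(M)) {
    popcount <- popcount + bitwAnd(bitwShiftR(masks, j - 1L), 1L)
  }
  v <- numeric(n_mask)
  for (m in masks) {
    H <- background
    on <- which(bitwAnd(m, bitwShiftL(1L, 0:(M - 1))) != 0)
    if (length(on)) H[, on] <- matrix(x[on], nrow(H), length(on), byrow = TRUE)
    v[m + 1] <- mean(f(H))
  }
  # w(s) = s! (M-s-1)! / M!
  w <- exp(lgamma(0:(M - 1) + 1) + lgamma(M - (0:(M - 1))) - lgamma(M + 1))
  phi <- numeric(M)
  for (m in masks) {
    s <- popcount[m + 1]
    for (j in seq_len(M)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) == 0) {
        phi[j] <- phi[j] + w[s + 1] * (v[bitwOr(m, bit) + 1] - v[m + 1])
      }
    }
  }
  names(phi) <- colnames(background)
  list(phi = phi, base_value = v[1], prediction = v[n_mask])
}

# ---- tree parsing ------------------------------------------------------

# Round doubles to their nearest float32 value. The learner stores
# thresholds and compares feature values in single precision; replaying
# its decisions exactly requires the same rounding on both sides.
float32 <- function(v) {
  out <- readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric",
                 size = 4, n = length(v))
  out[is.na(v)] <- NA_real_
  out
}

float32_matrix <- function(X) {
  out <- matrix(float32(X), nrow(X), ncol(X), dimnames = dimnames(X))
  out
}

# Parse an xgboost booster into per-tree node tables plus the additive
# intercept (margin minus the traversed leaf sum, constant by
# construction). The JSON dump is used because it prints thresholds and
# leaf values with enough digits to roundtrip their float32 values.
parse_tree_model <- function(booster, feature_names) {
  json <- paste(xgboost::xgb.dump(booster, dump_format = "json"),
                collapse = "\n")
  forest <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  flatten_tree <- function(node) {
    nodes <- list()
    walk <- function(nd) {
      nodes[[length(nodes) + 1]] <<- nd
      for (ch in nd$children %||% list()) walk(ch)
    }
    walk(node)
    ids <- vapply(nodes, function(nd) nd$nodeid, numeric(1))
    idx <- function(id) match(id, ids)
    is_leaf <- vapply(nodes, function(nd) is.null(nd$split), logical(1))
    list(
      feature = vapply(nodes, function(nd)
        if (is.null(nd$split)) NA_integer_
        else match(nd$split, feature_names), integer(1)),
      split = float32(vapply(nodes, function(nd)
        if (is.null(nd$split_condition)) NA_real_
        else as.numeric(nd$split_condition), numeric(1))),
      yes = vapply(nodes, function(nd)
        if (is.null(nd$yes)) NA_integer_ else idx(nd$yes), integer(1)),
      no = vapply(nodes, function(nd)
        if (is.null(nd$no)) NA_integer_ else idx(nd$no), integer(1)),
      missing = vapply(nodes, function(nd)
        if (is.null(nd$missing)) NA_integer_ else idx(nd$missing), integer(1)),
      value = vapply(nodes, function(nd)
        if (is.null(nd$leaf)) 0 else as.numeric(nd$leaf), numeric(1)),
      is_leaf = is_leaf,
      root = idx(0))
  }
  trees <- lapply(forest, flatten_tree)
  probe <- matrix(0, 1, length(feature_names),
                  dimnames = list(NULL, feature_names))
  margin <- stats::predict(booster, xgboost::xgb.DMatrix(probe, nthread = 1L),
                           outputmargin = TRUE)
  intercept <- margin - sum(vapply(trees, function(tr)
    traverse_tree(tr, as.numeric(probe)), numeric(1)))
  structure(list(trees = trees, intercept = intercept,
                 feature_names = feature_names), class = "parsed_tree_model")
}

# Leaf value reached by one row in one tree (NA values follow the
# missing direction, as in the learner).
traverse_tree <- function(tree, x) {
  i <- tree$root
  while (!tree$is_leaf[i]) {
    v <- x[tree$feature[i]]
    i <- if (is.na(v)) tree$missing[i]
      else if (v < tree$split[i]) tree$yes[i] else tree$no[i]
  }
  tree$value[i]
}

tree_margin <- function(parsed, X) {
  X <- as.matrix(X)
  sums <- apply(X, 1, function(x)
    sum(vapply(parsed$trees, traverse_tree, numeric(1), x = x)))
  parsed$intercept + sums
}

# Enumerate root-to-leaf paths of one tree. For each leaf, record its
# value and the per-feature split lists (threshold, required branch,
# missing branch).
tree_leaf_paths <- function(tree) {
  paths <- list()
  walk <- function(i, splits) {
    if (tree$is_leaf[i]) {
      paths[[length(paths) + 1]] <<- list(value = tree$value[i],
                                          splits = splits)
      return(invisible())
    }
    f <- tree$feature[i]; s <- tree$split[i]
    for (branch in c("yes", "no")) {
      child <- tree[[branch]][i]
      rec <- list(feature = f, split = s, want_yes = branch == "yes",
                  missing_goes_yes = tree$missing[i] == tree$yes[i])
      walk(child, c(splits, list(rec)))
    }
  }
  walk(tree$root, list())
  paths
}

# Does value v of the split's feature take the branch this path needs?
split_satisfied <- function(rec, v) {
  goes_yes <- if (is.na(v)) rec$missing_goes_yes else v < rec$split
  if (rec$want_yes) goes_yes else !goes_yes
}

# Per-leaf, per-path-feature satisfaction of a set of rows: list of
# logical matrices (rows x path features).
leaf_feature_satisfaction <- function(path, Z) {
  feats <- unique(vapply(path$splits, `[[`, numeric(1), "feature"))
  sat <- matrix(TRUE, nrow(Z), length(feats))
  for (rec in path$splits) {
    k <- match(rec$feature, feats)
    v <- Z[, rec$feature]
    goes_yes <- ifelse(is.na(v), rec$missing_goes_yes, v < rec$split)
    ok <- if (rec$want_yes) goes_yes else !goes_yes
    sat[, k] <- sat[, k] & ok
  }
  list(features = feats, sat = sat)
}

#' Interventional Shapley values for a tree ensemble
#'
#' Computes, for every row of `X`, the Shapley attribution of the
#' ensemble's output with the interventional expectation over
#' `background`. On the margin scale the attribution is exact (it equals
#' [exact_shapley()] run on the margin prediction function). On the
#' probability scale, per-background-row attributions are rescaled by
#' the chord slope of the logistic link between the two margins, which
#' preserves additivity exactly on the probability scale.
#'
#' @param model an `xgb.Booster`, a `taste_model` with a gradient-
#'   boosting learner, or a `parsed_tree_model`.
#' @param X numeric matrix of rows to explain (model feature space).
#' @param background numeric matrix of reference rows; defaults to `X`,
#'   subsampled to at most `max_background` rows.
#' @param scale `"margin"` (raw additive ensemble output) or
#'   `"probability"` (logistic-transformed, for binary learners).
#' @param max_background background subsample cap.
#' @param seed RNG seed for the background subsample.
#' @return object of class `shap_matrix`: `phi` (rows x features),
#'   `base_value`, `predictions`, `X`, `feature_names`.
#' @export
tree_shap_matrix <- function(model, X, background = NULL,
                             scale = c("margin", "probability"),
                             max_background = 256, seed = 1) {
  scale <- match.arg(scale)
  if (inherits(model, "taste_model")) {
    if (model$spec$family != "gradient_boosting") {
      stopf("tree attribution requires a tree ensemble; got '%s'",
            model$spec$family)
    }
    model <- parse_tree_model(model$model$fit, model$feature_names)
  } else if (inherits(model, "xgb.Booster")) {
    model <- parse_tree_model(model, colnames(X))
  }
  stopifnot(inherits(model, "parsed_tree_model"))
  X <- float32_matrix(as.matrix(X))
  if (is.null(background)) background <- X
  background <- float32_matrix(as.matrix(background))
  if (nrow(background) > max_background) {
    keep <- with_seed(seed, sample.int(nrow(background), max_background))
    background <- background[keep, , drop = FALSE]
  }
  M <- length(model$feature_names)
  nbg <- nrow(background)

  # leaf paths and background satisfaction, computed once
  all_paths <- unlist(lapply(model$trees, tree_leaf_paths), recursive = FALSE)
  bg_sat <- lapply(all_paths, leaf_feature_satisfaction, Z = background)

  margin_bg <- tree_margin(model, background)
  margin_x <- tree_margin(model, X)

  phi <- matrix(0, nrow(X), M, dimnames = list(rownames(X),
                                               model$feature_names))
  for (r in seq_len(nrow(X))) {
    x <- X[r, ]
    phi_z <- matrix(0, nbg, M)
    for (li in seq_along(all_paths)) {
      path <- all_paths[[li]]
      if (length(path$splits) == 0) next
      feats <- bg_sat[[li]]$features
      satZ <- bg_sat[[li]]$sat
      satx <- vapply(seq_along(feats), function(k) {
        ok <- TRUE
        for (rec in path$splits) {
          if (rec$feature == feats[k]) ok <- ok && split_satisfied(rec, x[feats[k]])
        }
        ok
      }, logical(1))
      in_x <- matrix(satx, nbg, length(feats), byrow = TRUE) & !satZ
      in_z <- matrix(!satx, nbg, length(feats), byrow = TRUE) & satZ
      dead <- matrix(!satx, nbg, length(feats), byrow = TRUE) & !satZ
      reach <- rowSums(dead) == 0
      if (!any(reach)) next
      a <- rowSums(in_x); b <- rowSums(in_z)
      rel <- reach & (a + b) > 0
      if (!any(rel)) next
      v <- path$value
      wx <- ifelse(a > 0,
                   v * exp(lgamma(a) + lgamma(b + 1) - lgamma(a + b + 1)), 0)
      wz <- ifelse(b > 0,
                   v * exp(lgamma(a + 1) + lgamma(b) - lgamma(a + b + 1)), 0)
      for (k in seq_along(feats)) {
        fcol <- feats[k]
        zi <- rel & in_x[, k]
        if (any(zi)) phi_z[zi, fcol] <- phi_z[zi, fcol] + wx[zi]
        zi <- rel & in_z[, k]
        if (any(zi)) phi_z[zi, fcol] <- phi_z[zi, fcol] - wz[zi]
      }
    }
    if (scale == "probability") {
      p_x <- stats::plogis(margin_x[r])
      p_z <- stats::plogis(margin_bg)
      dm <- margin_x[r] - margin_bg
      slope <- ifelse(abs(dm) < 1e-10, p_x * (1 - p_x), (p_x - p_z) / dm)
      phi_z <- phi_z * slope
    }
    phi[r, ] <- colMeans(phi_z)
  }
  if (scale == "probability") {
    base <- mean(stats::plogis(margin_bg))
    preds <- stats::plogis(margin_x)
  } else {
    base <- mean(margin_bg)
    preds <- margin_x
  }
  structure(list(phi = phi, base_value = base, predictions = preds,
                 X = X, feature_names = model$feature_names, scale = scale),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d rows x %d features (%s scale), base = %.4f\n",
              nrow(x$phi), ncol(x$phi), x$scale, x$base_value))
  invisible(x)
}

#' Extract one row's explanation
#'
#' @param matrix a `shap_matrix`.
#' @param i row index or row name.
#' @return object of class `shap_explanation` with `phi`, `base_value`,
#'   `prediction` and `feature_values`.
#' @export
shap_explanation <- function(matrix, i) {
  stopifnot(inherits(matrix, "shap_matrix"))
  structure(list(phi = matrix$phi[i, ], base_value = matrix$base_value,
                 prediction = unname(matrix$predictions[i]),
                 feature_values = matrix$X[i, ]),
            class = "shap_explanation")
}

#' Global feature importance
#'
#' Mean absolute Shapley value per feature, sorted descending (ties by
#' name).
#'
#' @param matrix a `shap_matrix`.
#' @return data.frame with `feature` and `importance`.
#' @export
global_importance <- function(matrix) {
  stopifnot(inherits(matrix, "shap_matrix"), nrow(matrix$phi) > 0)
  imp <- colMeans(abs(matrix$phi))
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Data behind a beeswarm summary plot
#'
#' For each feature (in descending global importance): the per-compound
#' Shapley value, the feature value and its percentile over the
#' non-missing values of the column.
#'
#' @param matrix a `shap_matrix`.
#' @param table optional [feature_table()] supplying raw feature values;
#'   defaults to the matrix's model-space values.
#' @return named list of data.frames `(phi, value, value_percentile,
#'   missing)`.
#' @export
summary_data <- function(matrix, table = NULL) {
  stopifnot(inherits(matrix, "shap_matrix"))
  V <- if (is.null(table)) matrix$X else
    table$values[rownames(matrix$phi), colnames(matrix$phi), drop = FALSE]
  imp <- global_importance(matrix)
  out <- lapply(imp$feature, function(f) {
    vals <- V[, f]
    obs <- vals[!is.na(vals)]
    pct <- if (length(obs)) stats::ecdf(obs)(vals) else rep(NA_real_, length(vals))
    data.frame(phi = matrix$phi[, f], value = vals,
               value_percentile = ifelse(is.na(vals), NA_real_, pct),
               missing = is.na(vals))
  })
  stats::setNames(out, imp$feature)
}

#' Data behind a dependence plot, with an optional cut-off point
#'
#' Scatter pairs (feature value, Shapley value), missing values excluded.
#' When the Shapley values change sign along the feature, the cut-off is
#' the zero crossing of an isotonic (monotone) fit — increasing or
#' decreasing according to the rank correlation of the scatter.
#'
#' @param matrix a `shap_matrix`.
#' @param feature feature name.
#' @param table optional [feature_table()] for raw values.
#' @return list with `data` (data.frame `value`, `phi`) and `cutoff`
#'   (numeric or `NA` when the sign never changes).
#' @export
dependence_data <- function(matrix, feature, table = NULL) {
  stopifnot(inherits(matrix, "shap_matrix"))
  if (!feature %in% colnames(matrix$phi)) stopf("unknown feature '%s'", feature)
  V <- if (is.null(table)) matrix$X else
    table$values[rownames(matrix$phi), colnames(matrix$phi), drop = FALSE]
  vals <- V[, feature]
  keep <- !is.na(vals)
  df <- data.frame(value = vals[keep], phi = matrix$phi[keep, feature])
  df <- df[order(df$value), ]
  cutoff <- NA_real_
  if (nrow(df) >= 3 && min(df$phi) < 0 && max(df$phi) > 0) {
    decreasing <- suppressWarnings(
      stats::cor(df$value, df$phi, method = "spearman")) < 0
    iso <- stats::isoreg(df$value, if (isTRUE(decreasing)) -df$phi else df$phi)
    yf <- if (isTRUE(decreasing)) -iso$yf else iso$yf
    s <- sign(yf)
    cross <- which(s[-1] * s[-length(s)] < 0)
    if (length(cross)) {
      i <- cross[1]
      x1 <- df$value[i]; x2 <- df$value[i + 1]
      y1 <- yf[i]; y2 <- yf[i + 1]
      cutoff <- if (y2 == y1) (x1 + x2) / 2 else x1 - y1 * (x2 - x1) / (y2 - y1)
    }
  }
  list(data = df, cutoff = cutoff)
}

#' Local explanation profile
#'
#' Features sorted by absolute Shapley value, truncated to `top_n`, the
#' remainder aggregated as `"(other)"`; the contributions sum to
#' `prediction - base_value`.
#'
#' @param explanation a [shap_explanation()].
#' @param top_n number of features listed individually.
#' @return data.frame with `feature`, `phi`, `value`.
#' @export
local_profile <- function(explanation, top_n = 10) {
  stopifnot(inherits(explanation, "shap_explanation"))
  ord <- order(-abs(explanation$phi), names(explanation$phi))
  phi <- explanation$phi[ord]
  vals <- explanation$feature_values[ord]
  n <- length(phi)
  if (top_n < n) {
    head_df <- data.frame(feature = names(phi)[seq_len(top_n)],
                          phi = unname(phi[seq_len(top_n)]),
                          value = unname(vals[seq_len(top_n)]))
    out <- rbind(head_df,
                 data.frame(feature = "(other)",
                            phi = sum(phi[(top_n + 1):n]), value = NA_real_))
  } else {
    out <- data.frame(feature = names(phi), phi = unname(phi),
                      value = unname(vals))
  }
  attr(out, "base_value") <- explanation$base_value
  attr(out, "prediction") <- explanation$prediction
  out
}

#' Write explanation artifacts
#'
#' @param matrix a `shap_matrix`.
#' @param phi_path CSV of per-compound Shapley values.
#' @param importance_path optional CSV of global importance.
#' @export
write_shap_matrix <- function(matrix, phi_path, importance_path = NULL) {
  utils::write.csv(data.frame(id = rownames(matrix$phi), matrix$phi,
                              check.names = FALSE),
                   phi_path, row.names = FALSE)
  if (!is.null(importance_path)) {
    utils::write.csv(global_importance(matrix), importance_path,
                     row.names = FALSE)
  }
  invisible(phi_path)
}

#' @export
plot.shap_matrix <- function(x, top_n = 15, ...) {
  imp <- global_importance(x)
  imp <- imp[seq_len(min(top_n, nrow(imp))), ]
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, col = "steelblue",
                    xlab = "mean |Shapley value|", ...)
  invisible(x)
}
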