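# Sequential feature selection: two-sample Kolmogorov-Smirnov ranking of
# univariate class separation, Ward clustering of the Spearman
# correlation structure, one representative per cluster, and a sweep over
# the number of clusters with cross-validated AUROC tracking.
#
# Rationale: descriptor tables are massively redundant (families of
# near-collinear descriptors). Clustering the absolute Spearman
# correlations groups redundant descriptors; keeping the single most
# class-separating member of each cluster yields compact, weakly
# correlated feature sets whose performance can be traded off against
# size along the sweep.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D` is the supremum over pooled sample points of the absolute
#' difference of the two empirical CDFs; the p-value uses the asymptotic
#' two-sample KS distribution. Missing values are dropped.
#'
#' @param x,y numeric samples (e.g. a descriptor's values for bitter and
#'   sweet compounds).
#' @return list with `D` and `p`.
#' @export
ks_statistic <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stopf("ks_statistic needs non-empty samples after dropping missing values")
  }
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  D <- max(abs(Fx - Fy))
  en <- sqrt(length(x) * length(y) / (length(x) + length(y)))
  lambda <- en * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(1, max(0, p)))
}

#' Rank features by univariate class separation
#'
#' KS statistic of each descriptor between the bitter (target 0) and
#' sweet (target 1) rows.
#'
#' @param table a [feature_table()].
#' @return data.frame of class `feature_ranking` with `name`, `ks_stat`,
#'   `ks_p`, sorted by descending `ks_stat` (ties by name).
#' @export
rank_features_ks <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  res <- lapply(colnames(table$values), function(nm) {
    col <- table$values[, nm]
    ks <- ks_statistic(col[table$target == 0], col[table$target == 1])
    data.frame(name = nm, ks_stat = ks$D, ks_p = ks$p)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$ks_stat, out$name), ]
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Spearman correlation structure with Ward linkage
#'
#' Pairwise Spearman rank correlations (pairwise-complete over missing
#' values, average ranks on ties); pairs undefined after pairing
#' (constant values) are set to 0 with a warning. The distance is
#' `1 - |rho|` by default — strong negative correlation is as redundant
#' as strong positive — or `1 - rho` with `sign = "signed"`. The Ward
#' merge tree is computed once and cut repeatedly during the sweep.
#'
#' @param table a [feature_table()].
#' @param sign `"absolute"` (default) or `"signed"` correlation-to-
#'   distance conversion.
#' @return object of class `correlation_structure` with `matrix`,
#'   `distance` and `linkage` (an [stats::hclust()] tree).
#' @export
spearman_structure <- function(table, sign = c("absolute", "signed")) {
  stopifnot(inherits(table, "feature_table"))
  sign <- match.arg(sign)
  rho <- suppressWarnings(stats::cor(table$values, method = "spearman",
                                     use = "pairwise.complete.obs"))
  if (anyNA(rho)) {
    warnf("%d undefined correlation pair(s) set to 0", sum(is.na(rho)) / 2)
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  dmat <- if (sign == "absolute") 1 - abs(rho) else 1 - rho
  linkage <- stats::hclust(stats::as.dist(dmat), method = "ward.D2")
  structure(list(matrix = rho, distance = dmat, linkage = linkage,
                 sign = sign), class = "correlation_structure")
}

#' @rdname spearman_structure
#' @export
spearman_matrix <- function(table) spearman_structure(table)$matrix

#' Cut the Ward tree into a given number of clusters
#'
#' @param structure a [spearman_structure()].
#' @param n_clusters number of clusters (1..n_features).
#' @return named integer vector of cluster ids per feature.
#' @export
ward_clusters <- function(structure, n_clusters) {
  stopifnot(inherits(structure, "correlation_structure"),
            n_clusters >= 1, n_clusters <= ncol(structure$matrix))
  stats::cutree(structure$linkage, k = n_clusters)
}

#' Pick one representative feature per cluster
#'
#' The member with the largest KS statistic; ties broken by
#' lexicographically smaller name.
#'
#' @param assignment cluster ids from [ward_clusters()].
#' @param ranking a `feature_ranking` from [rank_features_ks()].
#' @return character vector with one feature name per cluster.
#' @export
select_representatives <- function(assignment, ranking) {
  ks <- stats::setNames(ranking$ks_stat, ranking$name)
  missing <- setdiff(names(assignment), names(ks))
  if (length(missing)) {
    stopf("no ranking entry for feature(s): %s", paste(missing, collapse = ", "))
  }
  reps <- vapply(split(names(assignment), assignment), function(members) {
    members[order(-ks[members], members)][1]
  }, character(1))
  unname(reps)
}

#' Mean absolute within-cluster correlation
#'
#' Mean of `|rho|` over all unordered within-cluster pairs across all
#' non-singleton clusters; 0 by convention when every cluster is a
#' singleton.
#'
#' @inheritParams select_representatives
#' @param structure a [spearman_structure()].
#' @export
intra_cluster_mean_abs_corr <- function(assignment, structure) {
  vals <- c()
  for (members in split(names(assignment), assignment)) {
    if (length(members) < 2) next
    sub <- abs(structure$matrix[members, members])
    vals <- c(vals, sub[upper.tri(sub)])
  }
  if (length(vals) == 0) 0 else mean(vals)
}

#' Sequential cluster-count sweep
#'
#' For each requested cluster count `k`: cut the cached Ward tree, pick
#' the per-cluster KS representatives, train the reference learner on
#' those `k` features under stratified cross-validation and record the
#' mean AUROC together with the mean absolute intra-cluster correlation.
#' `k = 1` reduces to the single globally most class-separating feature.
#' KS ranking and clustering are computed once on the full table,
#' mirroring a selection pass run before model assessment; see the
#' vignette for the leakage discussion.
#'
#' @param table a cleaned [feature_table()].
#' @param model reference [model_spec()] (default gradient boosting).
#' @param cv a [cv_spec()] (default 5-fold, 1 repetition).
#' @param k_grid cluster counts to visit (default `1:n_features`).
#' @param sign correlation-to-distance convention, see
#'   [spearman_structure()].
#' @param leakage_safe when `TRUE`, ranking, clustering and
#'   representative choice are recomputed on the training split of every
#'   fold instead of once on the full table. The default (`FALSE`)
#'   selects once up front; the per-fold mode gives unbiased selection
#'   performance estimates at the cost of a fold-dependent feature set
#'   (see the vignette).
#' @param verbose print progress.
#' @return data.frame of class `selection_trace` with columns `k`,
#'   `features` (list column), `cv_auroc`, `intra_cluster_abs_corr`.
#' @export
sequential_sweep <- function(table, model = model_spec("gradient_boosting"),
                             cv = cv_spec(k = 5, repeats = 1, seed = 42),
                             k_grid = NULL, sign = "absolute",
                             leakage_safe = FALSE, verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  p <- ncol(table$values)
  k_grid <- sort(unique(as.integer(k_grid %||% seq_len(p))))
  stopifnot(all(k_grid >= 1), all(k_grid <= p))
  ranking <- rank_features_ks(table)
  structure_ <- spearman_structure(table, sign = sign)
  rows <- lapply(k_grid, function(k) {
    assignment <- ward_clusters(structure_, k)
    feats <- sort(select_representatives(assignment, ranking))
    au <- if (leakage_safe) {
      sweep_cv_auroc_perfold(table, model, cv, k, sign)
    } else {
      mean(run_cv(ft_select(table, feats), model, cv)$per_fold$auroc)
    }
    if (verbose) message(sprintf("k = %d: AUROC %.3f", k, au))
    data.frame(k = k, features = I(list(feats)),
               cv_auroc = au,
               intra_cluster_abs_corr =
                 intra_cluster_mean_abs_corr(assignment, structure_))
  })
  out <- do.call(rbind, rows)
  attr(out, "ranking") <- ranking
  attr(out, "structure") <- structure_
  class(out) <- c("selection_trace", "data.frame")
  out
}

# Leakage-safe sweep fold loop: rank, cluster and select on the
# training split only, then score the held-out split.
sweep_cv_auroc_perfold <- function(table, model, cv, k, sign) {
  aurocs <- c()
  for (r in seq_len(cv$repeats)) {
    rep_seed <- cv$seed + r - 1L
    folds <- stratified_fold_indices(table$target, cv$k, rep_seed)
    for (f in seq_len(cv$k)) {
      test <- folds == f
      train_tab <- ft_replace(table, table$values[!test, , drop = FALSE],
                              table$target[!test])
      rk <- rank_features_ks(train_tab)
      st <- spearman_structure(train_tab, sign = sign)
      feats <- sort(select_representatives(ward_clusters(st, k), rk))
      prep <- fit_preprocess(train_tab$values[, feats, drop = FALSE],
                             model$preprocess)
      Xtr <- apply_preprocess(prep, train_tab$values[, feats, drop = FALSE])
      Xte <- apply_preprocess(prep, table$values[test, feats, drop = FALSE])
      fit <- fit_family(model, Xtr, table$target[!test], rep_seed)
      aurocs <- c(aurocs, auroc(predict_family(fit, Xte), table$target[test]))
    }
  }
  mean(aurocs)
}

#' Choose the working feature set from a sweep trace
#'
#' `fixed_k` returns the trace entry at `k`; `knee` returns the smallest
#' `k` whose AUROC is within `tolerance` of the best AUROC in the trace.
#'
#' @param trace a `selection_trace`.
#' @param strategy `"fixed_k"` or `"knee"`.
#' @param k cluster count for `fixed_k`.
#' @param tolerance AUROC slack for `knee`.
#' @return character vector of selected feature names.
#' @export
choose_k <- function(trace, strategy = c("fixed_k", "knee"), k = 29,
                     tolerance = 0.01) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(trace, "selection_trace"), nrow(trace) > 0)
  if (strategy == "fixed_k") {
    i <- match(k, trace$k)
    if (is.na(i)) stopf("k = %d is not in the trace", k)
  } else {
    best <- max(trace$cv_auroc)
    i <- which(trace$cv_auroc >= best - tolerance)[1]
  }
  trace$features[[i]]
}

#' Write a selection trace as CSV
#'
#' Features are semicolon-joined per row so the trace can be re-plotted
#' or re-loaded without the package.
#'
#' @param trace a `selection_trace`.
#' @param path output path.
#' @export
write_selection_trace <- function(trace, path) {
  df <- data.frame(k = trace$k,
                   features = vapply(trace$features, paste, "", collapse = ";"),
                   cv_auroc = trace$cv_auroc,
                   intra_cluster_abs_corr = trace$intra_cluster_abs_corr)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.selection_trace <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$k, x$cv_auroc, type = "b", pch = 16, col = "steelblue",
                 xlab = "number of clusters", ylab = "CV AUROC", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$k, x$intra_cluster_abs_corr, type = "b", pch = 1,
                 col = "firebrick", axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "firebrick")
  graphics::mtext("mean intra-cluster |rho|", side = 4, line = 2.5,
                  col = "firebrick")
  invisible(x)
}
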