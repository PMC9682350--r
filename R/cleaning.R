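# Rule-based cleaning of the raw descriptor table and per-model-family
# preprocessing (winsorization, min-max scaling, constant imputation).
#
# The cleaning order is fixed: duplicate rows -> high-missing columns ->
# near-constant columns -> duplicate columns. Every step returns the
# table plus a report whose counts are exact, so the column arithmetic
#   n_cols_out = n_cols_in - dropped - (collapsed sizes - groups)
# can be asserted on fixtures with planted defects.

new_cleaning_report <- function(...) {
  structure(list(...), class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) v <- sprintf("<%d groups>", length(v))
    if (length(v) > 6) v <- c(v[1:6], "...")
    cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

row_key <- function(values) {
  apply(values, 1, function(r) paste(format(r, digits = 15), collapse = "\r"))
}

#' Resolve duplicate feature rows
#'
#' Rows identical across all feature columns (missing matching missing)
#' form a group: if the group's targets agree, the first row is kept;
#' if they conflict, the whole group is removed — structures that the
#' descriptor space cannot distinguish but that carry opposite labels are
#' ambiguous for the model.
#'
#' @param table a [feature_table()].
#' @return list with `table` and `report` (kept / collapsed / removed
#'   counts plus removed row ids).
#' @export
resolve_duplicate_rows <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  keys <- row_key(table$values)
  grp <- split(seq_len(nrow(table$values)), keys)
  keep <- integer(0); removed <- integer(0)
  n_collapsed_groups <- 0L; n_collapsed_rows <- 0L
  for (idx in grp) {
    targs <- unique(table$target[idx])
    if (length(targs) > 1) {
      removed <- c(removed, idx)
    } else {
      keep <- c(keep, idx[1])
      if (length(idx) > 1) {
        n_collapsed_groups <- n_collapsed_groups + 1L
        n_collapsed_rows <- n_collapsed_rows + length(idx) - 1L
      }
    }
  }
  keep <- sort(keep)
  out <- ft_replace(table, table$values[keep, , drop = FALSE],
                    table$target[keep])
  report <- new_cleaning_report(
    n_rows_in = nrow(table$values), n_rows_out = length(keep),
    collapsed_duplicate_rows = n_collapsed_rows,
    collapsed_duplicate_row_groups = n_collapsed_groups,
    removed_conflicting_rows = table$row_ids[sort(removed)])
  list(table = out, report = report)
}

#' Drop columns with excessive missingness
#'
#' Columns whose missing fraction is greater than or equal to `threshold`
#' (default 0.95) are removed.
#'
#' @param table a [feature_table()].
#' @param threshold missing fraction cut-off in (0, 1].
#' @export
drop_high_missing <- function(table, threshold = 0.95) {
  stopifnot(inherits(table, "feature_table"), threshold > 0, threshold <= 1)
  frac <- colMeans(is.na(table$values))
  drop <- names(frac)[frac >= threshold]
  out <- ft_replace(table, table$values[, setdiff(colnames(table$values), drop),
                                        drop = FALSE])
  list(table = out,
       report = new_cleaning_report(n_cols_in = ncol(table$values),
                                    n_cols_out = ncol(out$values),
                                    dropped_high_missing = drop))
}

#' Drop constant and near-constant columns
#'
#' A column is dropped when its modal non-missing value accounts for at
#' least `dominance` (default 0.99) of the non-missing entries, or when
#' it is constant (including all-missing).
#'
#' @param table a [feature_table()].
#' @param dominance modal share cut-off in (0, 1].
#' @export
drop_near_constant <- function(table, dominance = 0.99) {
  stopifnot(inherits(table, "feature_table"), dominance > 0, dominance <= 1)
  is_dominated <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(TRUE)
    tab <- table(x)
    max(tab) / length(x) >= dominance || length(tab) == 1
  }
  drop <- colnames(table$values)[apply(table$values, 2, is_dominated)]
  out <- ft_replace(table, table$values[, setdiff(colnames(table$values), drop),
                                        drop = FALSE])
  list(table = out,
       report = new_cleaning_report(n_cols_in = ncol(table$values),
                                    n_cols_out = ncol(out$values),
                                    dropped_near_constant = drop))
}

#' Collapse entrywise-identical columns
#'
#' Columns identical on every entry (missing matching missing) are
#' collapsed to a single column carrying the lexicographically first
#' name of the group.
#'
#' @param table a [feature_table()].
#' @export
collapse_duplicate_columns <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  keys <- apply(table$values, 2, function(col)
    paste(format(col, digits = 15), collapse = "\r"))
  grp <- split(colnames(table$values), keys)
  groups <- Filter(function(g) length(g) > 1, grp)
  keep <- sort(vapply(grp, function(g) sort(g)[1], character(1)))
  out <- ft_replace(table, table$values[, keep, drop = FALSE])
  list(table = out,
       report = new_cleaning_report(
         n_cols_in = ncol(table$values), n_cols_out = ncol(out$values),
         collapsed_duplicate_columns = unname(lapply(groups, sort))))
}

#' Run the full cleaning pipeline
#'
#' Duplicate rows, then high-missing columns, then near-constant columns,
#' then duplicate columns, with one merged report.
#'
#' @param table a [feature_table()].
#' @inheritParams drop_high_missing
#' @inheritParams drop_near_constant
#' @return list with `table` and `report`.
#' @export
clean_feature_table <- function(table, threshold = 0.95, dominance = 0.99) {
  s1 <- resolve_duplicate_rows(table)
  s2 <- drop_high_missing(s1$table, threshold)
  s3 <- drop_near_constant(s2$table, dominance)
  s4 <- collapse_duplicate_columns(s3$table)
  report <- new_cleaning_report(
    n_rows_in = nrow(table$values), n_rows_out = nrow(s4$table$values),
    n_cols_in = ncol(table$values), n_cols_out = ncol(s4$table$values),
    collapsed_duplicate_rows = s1$report$collapsed_duplicate_rows,
    removed_conflicting_rows = s1$report$removed_conflicting_rows,
    dropped_high_missing = s2$report$dropped_high_missing,
    dropped_near_constant = s3$report$dropped_near_constant,
    collapsed_duplicate_columns = s4$report$collapsed_duplicate_columns)
  list(table = s4$table, report = report)
}

#' Write a cleaning report as JSON
#' @param report a `cleaning_report`.
#' @param path output path.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- per-model-family preprocessing -----------------------------------

#' Preprocessing policy
#'
#' Winsorization percentiles, optional min-max scaling and the
#' missing-value imputation constant for one model family. Descriptor
#' missingness is missing-not-at-random, so imputation uses a constant
#' out-of-distribution value (or the learner's native missing handling)
#' rather than a distributional estimate.
#'
#' @param winsorize_lo,winsorize_hi percentiles in (0, 100), lo < hi.
#' @param scale `"minmax"` or `"none"`.
#' @param impute_constant a finite number, or `"native_missing"` to pass
#'   missing values through to a learner that handles them natively.
#' @export
preprocess_policy <- function(winsorize_lo = 5, winsorize_hi = 95,
                              scale = c("minmax", "none"),
                              impute_constant = 1) {
  scale <- match.arg(scale)
  stopifnot(winsorize_lo < winsorize_hi, winsorize_lo > 0, winsorize_hi < 100)
  if (!identical(impute_constant, "native_missing")) {
    stopifnot(is.numeric(impute_constant), is.finite(impute_constant))
  }
  structure(list(winsorize_lo = winsorize_lo, winsorize_hi = winsorize_hi,
                 scale = scale, impute_constant = impute_constant),
            class = "preprocess_policy")
}

default_policy <- function(family) {
  switch(family,
    logistic_regression = ,
    knn = ,
    mlp = preprocess_policy(scale = "minmax", impute_constant = 1),
    random_forest = preprocess_policy(scale = "none", impute_constant = -99999),
    gradient_boosting = preprocess_policy(scale = "none",
                                          impute_constant = "native_missing"),
    stopf("unknown model family '%s'", family))
}

#' Fit winsorization bounds on training values
#'
#' Percentiles use the linear-interpolation convention (R quantile
#' type 7). Bounds fitted on a training split are reusable on held-out
#' data; missing values pass through untouched.
#'
#' @param x training values (may contain `NA`).
#' @param lo,hi percentiles in (0, 100).
#' @return numeric `c(lo, hi)` clipping bounds.
#' @export
winsorize_fit <- function(x, lo = 5, hi = 95) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stopf("winsorization needs >= 2 non-missing training values")
  stats::quantile(x, c(lo, hi) / 100, names = FALSE, type = 7)
}

#' @rdname winsorize_fit
#' @param bounds fitted bounds from `winsorize_fit`.
#' @export
winsorize_apply <- function(x, bounds) {
  out <- pmin(pmax(x, bounds[1]), bounds[2])
  out[is.na(x)] <- NA_real_
  out
}

#' Fit / apply min-max scaling
#'
#' Training values map into \[0, 1\]; held-out values may fall outside
#' and are not re-clipped; missing values pass through.
#'
#' @param x training values.
#' @return `minmax_fit`: numeric `c(min, max)`.
#' @export
minmax_fit <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] >= r[2]) {
    stopf("min-max scaling needs a non-degenerate training range")
  }
  r
}

#' @rdname minmax_fit
#' @param fitted fitted range from `minmax_fit`.
#' @export
minmax_apply <- function(x, fitted) (x - fitted[1]) / (fitted[2] - fitted[1])

#' Impute missing values with a policy constant
#'
#' @param values numeric matrix.
#' @param policy a [preprocess_policy()]; `"native_missing"` returns the
#'   input unchanged.
#' @export
impute_mnar <- function(values, policy) {
  if (identical(policy$impute_constant, "native_missing")) return(values)
  values[is.na(values)] <- policy$impute_constant
  values
}

# Fit the full per-column preprocessing on a training matrix. Columns
# that are degenerate within a fold (constant after winsorization) are
# scaled to zero rather than aborting the fold; globally constant
# columns are removed earlier by drop_near_constant.
fit_preprocess <- function(X, policy) {
  cols <- colnames(X)
  bounds <- matrix(NA_real_, 2, length(cols), dimnames = list(NULL, cols))
  ranges <- matrix(NA_real_, 2, length(cols), dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    x <- X[, j]
    if (sum(!is.na(x)) >= 2) {
      bounds[, j] <- winsorize_fit(x, policy$winsorize_lo, policy$winsorize_hi)
    } else {
      bounds[, j] <- c(-Inf, Inf)
    }
    if (policy$scale == "minmax") {
      w <- winsorize_apply(x, bounds[, j])
      r <- suppressWarnings(range(w, na.rm = TRUE))
      ranges[, j] <- if (is.finite(r[1]) && r[1] < r[2]) r else c(NA, NA)
    }
  }
  structure(list(policy = policy, bounds = bounds, ranges = ranges),
            class = "preprocess_fit")
}

apply_preprocess <- function(fit, X) {
  out <- X
  for (j in seq_len(ncol(X))) {
    x <- winsorize_apply(X[, j], fit$bounds[, j])
    if (fit$policy$scale == "minmax") {
      r <- fit$ranges[, j]
      x <- if (anyNA(r)) ifelse(is.na(x), NA_real_, 0) else minmax_apply(x, r)
    }
    out[, j] <- x
  }
  impute_mnar(out, fit$policy)
}
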