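# Fingerprint-similarity applicability domain.
#
# Reliability of a taste prediction is judged by structural similarity
# to the training chemistry: a query's score is the mean Tanimoto
# similarity of its circular fingerprint to its 5 most similar training
# compounds, and the verdict compares that score with a threshold
# calibrated from the train/validation score distributions of a random
# 90:10 split.

FINGERPRINT_BITS <- 1024L

#' Circular (Morgan-type) fingerprint
#'
#' Radius-2 circular substructure fingerprint from the cheminformatics
#' backend (ECFP4 hashing), folded to a fixed 1024-bit vector. Identical
#' structures (any SMILES spelling) give identical bits.
#'
#' @param smiles one or more SMILES strings.
#' @return a 0/1 integer matrix with `length(smiles)` rows and 1024
#'   columns.
#' @export
fingerprint <- function(smiles) {
  std <- lapply(smiles, standardize_compound)
  bad <- !vapply(std, `[[`, logical(1), "ok")
  if (any(bad)) {
    stopf("cannot fingerprint invalid SMILES: %s",
          paste(smiles[bad], collapse = ", "))
  }
  can <- vapply(std, `[[`, character(1), "smiles")
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(can, sprintf("m%d", seq_along(can)))))
  fp_of <- function(s) ChemmineR::as.matrix(ChemmineR::fingerprintOB(s, "ECFP4"))
  fp <- tryCatch(fp_of(sdf), error = function(e) NULL)
  if (is.null(fp)) {
    # structures without bonded environments (single heavy atoms, ...)
    # abort the backend; give them an empty fingerprint instead
    rows <- lapply(seq_along(can), function(i) {
      r <- tryCatch(fp_of(sdf[i]), error = function(e) NULL)
      if (is.null(r)) matrix(0L, 1, 4096) else r
    })
    fp <- do.call(rbind, rows)
  }
  folded <- matrix(0L, nrow(fp), FINGERPRINT_BITS)
  for (block in seq_len(ncol(fp) / FINGERPRINT_BITS)) {
    cols <- ((block - 1) * FINGERPRINT_BITS + 1):(block * FINGERPRINT_BITS)
    folded <- folded | fp[, cols, drop = FALSE]
  }
  storage.mode(folded) <- "integer"
  rownames(folded) <- NULL
  folded
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of the bit sets; two empty fingerprints give
#' 0 with a warning.
#'
#' @param a,b 0/1 vectors of equal length.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stopf("fingerprint lengths differ (%d vs %d)",
                                    length(a), length(b))
  union <- sum(a | b)
  if (union == 0) {
    warnf("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / union
}

# Tanimoto of one query against a fingerprint matrix (vectorized).
tanimoto_vector <- function(query, reference) {
  inter <- as.numeric(reference %*% query)
  union <- rowSums(reference) + sum(query) - inter
  ifelse(union == 0, 0, inter / union)
}

#' Mean similarity to the k nearest training compounds
#'
#' Mean of the `k` largest Tanimoto similarities of `query` against the
#' reference set; with fewer than `k` references, the mean over all.
#' When the query is itself a reference member, pass its row index as
#' `exclude` so self-similarity does not inflate the score.
#'
#' @param query fingerprint vector.
#' @param reference fingerprint matrix.
#' @param k neighbourhood size (default 5).
#' @param exclude optional reference row index to leave out.
#' @export
average_top_k_similarity <- function(query, reference, k = 5, exclude = NULL) {
  if (nrow(reference) == 0) stopf("empty reference set")
  sims <- tanimoto_vector(query, reference)
  if (!is.null(exclude)) sims <- sims[-exclude]
  if (length(sims) == 0) stopf("no reference compounds left after exclusion")
  mean(sort(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))])
}

#' Calibrate the applicability-domain threshold
#'
#' Computes the average-top-`k` similarity score of every training
#' compound against the training set (self excluded) and of every
#' validation compound against the training set; the threshold is the
#' `percentile_p`-th percentile of the validation score distribution.
#' Both distributions are stored for inspection.
#'
#' @param train_fps,validation_fps fingerprint matrices from
#'   [fingerprint()].
#' @param k neighbourhood size.
#' @param percentile_p percentile of the validation distribution
#'   (default 5).
#' @return object of class `ad_model`.
#' @export
calibrate_threshold <- function(train_fps, validation_fps, k = 5,
                                percentile_p = 5) {
  stopifnot(nrow(train_fps) > 0, nrow(validation_fps) > 0)
  train_scores <- vapply(seq_len(nrow(train_fps)), function(i)
    average_top_k_similarity(train_fps[i, ], train_fps, k, exclude = i),
    numeric(1))
  validation_scores <- vapply(seq_len(nrow(validation_fps)), function(i)
    average_top_k_similarity(validation_fps[i, ], train_fps, k), numeric(1))
  threshold <- stats::quantile(validation_scores, percentile_p / 100,
                               names = FALSE, type = 7)
  structure(list(train_fingerprints = train_fps, threshold = threshold,
                 k = k, percentile_p = percentile_p,
                 calibration = list(train_scores = train_scores,
                                    validation_scores = validation_scores)),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model> %d training fingerprints, top-%d threshold = %.3f (p%g of validation)\n",
              nrow(x$train_fingerprints), x$k, x$threshold, x$percentile_p))
  invisible(x)
}

#' Calibrate an applicability domain from a curated dataset
#'
#' Convenience wrapper: a stratified 90:10 split (one fold of a 10-fold
#' assignment) provides the validation set, the remainder the training
#' references.
#'
#' @param dataset a curated [curated_dataset()].
#' @param seed split seed.
#' @inheritParams calibrate_threshold
#' @export
calibrate_ad <- function(dataset, seed = 42, k = 5, percentile_p = 5) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  folds <- stratified_fold_indices(rec$label, 10, seed)
  fps <- fingerprint(rec$smiles)
  calibrate_threshold(fps[folds != 1, , drop = FALSE],
                      fps[folds == 1, , drop = FALSE],
                      k = k, percentile_p = percentile_p)
}

#' Applicability-domain verdict for a query molecule
#'
#' Inside the domain iff the average-top-k similarity is greater than or
#' equal to the calibrated threshold (boundary counts as inside). The
#' score is always reported next to the verdict. A degenerate empty
#' fingerprint is outside, with a warning.
#'
#' @param query a SMILES string.
#' @param model an [ad_model][calibrate_threshold()].
#' @return list with `verdict` (`"inside"`/`"outside"`) and `score`.
#' @export
in_domain <- function(query, model) {
  stopifnot(inherits(model, "ad_model"))
  fp <- fingerprint(query)[1, ]
  if (sum(fp) == 0) {
    warnf("query fingerprint is empty; verdict 'outside'")
    return(list(verdict = "outside", score = 0))
  }
  score <- average_top_k_similarity(fp, model$train_fingerprints, model$k)
  list(verdict = if (score >= model$threshold) "inside" else "outside",
       score = score)
}

#' Serialize / restore an applicability-domain model
#'
#' Fingerprints are stored as character bit strings in JSON.
#'
#' @param model an `ad_model`.
#' @param path JSON path.
#' @export
write_ad_model <- function(model, path) {
  obj <- list(threshold = model$threshold, k = model$k,
              percentile_p = model$percentile_p,
              calibration = model$calibration,
              train_fingerprints = apply(model$train_fingerprints, 1, paste,
                                         collapse = ""))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ad_model
#' @export
read_ad_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fps <- do.call(rbind, lapply(strsplit(obj$train_fingerprints, ""),
                               as.integer))
  structure(list(train_fingerprints = fps, threshold = obj$threshold,
                 k = obj$k, percentile_p = obj$percentile_p,
                 calibration = obj$calibration), class = "ad_model")
}
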