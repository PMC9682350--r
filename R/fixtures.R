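# Synthetic fixtures with known ground truth.
#
# The block generator emulates the redundancy structure of real
# descriptor tables: blocks of strongly rank-correlated features
# (realized through a per-block latent factor plus a weak global factor),
# a subset of "informative" blocks whose members separate the two
# classes with a known within-block ordering of effect sizes, optional
# value-dependent (MNAR) missingness, and seed determinism throughout.
# Ground truth (block membership, expected per-block representative) is
# returned so parameter-recovery tests need no stored fixtures.

#' Block-structure specification
#'
#' @param n_blocks,block_size layout of the feature space.
#' @param within_block_corr,between_block_corr latent-factor
#'   correlations, `0 <= between < within <= 1`.
#' @param informative_blocks indices of blocks whose features shift with
#'   the class.
#' @param class_shift mean shift (in SD units) of the strongest member
#'   of each informative block for class-1 rows; the remaining members
#'   shift by half of it, so the within-block KS ranking is known.
#' @param n_rows number of rows (balanced classes).
#' @param seed RNG seed.
#' @export
block_spec <- function(n_blocks = 20, block_size = 8, within_block_corr = 0.9,
                       between_block_corr = 0.05, informative_blocks = 1:5,
                       class_shift = 1.0, n_rows = 600, seed = 1) {
  stopifnot(between_block_corr >= 0, between_block_corr < within_block_corr,
            within_block_corr <= 1,
            all(informative_blocks %in% seq_len(n_blocks)))
  structure(list(n_blocks = n_blocks, block_size = block_size,
                 within_block_corr = within_block_corr,
                 between_block_corr = between_block_corr,
                 informative_blocks = as.integer(informative_blocks),
                 class_shift = class_shift, n_rows = as.integer(n_rows),
                 seed = as.integer(seed)), class = "block_spec")
}

ATTENUATION <- 0.5  # shift multiplier for non-lead members of a block

#' Generate a block-correlated feature table
#'
#' Feature `j` of block `b` is `sqrt(v) g0 + sqrt(w - v) g_b + sqrt(1-w) e`
#' with `g0` a global factor (`v` = between-block correlation), `g_b`
#' the block factor (`w` = within-block correlation) and `e` independent
#' noise. In informative blocks, class-1 rows additionally shift the
#' first ("lead") member by `class_shift` and the others by half of it.
#'
#' @param spec a [block_spec()].
#' @return list with `table` (a [feature_table()]) and `truth`
#'   (`block` assignment per feature, `informative` flags,
#'   `expected_representative` per informative block).
#' @export
generate_block_table <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  p <- spec$n_blocks * spec$block_size
  n <- spec$n_rows
  target <- rep(c(0, 1), length.out = n)
  feat_names <- as.vector(t(outer(seq_len(spec$n_blocks),
                                  seq_len(spec$block_size),
                                  function(b, j) sprintf("blk%02d_f%d", b, j))))
  block_of <- rep(seq_len(spec$n_blocks), each = spec$block_size)
  a <- sqrt(spec$between_block_corr)
  b_load <- sqrt(spec$within_block_corr - spec$between_block_corr)
  e_load <- sqrt(1 - spec$within_block_corr)
  values <- with_seed(spec$seed, {
    g0 <- stats::rnorm(n)
    G <- matrix(stats::rnorm(n * spec$n_blocks), n, spec$n_blocks)
    E <- matrix(stats::rnorm(n * p), n, p)
    V <- a * g0 + b_load * G[, block_of] + e_load * E
    for (blk in spec$informative_blocks) {
      cols <- which(block_of == blk)
      shifts <- c(spec$class_shift,
                  rep(ATTENUATION * spec$class_shift, length(cols) - 1))
      V[target == 1, cols] <- V[target == 1, cols] +
        matrix(shifts, sum(target == 1), length(cols), byrow = TRUE)
    }
    V
  })
  colnames(values) <- feat_names
  rownames(values) <- sprintf("row%04d", seq_len(n))
  truth <- list(
    block = stats::setNames(block_of, feat_names),
    informative = seq_len(spec$n_blocks) %in% spec$informative_blocks,
    expected_representative = stats::setNames(
      sprintf("blk%02d_f1", spec$informative_blocks), spec$informative_blocks))
  list(table = feature_table(values, target, source_tag = "synthetic"),
       truth = truth)
}

#' Inject value-dependent (MNAR) missingness
#'
#' Entries of the chosen columns become missing when their value exceeds
#' the column's `1 - fraction` quantile — deterministic, value-caused
#' missingness mimicking descriptors that are incomputable for certain
#' structures. The realized missing fraction is within 0.02 of the
#' target for continuous columns.
#'
#' @param table a [feature_table()].
#' @param columns column names to affect.
#' @param fraction target missing fraction in (0, 1).
#' @export
inject_mnar <- function(table, columns, fraction) {
  stopifnot(inherits(table, "feature_table"), fraction > 0, fraction < 1)
  vals <- table$values
  for (cn in columns) {
    q <- stats::quantile(vals[, cn], 1 - fraction, na.rm = TRUE, names = FALSE,
                         type = 7)
    vals[vals[, cn] > q, cn] <- NA_real_
  }
  ft_replace(table, vals)
}

#' Toy boosted tree model for explanation oracle tests
#'
#' Fits a small gradient-boosted regression ensemble on generated data
#' whose response depends on the first `n_features - 1` columns only;
#' the last column is constant during training, so no tree can split on
#' it and its Shapley value must be exactly 0 (dummy axiom hook). The
#' returned prediction function is the raw additive margin.
#'
#' @param n_features number of features (<= 12).
#' @param n_rows training rows.
#' @param n_background background rows returned for explanations.
#' @param seed RNG seed.
#' @return list with `booster`, `predict_fun`, `X`, `background`,
#'   `feature_names`.
#' @export
toy_tree_model <- function(n_features = 8, n_rows = 200, n_background = 64,
                           seed = 1) {
  stopifnot(n_features >= 2, n_features <= 12)
  feat <- sprintf("f%02d", seq_len(n_features))
  dat <- with_seed(seed, {
    X <- matrix(stats::rnorm(n_rows * n_features), n_rows, n_features,
                dimnames = list(NULL, feat))
    X[, n_features] <- 0  # structurally unused feature
    w <- stats::rnorm(n_features - 1)
    y <- X[, -n_features, drop = FALSE] %*% w +
      0.5 * X[, 1] * X[, 2] + 0.2 * stats::rnorm(n_rows)
    list(X = X, y = as.numeric(y))
  })
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = 3, eta = 0.3,
                  nthread = 1L),
    data = xgboost::xgb.DMatrix(dat$X, label = dat$y, nthread = 1L),
    nrounds = 20, verbose = 0))
  bg <- with_seed(seed + 1L, {
    B <- dat$X[sample.int(n_rows, min(n_background, n_rows)), , drop = FALSE]
    B[, n_features] <- stats::rnorm(nrow(B))  # exercised at explain time
    B
  })
  predict_fun <- function(M) stats::predict(
    booster, xgboost::xgb.DMatrix(as.matrix(M), nthread = 1L),
    outputmargin = TRUE)
  list(booster = booster, predict_fun = predict_fun, X = dat$X,
       background = bg, feature_names = feat)
}

#' Programmatic compound families
#'
#' Enumerates valid SMILES with controllable structural similarity
#' gradients: linear alkanes, polyol ("sugar-like") chains, and
#' alkyl-substituted benzenes.
#'
#' @param scaffold_family `"alkanes"`, `"sugars_like"` or `"aromatics"`.
#' @param n number of molecules.
#' @return character vector of `n` SMILES.
#' @export
toy_compound_set <- function(scaffold_family = c("alkanes", "sugars_like",
                                                 "aromatics"), n) {
  scaffold_family <- match.arg(scaffold_family)
  i <- seq_len(n)
  switch(scaffold_family,
    alkanes = strrep("C", i + 1),
    sugars_like = paste0("OC", strrep("C(O)", i), "CO"),
    aromatics = paste0(strrep("C", i - 1), "c1ccccc1"))
}

#' Reference molecules with published SMILES
#'
#' Six standard compounds used as worked explanation examples: three
#' sweet (sucrose, glucose, aspartame) and three bitter (propranolol,
#' caffeine, denatonium).
#'
#' @return named character vector of SMILES.
#' @export
reference_molecules <- function() {
  c(sucrose = "OC[C@H]1O[C@@](CO)(O[C@H]2O[C@H](CO)[C@@H](O)[C@H](O)[C@H]2O)[C@@H](O)[C@@H]1O",
    glucose = "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O",
    aspartame = "COC(=O)[C@H](Cc1ccccc1)NC(=O)[C@@H](N)CC(=O)O",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    denatonium = "CC[N+](CC)(Cc1ccccc1)CC(=O)Nc1c(C)cccc1C")
}

#' Demo bitter/sweet compound set
#'
#' A programmatic ~50-molecule dataset for end-to-end runs: polyol
#' chains labelled sweet, substituted aromatics and alkanes labelled
#' bitter (a caricature of the real chemistry, adequate for exercising
#' every pipeline stage).
#'
#' @param n_per_class compounds per class.
#' @return a [curated_dataset()] of raw (unstandardized) records.
#' @export
demo_compound_set <- function(n_per_class = 25) {
  sweet <- toy_compound_set("sugars_like", n_per_class)
  n_arom <- ceiling(n_per_class / 2)
  bitter <- c(toy_compound_set("aromatics", n_arom),
              toy_compound_set("alkanes", n_per_class - n_arom))
  curated_dataset(data.frame(
    id = make_compound_ids(2 * n_per_class),
    smiles = c(sweet, bitter),
    taste = rep(c("sweet", "bitter"), each = n_per_class),
    source = "demo", stringsAsFactors = FALSE))
}
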