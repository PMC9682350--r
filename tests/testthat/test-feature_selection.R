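# KS ranking, Spearman/Ward structure, representatives, and the sweep.

test_that("ks statistic matches hand-derived cases", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_statistic(c(0, 1), c(2, 3))$D, 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3)
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")
  # missing values are dropped, not imputed
  expect_equal(ks_statistic(c(1, 2, 3, NA), c(2, 3, 4))$D, 1 / 3)
})

test_that("ks statistic equals the pooled-grid oracle; p agrees with ks.test", {
  set.seed(13)
  for (i in 1:40) {
    n1 <- sample(5:250, 1); n2 <- sample(5:250, 1)
    x <- round(rnorm(n1), sample(0:2, 1))
    y <- round(rnorm(n2, sample(c(0, 0.5), 1)), sample(0:2, 1))
    ks <- ks_statistic(x, y)
    expect_equal(ks$D, ks_grid(x, y))
    if (!any(duplicated(c(x, y)))) {
      ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      expect_equal(ks$D, unname(ref$statistic))
      expect_equal(ks$p, ref$p.value, tolerance = 1e-6)
    }
  }
})

test_that("spearman structure handles identity, monotone maps and reversal", {
  set.seed(4)
  x <- rnorm(40)
  v <- cbind(x = x, expx = exp(x), revx = max(x) - x + rnorm(40, sd = 1e-9))
  colnames(v) <- c("x", "expx", "revx")
  ft <- feature_table(v, rep(c(0, 1), 20))
  rho <- spearman_matrix(ft)
  expect_equal(unname(diag(rho)), rep(1, 3))
  expect_equal(rho["x", "expx"], 1)
  expect_equal(rho["x", "revx"], -1, tolerance = 1e-6)
})

test_that("spearman matrix is invariant under strictly monotone transforms", {
  set.seed(6)
  v <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  ft1 <- feature_table(v, rep(c(0, 1), 25))
  v2 <- v; v2[, 2] <- exp(v[, 2]); v2[, 3] <- v[, 3]^3
  ft2 <- feature_table(v2, ft1$target)
  expect_equal(spearman_matrix(ft1), spearman_matrix(ft2), ignore_attr = TRUE)
})

test_that("ward cuts recover planted correlation blocks and nest across k", {
  g <- generate_block_table(block_spec(n_blocks = 3, block_size = 4,
                                       informative_blocks = 1,
                                       within_block_corr = 0.95,
                                       between_block_corr = 0.05,
                                       n_rows = 300, seed = 5))
  st <- spearman_structure(g$table)
  a3 <- ward_clusters(st, 3)
  expect_equal(length(unique(a3)), 3)
  # recovered clusters coincide with planted blocks
  expect_equal(unname(vapply(split(g$truth$block[names(a3)], a3),
                             function(b) length(unique(b)), integer(1))),
               rep(1L, 3))
  # extremes
  expect_equal(length(unique(ward_clusters(st, 1))), 1)
  expect_equal(length(unique(ward_clusters(st, 12))), 12)
  # nesting: cutting at k and k+1 differs by exactly one cluster split
  for (k in 1:11) {
    ak <- ward_clusters(st, k); ak1 <- ward_clusters(st, k + 1)
    crossed <- table(ak, ak1)
    expect_equal(sum(rowSums(crossed > 0) > 1), 1L)
  }
})

test_that("representatives are per-cluster KS argmax with lexicographic ties", {
  ranking <- structure(data.frame(name = c("A", "B", "C", "D"),
                                  ks_stat = c(0.6, 0.3, 0.5, 0.5),
                                  ks_p = 0), class = c("feature_ranking",
                                                       "data.frame"))
  asg <- c(A = 1, B = 1, C = 2, D = 2)
  expect_setequal(select_representatives(asg, ranking), c("A", "C"))
  expect_error(select_representatives(c(E = 1), ranking), "no ranking entry")
  # singleton cluster returns its only member
  expect_setequal(select_representatives(c(A = 1, B = 2, C = 3, D = 4),
                                         ranking), c("A", "B", "C", "D"))
})

test_that("intra-cluster mean absolute correlation follows its definition", {
  rho <- diag(4)
  dimnames(rho) <- list(letters[1:4], letters[1:4])
  rho["a", "b"] <- rho["b", "a"] <- -0.8
  rho["c", "d"] <- rho["d", "c"] <- 0.7
  st <- structure(list(matrix = rho), class = "correlation_structure")
  expect_equal(intra_cluster_mean_abs_corr(c(a = 1, b = 1, c = 2, d = 2), st),
               0.75)
  expect_equal(intra_cluster_mean_abs_corr(c(a = 1, b = 2, c = 3, d = 4), st),
               0)
  expect_equal(intra_cluster_mean_abs_corr(c(a = 1, b = 1, c = 2, d = 3), st),
               0.8)
})

test_that("sweep traces selection, AUROC and intra-cluster correlation", {
  g <- generate_block_table(block_spec(n_blocks = 4, block_size = 3,
                                       informative_blocks = 1:2,
                                       class_shift = 1.2, n_rows = 200,
                                       seed = 12))
  spec <- model_spec("gradient_boosting", list(nrounds = 25, max_depth = 3))
  cv <- cv_spec(5, 1, 31)
  tr <- sequential_sweep(g$table, spec, cv, k_grid = c(1, 4, 12))
  expect_s3_class(tr, "selection_trace")
  expect_equal(lengths(tr$features), c(1, 4, 12))
  # k = 1 is the global KS argmax
  rk <- rank_features_ks(g$table)
  expect_equal(tr$features[[1]], rk$name[1])
  # all-singleton cut has zero intra-cluster correlation
  expect_equal(tr$intra_cluster_abs_corr[3], 0)
  # at k = p the sweep equals a direct CV run on all features
  direct <- run_cv(ft_select(g$table, sort(colnames(g$table$values))), spec, cv)
  expect_equal(tr$cv_auroc[3], mean(direct$per_fold$auroc))
  # serialization
  csv <- tempfile(fileext = ".csv")
  write_selection_trace(tr, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$k, c(1, 4, 12))
  expect_equal(strsplit(back$features[2], ";")[[1]], tr$features[[2]])
})

test_that("leakage-safe sweep recomputes selection per fold", {
  g <- generate_block_table(block_spec(n_blocks = 3, block_size = 3,
                                       informative_blocks = 1,
                                       class_shift = 1.5, n_rows = 150,
                                       seed = 9))
  tr <- sequential_sweep(g$table,
                         model_spec("gradient_boosting", list(nrounds = 20)),
                         cv_spec(3, 1, 2), k_grid = 3, leakage_safe = TRUE)
  expect_true(tr$cv_auroc > 0.7)
})

test_that("choose_k honours fixed and knee strategies", {
  tr <- structure(data.frame(k = 1:4,
                             cv_auroc = c(0.80, 0.90, 0.905, 0.903)),
                  class = c("selection_trace", "data.frame"))
  tr$features <- list("a", c("a", "b"), c("a", "b", "c"),
                      c("a", "b", "c", "d"))
  expect_equal(choose_k(tr, "fixed_k", k = 1), "a")
  expect_equal(choose_k(tr, "fixed_k", k = 3), c("a", "b", "c"))
  expect_error(choose_k(tr, "fixed_k", k = 29), "not in the trace")
  expect_equal(choose_k(tr, "knee", tolerance = 0), c("a", "b", "c"))
  expect_equal(choose_k(tr, "knee", tolerance = 0.01), c("a", "b"))
})
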