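# Independent brute-force oracles and planted-defect fixtures used
# across the suite. These deliberately avoid the package's own
# implementation paths.

# AUROC as the literal all-pairs Mann-Whitney probability.
auroc_allpairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Two-sample KS statistic by evaluating the ECDF difference on the full
# pooled grid with plain proportions.
ks_grid <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  d <- vapply(grid, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1))
  max(d)
}

# Feature table with exactly known cleaning defects:
#   7 columns: f1 f2 f3 c_dup1 c_dup2(=c_dup1) c_miss c_dom
#   105 rows: 100 base + conflicting identical pair (101,102) +
#   identical triple with agreeing targets (103-105)
make_cleaning_fixture <- function(seed = 7) {
  set.seed(seed)
  n_base <- 100
  vals <- cbind(f1 = rnorm(n_base), f2 = rnorm(n_base), f3 = rnorm(n_base),
                c_dup1 = rnorm(n_base))
  vals <- cbind(vals, c_dup2 = vals[, "c_dup1"])
  c_miss <- rnorm(n_base); c_miss[1:97] <- NA
  c_dom <- rep(7, n_base); c_dom[50] <- 8
  vals <- cbind(vals, c_miss = c_miss, c_dom = c_dom)
  target <- rep(c(0, 1), length.out = n_base)
  conflict <- c(rnorm(4), NA, 7)  # rows 101 = 102, targets 0 vs 1
  triple <- c(rnorm(4), NA, 7)    # rows 103 = 104 = 105, targets all 1
  conflict <- c(conflict[1:4], conflict[4], conflict[5:6])  # dup col pattern
  triple <- c(triple[1:4], triple[4], triple[5:6])
  vals <- rbind(vals, conflict, conflict, triple, triple, triple)
  rownames(vals) <- sprintf("r%03d", seq_len(nrow(vals)))
  target <- c(target, 0, 1, 1, 1, 1)
  list(table = feature_table(vals, target),
       expected = list(
         n_rows_in = 105, n_rows_out = 101, n_cols_in = 7, n_cols_out = 4,
         collapsed_duplicate_rows = 2,
         removed_conflicting_rows = c("r101", "r102"),
         dropped_high_missing = "c_miss",
         dropped_near_constant = "c_dom",
         collapsed_duplicate_columns = list(c("c_dup1", "c_dup2"))))
}

# Small separable fixture reused by modeling tests.
make_separable_table <- function(n = 200, seed = 2) {
  g <- generate_block_table(block_spec(n_blocks = 4, block_size = 3,
                                       informative_blocks = 1:2,
                                       class_shift = 1.5, n_rows = n,
                                       seed = seed))
  g$table
}
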