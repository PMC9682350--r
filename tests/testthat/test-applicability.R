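# Fingerprints, Tanimoto similarity and the applicability domain.

test_that("fingerprints are 1024-bit, deterministic and spelling-invariant", {
  fp <- fingerprint(c("CCO", "OCC", "CCO"))
  expect_equal(ncol(fp), 1024)
  expect_identical(fp[1, ], fp[2, ])
  expect_identical(fp[1, ], fp[3, ])
  expect_true(all(fp %in% c(0L, 1L)))
  expect_gt(sum(fp[1, ]), 0)
  expect_error(fingerprint("C1CC"), "invalid SMILES")
})

test_that("tanimoto similarity follows intersection over union", {
  a <- integer(1024); b <- integer(1024)
  a[1:3] <- 1L; b[2:4] <- 1L
  expect_equal(tanimoto(a, b), 0.5)  # 2 shared / 4 union
  expect_equal(tanimoto(a, a), 1)
  b2 <- integer(1024); b2[10:12] <- 1L
  expect_equal(tanimoto(a, b2), 0)
  expect_warning(z <- tanimoto(integer(8), integer(8)), "empty")
  expect_equal(z, 0)
  expect_error(tanimoto(a, integer(10)), "lengths differ")
  # symmetry and bounds on real fingerprints
  fps <- fingerprint(c("CCO", "CCCCO", "c1ccccc1"))
  for (i in 1:3) for (j in 1:3) {
    s <- tanimoto(fps[i, ], fps[j, ])
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, tanimoto(fps[j, ], fps[i, ]))
    if (i == j) expect_equal(s, 1)
  }
})

test_that("average top-k similarity averages, falls back and excludes self", {
  q <- integer(20); q[1:10] <- 1L
  ref <- rbind(c(rep(1L, 9), integer(11)),   # subset: 9/10 = 0.9
               c(rep(1L, 4), integer(16)),   # 4/10 = 0.4
               c(rep(1L, 2), integer(18)))   # 2/10 = 0.2
  expect_equal(average_top_k_similarity(q, ref, k = 5), mean(c(0.9, 0.4, 0.2)))
  expect_equal(average_top_k_similarity(q, ref, k = 1), 0.9)
  expect_equal(average_top_k_similarity(q, ref, k = 2), 0.65)
  # monotone non-increasing in k
  sims <- vapply(1:3, function(k) average_top_k_similarity(q, ref, k),
                 numeric(1))
  expect_true(all(diff(sims) <= 0))
  # self-exclusion
  ref2 <- rbind(q, ref)
  expect_equal(average_top_k_similarity(q, ref2, k = 3, exclude = 1),
               average_top_k_similarity(q, ref, k = 3))
  expect_error(average_top_k_similarity(q, ref[0, , drop = FALSE]), "empty")
})

test_that("threshold calibration separates familiar from alien chemistry", {
  train <- fingerprint(toy_compound_set("sugars_like", 15))
  valid <- fingerprint(toy_compound_set("sugars_like", 18)[16:18])
  ad <- calibrate_threshold(train, valid, percentile_p = 5)
  expect_s3_class(ad, "ad_model")
  expect_equal(length(ad$calibration$train_scores), 15)
  expect_equal(length(ad$calibration$validation_scores), 3)
  # same-family validation sits almost entirely above the threshold
  expect_gte(mean(ad$calibration$validation_scores >= ad$threshold), 0.95)
  # structurally alien scaffolds score below the familiar chemistry
  alien <- fingerprint(toy_compound_set("aromatics", 5))
  alien_scores <- vapply(seq_len(5), function(i)
    average_top_k_similarity(alien[i, ], train, 5), numeric(1))
  expect_lt(max(alien_scores), min(ad$calibration$train_scores))
  # p = 0 gives the validation minimum
  ad0 <- calibrate_threshold(train, valid, percentile_p = 0)
  expect_equal(ad0$threshold, min(ad0$calibration$validation_scores))
})

test_that("in_domain verdicts use the >= boundary convention", {
  train <- fingerprint(toy_compound_set("alkanes", 12))
  ad <- calibrate_threshold(train, train[1:3, ], percentile_p = 5)
  # a training compound is inside its own domain
  r <- in_domain("CCCC", ad)
  expect_equal(r$verdict, "inside")
  expect_true(is.numeric(r$score))
  # boundary score counts as inside
  ad_edge <- ad
  ad_edge$threshold <- r$score
  expect_equal(in_domain("CCCC", ad_edge)$verdict, "inside")
  # degenerate single-atom query has an empty fingerprint
  expect_warning(out <- in_domain("O", ad), "empty")
  expect_equal(out$verdict, "outside")
})

test_that("ad calibration is split-stable under a fixed seed and round-trips", {
  ds <- demo_compound_set(12)
  cur <- curate_compounds(ds)$dataset
  ad1 <- calibrate_ad(cur, seed = 31)
  ad2 <- calibrate_ad(cur, seed = 31)
  expect_equal(ad1$threshold, ad2$threshold)
  expect_equal(ad1$calibration, ad2$calibration)
  path <- tempfile(fileext = ".json")
  write_ad_model(ad1, path)
  back <- read_ad_model(path)
  expect_equal(back$threshold, ad1$threshold)
  expect_equal(back$train_fingerprints, ad1$train_fingerprints,
               ignore_attr = TRUE)
  q <- reference_molecules()[["sucrose"]]
  expect_equal(in_domain(q, back)$score, in_domain(q, ad1)$score)
})
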