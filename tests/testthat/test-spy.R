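test_that("the unified threshold is the mean of per-repetition minima", {
  ds <- make_random_dataset(m = 14, n = 6, seed = 8)
  thr <- estimate_spy_threshold(ds, spy_config(seed = 3))
  expect_s3_class(thr, "spy_threshold")
  expect_equal(thr$t, mean(thr$per_rep_minima))
  expect_gte(thr$t, min(thr$per_rep_minima))
  expect_lte(thr$t, max(thr$per_rep_minima))
  # source target carries the maximum positive count
  expect_equal(thr$source_target,
               ds$target_ids[which.max(colSums(ds$A))])
  expect_equal(nrow(tidy(thr)), 10)
})

test_that("threshold estimation matches a replayed explicit-inversion pipeline", {
  ds <- make_random_dataset(m = 16, n = 8, seed = 21)
  thr <- estimate_spy_threshold(ds, spy_config(seed = 12), lambda = 0.5)
  replayed <- replay_spy_threshold(ds, 0.10, 10, seed = 12, lambda = 0.5)
  expect_lt(abs(thr$t - replayed), 1e-8)
})

test_that("degenerate positive sets are rejected with guidance", {
  A <- matrix(0, 4, 2)
  A[1, 1] <- 1  # max degree 1
  ds <- dti_dataset(A, diag(4), diag(2))
  expect_error(estimate_spy_threshold(ds), "larger dataset")

  ds2 <- make_random_dataset(m = 10, n = 4, seed = 2)
  expect_error(
    estimate_spy_threshold(ds2, spy_config(spy_fraction = 0.95)),
    "empty the positive set"
  )
})

test_that("reliable negatives use a strict score threshold and stay in U", {
  # identity kernel, lambda 0: training scores equal the labels exactly,
  # so unlabeled drugs score 0 and positives score 1
  A <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4)
  ds <- dti_dataset(A, diag(4), diag(2))
  rn_above <- identify_reliable_negatives(ds, threshold = 1e-6, lambda = 0)
  expect_true(all(rn_above[A == 0]))   # 0 < 1e-6: reliable
  expect_false(any(rn_above[A == 1]))  # disjoint from positives
  rn_at <- identify_reliable_negatives(ds, threshold = 0, lambda = 0)
  expect_false(any(rn_at))             # 0 < 0 is false: boundary excluded
})

test_that("reliable negatives dominate unlabeled pairs on clean separated data", {
  frac <- c()
  for (s in 1:5) {
    sim <- generate_dti(synthetic_spec(m = 50, n = 16, hidden_fraction = 0,
                                       seed = 100 + s))
    thr <- estimate_spy_threshold(sim$dataset, spy_config(seed = s))
    rn <- identify_reliable_negatives(sim$dataset, thr)
    u <- sim$dataset$A == 0
    frac <- c(frac, sum(rn[u]) / sum(u))
  }
  expect_gte(mean(frac), 0.5)
})

test_that("spy classifiers train on positives plus reliable negatives only", {
  ds <- make_random_dataset(m = 10, n = 4, seed = 31)

  # force RN = all unlabeled: the spy layer must collapse onto the ordinary one
  rn_all <- structure(ds$A == 0, dimnames = dimnames(ds$A))
  layer <- train_spy_classifiers(ds, rn_all)
  ordinary <- train_local_classifiers(ds)
  q <- ds$drug_sim[1:3, ]
  expect_equal(
    dtilocal:::score_bottom_layer(layer, q),
    dtilocal:::score_bottom_layer(ordinary, q)
  )

  # P = {d1}, RN = {d3}: the 2x2 restricted system, solved explicitly
  rn_one <- structure(matrix(FALSE, 10, 4), dimnames = dimnames(ds$A))
  A_mod <- ds$A
  A_mod[, 2] <- 0
  A_mod[1, 2] <- 1
  ds2 <- dti_dataset(A_mod, ds$drug_sim, ds$target_sim)
  rn_one[3, 2] <- TRUE
  suppressWarnings(layer2 <- train_spy_classifiers(ds2, rn_one))
  idx <- c(1, 3)
  w_exp <- solve(ds$drug_sim[idx, idx] + diag(0.5, 2)) %*% c(1, 0)
  expect_equal(unname(layer2$models[[2]]$weights), unname(drop(w_exp)))
  expect_equal(unname(layer2$models[[2]]$idx), idx)

  # empty RN falls back to the ordinary classifier with a warning
  rn_none <- structure(matrix(FALSE, 10, 4), dimnames = dimnames(ds$A))
  expect_warning(layer3 <- train_spy_classifiers(ds, rn_none),
                 "ordinary classifier")
  expect_equal(
    dtilocal:::score_bottom_layer(layer3, q),
    dtilocal:::score_bottom_layer(ordinary, q)
  )
})

test_that("the spy pipeline is deterministic under a fixed seed", {
  ds <- make_random_dataset(m = 15, n = 6, seed = 9)
  t1 <- estimate_spy_threshold(ds, spy_config(seed = 77))
  t2 <- estimate_spy_threshold(ds, spy_config(seed = 77))
  expect_identical(t1$per_rep_minima, t2$per_rep_minima)
  rn1 <- identify_reliable_negatives(ds, t1)
  rn2 <- identify_reliable_negatives(ds, t2)
  expect_identical(unclass(rn1), unclass(rn2))
  t3 <- estimate_spy_threshold(ds, spy_config(seed = 78))
  expect_false(identical(t1$per_rep_minima, t3$per_rep_minima))
})
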