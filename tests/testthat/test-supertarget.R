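block_similarity <- function(sizes, within, between) {
  lab <- rep(seq_along(sizes), sizes)
  S <- ifelse(outer(lab, lab, "=="), within, between)
  diag(S) <- 1
  S
}

test_that("target clustering recovers separated blocks and degenerate cuts", {
  S <- block_similarity(c(3, 4), within = 0.9, between = 0.1)
  part <- cluster_targets(S, cut_similarity = 0.6)
  expect_true(same_partition(part, rep(c(1, 2), c(3, 4))))

  part_hi <- cluster_targets(S, cut_similarity = 0.999)
  expect_equal(length(unique(part_hi)), 7)  # all singletons

  expect_error(cluster_targets(S, cut_similarity = 1.2), "range")
})

test_that("clustering matches a naive average-linkage oracle", {
  for (s in 1:5) {
    withr::with_seed(s, {
      S <- matrix(runif(64), 8)
      S <- (S + t(S)) / 2
      diag(S) <- 1
    })
    for (cut in c(0.3, 0.5, 0.7)) {
      expect_true(same_partition(
        cluster_targets(S, cut),
        naive_average_linkage(S, 1 - cut)
      ), info = sprintf("seed %d cut %.1f", s, cut))
    }
  }
})

test_that("raising the cut never merges previously separate super-targets", {
  withr::with_seed(42, {
    S <- matrix(runif(100), 10)
    S <- (S + t(S)) / 2
    diag(S) <- 1
  })
  coarse <- cluster_targets(S, 0.4)
  fine <- cluster_targets(S, 0.7)
  # refinement: targets together at the fine cut are together at the coarse cut
  together_fine <- outer(fine, fine, "==")
  together_coarse <- outer(coarse, coarse, "==")
  expect_true(all(together_coarse[together_fine]))
})

test_that("union adjacency is the column-wise OR", {
  A <- cbind(c(1, 0, 0, 1), c(0, 0, 0, 1), c(0, 1, 0, 0))
  B <- build_union_adjacency(A, c(1, 1, 2))
  expect_equal(unname(B[, 1]), c(1, 0, 0, 1))
  expect_equal(unname(B[, 2]), c(0, 1, 0, 0))  # singleton copied unchanged

  withr::with_seed(10, {
    A_r <- matrix(rbinom(60, 1, 0.3), 10)
    part <- sample(1:3, 6, replace = TRUE)
  })
  B_r <- build_union_adjacency(A_r, part)
  for (q in sort(unique(part))) {
    for (i in 1:10) {
      expect_equal(unname(B_r[i, paste0("st", q)]),
                   as.numeric(any(A_r[i, part == q] == 1)))
    }
  }
})

test_that("fake interactions mark structurally isolated interactors", {
  # a super-target with exactly one interacting drug has no co-interactors
  S <- block_similarity(c(4, 2), 0.9, 0.1)
  B <- cbind(c(1, 1, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 0))
  fake <- mark_fake_interactions(B, S, k = 3)
  expect_equal(unname(fake[, 2]), c(0, 0, 0, 0, 1, 0))
  # four mutually most-similar interactors: a clique, no fakes
  expect_equal(sum(fake[, 1]), 0)

  expect_error(mark_fake_interactions(B, S, k = 6), "smaller")
})

test_that("fake mask and acceptance flags equal brute-force recomputation", {
  for (s in 1:5) {
    withr::with_seed(s, {
      m <- 12
      S <- matrix(runif(m * m), m)
      S <- (S + t(S)) / 2
      diag(S) <- 1
      B <- matrix(rbinom(m * 4, 1, 0.4), m)
    })
    fake <- mark_fake_interactions(B, S, k = 3)
    expect_equal(unname(fake), brute_fake_mask(B, S, 3))
    B_clean <- B * (1 - fake)
    expect_true(all(B_clean <= B))  # cleaning never creates interactions
    flags <- acceptance_flags(B_clean, S, k = 3)
    expect_equal(flags$accepted, brute_acceptance(B_clean, S, 3))
  }
})

test_that("the adaptive rule compares mean neighbor counts with k/2", {
  # two interactors that are each other's nearest neighbors: n_u = 1 < 1.5
  S <- block_similarity(c(2, 4), 0.9, 0.1)
  B <- matrix(c(1, 1, 0, 0, 0, 0), ncol = 1)
  flags <- acceptance_flags(B, S, k = 3)
  expect_equal(flags$mean_neighbor_count, 1)
  expect_false(flags$accepted)

  # four mutually-similar interactors: n_u = 3 >= 1.5
  B4 <- matrix(c(1, 1, 1, 1, 0, 0), ncol = 1)
  S4 <- block_similarity(c(4, 2), 0.9, 0.1)
  flags4 <- acceptance_flags(B4, S4, k = 3)
  expect_equal(flags4$mean_neighbor_count, 3)
  expect_true(flags4$accepted)

  # empty super-target columns are rejected
  B0 <- cbind(B4, 0)
  expect_false(acceptance_flags(B0, S4, k = 3)$accepted[2])
})

test_that("super-target classifiers reduce to per-target models when the layer is trivial", {
  ds <- make_random_dataset(m = 8, n = 4, seed = 17)
  part <- 1:4  # all singletons, no cleaning applied
  B <- build_union_adjacency(ds$A, part)
  expect_equal(unname(B), unname(ds$A))
  W_super <- train_supertarget_classifiers(B, ds$drug_sim)
  W_ord <- train_local_classifiers(ds)$weight_matrix
  expect_equal(unname(W_super), unname(W_ord))

  # all-zero cleaned column: all scores zero
  B0 <- B; B0[, 2] <- 0
  W0 <- train_supertarget_classifiers(B0, ds$drug_sim)
  expect_equal(unname(drop(ds$drug_sim[1:3, ] %*% W0[, 2])), rep(0, 3))

  # 3-drug toy with identity kernel: labels / 1.5 on one-hot queries
  W3 <- train_supertarget_classifiers(matrix(c(1, 0, 1), 3), diag(3))
  expect_equal(unname(drop(diag(3) %*% W3)), c(1, 0, 1) / 1.5)
})

test_that("the assembled layer is internally consistent and tidyable", {
  ds <- make_random_dataset(m = 12, n = 8, seed = 23)
  layer <- build_supertarget_layer(ds, cut_similarity = 0.5, k = 3)
  B <- layer$union_adjacency
  expect_true(all(layer$fake_mask <= B))          # only existing links marked
  expect_equal(layer$cleaned_adjacency, B * (1 - layer$fake_mask))
  expect_equal(sort(unique(layer$partition)),
               seq_len(ncol(B)))                  # total partition
  td <- tidy(layer)
  expect_equal(nrow(td), 8)
  expect_equal(glance(layer)$n_supertargets, ncol(B))
})
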