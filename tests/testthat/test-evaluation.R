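test_that("pessimistic ranks give ties the worst rank of their group", {
  r <- pessimistic_ranks(c(0.9, 0.5, 0.5, 0.2))
  expect_equal(r, c(1, 3, 3, 4))
  # matrix form ranks within rows
  m <- pessimistic_ranks(rbind(c(3, 1, 2), c(1, 1, 1)))
  expect_equal(unname(m), rbind(c(1, 3, 2), c(3, 3, 3)))
  # distinct scores: a permutation; ties: weakly increasing as scores fall
  withr::with_seed(1, s <- runif(8))
  expect_setequal(pessimistic_ranks(s), 1:8)
})

test_that("AUC matches its pairwise definition", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auc_score(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  # 3 wins + 1 tie over 4 positive/negative pairs
  expect_equal(auc_score(c(0.9, 0.5, 0.5, 0.2), c(1, 1, 0, 0)), 0.875)
  expect_true(is.na(auc_score(c(0.1, 0.9), c(1, 1))))

  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(5:50, 1)
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
      labels <- rbinom(n, 1, 0.4)
    })
    if (sum(labels) %in% c(0, n)) labels[1:2] <- c(0, 1)
    expect_identical(auc_score(scores, labels), brute_auc(scores, labels))
  }
})

test_that("average precision handles ties pessimistically", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # single positive tied with a negative at the top: pessimistic rank 2 of 10
  scores <- c(0.9, 0.9, runif(8, 0, 0.5))
  labels <- c(1, rep(0, 9))
  expect_equal(aupr_score(scores, labels), 0.5)
  expect_true(is.na(aupr_score(runif(4), rep(0, 4))))

  for (s in 1:30) {
    withr::with_seed(s, {
      scores <- round(runif(20), 2)
      labels <- rbinom(20, 1, 0.3)
    })
    if (sum(labels) == 0) labels[1] <- 1
    expect_lt(abs(aupr_score(scores, labels) - brute_ap(scores, labels)),
              1e-10)
  }
})

test_that("Coverage is the mean worst rank of the true targets, minus one", {
  expect_equal(coverage(c(5, 4, 3, 2, 1), c(1, 0, 0, 0, 1)), 4)
  sc <- rbind(5:1, 5:1)
  lb <- rbind(c(0, 0, 1, 0, 0), c(1, 0, 0, 0, 1))
  expect_equal(coverage(sc, lb), (3 + 5) / 2 - 1)
  expect_equal(coverage(sc, lb, subtract_one = FALSE), 4)

  # drugs with no true target are excluded from p, with a message
  lb0 <- rbind(c(0, 0, 1, 0, 0), c(0, 0, 0, 0, 0))
  expect_message(cv <- coverage(sc, lb0), "excluded")
  expect_equal(cv, 2)
  expect_error(coverage(sc, lb * 0), "no test drug")

  withr::with_seed(7, {
    S <- matrix(runif(160), 20, 8)
    L <- matrix(rbinom(160, 1, 0.3), 20, 8)
  })
  L[rowSums(L) == 0, 1] <- 1
  expect_equal(coverage(S, L), naive_coverage(S, L))
})

test_that("the oracle baseline equals the mean positive count minus one", {
  expect_equal(oracle_coverage(diag(4)), 0)
  L <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_equal(oracle_coverage(L), 1)
  expect_equal(oracle_coverage(L, subtract_one = FALSE), 2)
  # self-consistency: labels used as scores give the same value
  withr::with_seed(3, Lr <- matrix(rbinom(60, 1, 0.4), 10, 6))
  Lr[rowSums(Lr) == 0, 1] <- 1
  expect_equal(oracle_coverage(Lr), coverage(Lr, Lr))
})

test_that("the random baseline agrees with its closed form", {
  # one target: only one rank exists
  one <- random_coverage(matrix(1, 5, 1), reps = 5, seed = 1)
  expect_equal(one$estimate, 0)
  expect_equal(one$closed_form, 0)
  # one drug, one positive among nine targets: expected rank (n+1)/2
  single <- random_coverage(matrix(c(1, rep(0, 8)), 1), reps = 50, seed = 2)
  expect_equal(single$closed_form, 4)
  expect_lt(abs(single$estimate - 4), 3 * single$se + 1e-9)
})

test_that("normalized Coverage interpolates between the baselines", {
  expect_equal(normalized_coverage(2, 2, 10), 0)
  expect_equal(normalized_coverage(10, 2, 10), 1)
  expect_equal(normalized_coverage(6, 2, 10), 0.5)
  expect_true(is.na(normalized_coverage(5, 3, 3)))
})

test_that("ranking metrics are invariant under strictly increasing transforms", {
  withr::with_seed(11, {
    S <- matrix(runif(80), 10, 8)
    L <- matrix(rbinom(80, 1, 0.35), 10, 8)
  })
  L[rowSums(L) == 0, 1] <- 1
  f <- function(x) exp(3 * x) - 1  # strictly increasing
  expect_equal(auc_score(as.vector(S), as.vector(L)),
               auc_score(as.vector(f(S)), as.vector(L)))
  expect_equal(aupr_score(as.vector(S), as.vector(L)),
               aupr_score(as.vector(f(S)), as.vector(L)))
  expect_equal(coverage(S, L), coverage(f(S), L))
})

test_that("the metrics panel is coherent", {
  withr::with_seed(21, {
    S <- matrix(runif(120), 15, 8)
    L <- matrix(rbinom(120, 1, 0.3), 15, 8)
  })
  L[rowSums(L) == 0, 1] <- 1
  panel <- dti_metrics(S, L)
  expect_equal(panel$auc, auc_score(as.vector(S), as.vector(L)))
  expect_equal(panel$coverage, suppressMessages(coverage(S, L)))
  expect_equal(panel$nc,
               normalized_coverage(panel$coverage, panel$c_oracle,
                                   panel$c_random))
  expect_equal(panel$c_over_n_targets, panel$coverage / 8)
})
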