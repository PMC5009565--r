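# Ranking-based evaluation: AUC, average precision, and the Coverage measure
# with its random and oracle baselines. The tie rule is pessimistic
# (maximum / competition ranks) everywhere: rank 1 is the highest score and
# tied scores all receive the worst rank of their tie group.

#' Pessimistic ranks of scores
#'
#' Rank 1 is the highest score; ties share the maximum (worst) rank of their
#' group. For a matrix, ranks are computed within each row.
#'
#' @param scores Numeric vector or matrix (rows = test drugs).
#' @return Integer ranks, same shape as `scores`.
#' @export
pessimistic_ranks <- function(scores) {
  rank_row <- function(s) rank(-s, ties.method = "max")
  if (is.matrix(scores)) {
    out <- t(apply(scores, 1, rank_row))
    dimnames(out) <- dimnames(scores)
    out
  } else {
    rank_row(scores)
  }
}

#' Area under the ROC curve
#'
#' Computed as `(n' + 0.5 n'') / (n_pos * n_neg)` where `n'` counts
#' positive/negative pairs in which the positive scores higher and `n''`
#' counts score ties — evaluated exactly, via average ranks, in
#' `O(n log n)`.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 labels of the same length.
#' @return The AUC, or `NA` when only one class is present.
#' @examples
#' auc_score(c(0.9, 0.5, 0.5, 0.2), c(1, 1, 0, 0))  # 0.875
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("length mismatch")
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: the mean, over positives, of the
#' precision at each positive's position in the ranking. Tied scores are
#' ordered pessimistically (negatives before positives within a tie group),
#' consistent with [pessimistic_ranks()].
#'
#' @inheritParams auc_score
#' @return The average precision, or `NA` when there are no positives.
#' @export
aupr_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    return(NA_real_)
  }
  ord <- order(-scores, labels)  # within ties, label 0 first (pessimistic)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1]) / n_pos
}

#' Coverage of the true targets
#'
#' For each test drug, the worst (maximum, pessimistic) rank among its true
#' targets; Coverage is the mean over drugs, minus one: how far down the
#' predicted target list one must go, on average, to cover every true target
#' of a drug. Lower is better. Drugs with no true target are excluded from
#' the average (with a message) since their worst rank is undefined.
#'
#' @param score_matrix `p x n` matrix of confidence scores (rows = test
#'   drugs). A vector is treated as a single drug.
#' @param label_matrix Binary matrix of the same shape marking true
#'   interactions.
#' @param subtract_one Keep the trailing `- 1` of the definition (default
#'   `TRUE`). `FALSE` reports the mean worst rank itself, a variant some
#'   summaries use.
#' @return The Coverage value.
#' @examples
#' coverage(c(5, 4, 3, 2, 1), c(1, 0, 0, 0, 1))  # worst rank 5 -> 4
#' @export
coverage <- function(score_matrix, label_matrix, subtract_one = TRUE) {
  if (!is.matrix(score_matrix)) score_matrix <- matrix(score_matrix, nrow = 1)
  if (!is.matrix(label_matrix)) label_matrix <- matrix(label_matrix, nrow = 1)
  if (!identical(dim(score_matrix), dim(label_matrix))) {
    abort("score and label matrices must have the same shape")
  }
  if (nrow(score_matrix) == 0L) abort("empty test set")
  keep <- rowSums(label_matrix) > 0
  if (!any(keep)) abort("no test drug has a true target")
  if (any(!keep)) {
    inform(sprintf("%d test drug(s) with no true target excluded from Coverage",
                   sum(!keep)))
  }
  worst <- vapply(which(keep), function(i) {
    r <- pessimistic_ranks(score_matrix[i, ])
    max(r[label_matrix[i, ] == 1])
  }, numeric(1))
  mean(worst) - if (subtract_one) 1 else 0
}

#' Oracle Coverage baseline
#'
#' Coverage of a perfect scorer that outputs the labels themselves. Under the
#' pessimistic tie rule all of a drug's positives tie at rank equal to its
#' positive count, so the baseline is the mean positive count minus one.
#'
#' @inheritParams coverage
#' @return The oracle Coverage.
#' @export
oracle_coverage <- function(label_matrix, subtract_one = TRUE) {
  if (!is.matrix(label_matrix)) label_matrix <- matrix(label_matrix, nrow = 1)
  k <- rowSums(label_matrix)
  k <- k[k > 0]
  if (length(k) == 0L) abort("no test drug has a true target")
  mean(k) - if (subtract_one) 1 else 0
}

#' Random-prediction Coverage baseline
#'
#' Mean Coverage over `reps` independent uniform score matrices, together
#' with the closed-form expectation: for a drug with `k` true targets among
#' `n`, the expected worst rank of `k` uniformly placed targets is
#' `k (n + 1) / (k + 1)`.
#'
#' @inheritParams coverage
#' @param reps Number of Monte-Carlo repetitions (default 100).
#' @param seed Integer seed.
#' @return A list with `estimate` (Monte-Carlo mean), `closed_form`, `se`
#'   (standard error of the estimate), and `reps`.
#' @export
random_coverage <- function(label_matrix, reps = 100L, seed = 1L,
                            subtract_one = TRUE) {
  check_scalar(reps, "reps", lower = 1)
  if (!is.matrix(label_matrix)) label_matrix <- matrix(label_matrix, nrow = 1)
  n <- ncol(label_matrix)
  offset <- if (subtract_one) 1 else 0
  k <- rowSums(label_matrix)
  k_pos <- k[k > 0]
  if (length(k_pos) == 0L) abort("no test drug has a true target")
  closed <- mean(k_pos * (n + 1) / (k_pos + 1)) - offset
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(r) {
      suppressMessages(coverage(
        matrix(runif(length(label_matrix)), nrow(label_matrix)),
        label_matrix, subtract_one = subtract_one
      ))
    }, numeric(1))
  })
  list(estimate = mean(draws), closed_form = closed,
       se = stats::sd(draws) / sqrt(reps), reps = as.integer(reps))
}

#' Normalized Coverage
#'
#' Rescales Coverage between the oracle baseline (0) and the random baseline
#' (1): `NC = (Coverage - C_oracle) / (C_random - C_oracle)`. Lower is
#' better.
#'
#' @param coverage Observed Coverage.
#' @param c_oracle,c_random Baselines from [oracle_coverage()] and
#'   [random_coverage()].
#' @return The normalized Coverage, or `NA` when `c_random <= c_oracle`.
#' @export
normalized_coverage <- function(coverage, c_oracle, c_random) {
  if (c_random <= c_oracle) {
    return(NA_real_)
  }
  (coverage - c_oracle) / (c_random - c_oracle)
}

#' Full metrics panel for a score matrix
#'
#' Computes the pooled AUC and average precision over all (drug, target)
#' pairs, Coverage with its oracle and random (closed-form expectation)
#' baselines, the normalized Coverage, the Coverage-to-target-count ratio,
#' and the mean per-drug AUC over drugs carrying both classes.
#'
#' @inheritParams coverage
#' @return A one-row tibble.
#' @export
dti_metrics <- function(score_matrix, label_matrix, subtract_one = TRUE) {
  if (!is.matrix(score_matrix)) score_matrix <- matrix(score_matrix, nrow = 1)
  if (!is.matrix(label_matrix)) label_matrix <- matrix(label_matrix, nrow = 1)
  cov <- suppressMessages(coverage(score_matrix, label_matrix, subtract_one))
  c_or <- oracle_coverage(label_matrix, subtract_one)
  n <- ncol(label_matrix)
  k <- rowSums(label_matrix)
  k_pos <- k[k > 0]
  c_rand <- mean(k_pos * (n + 1) / (k_pos + 1)) - if (subtract_one) 1 else 0
  per_drug <- vapply(seq_len(nrow(score_matrix)), function(i) {
    auc_score(score_matrix[i, ], label_matrix[i, ])
  }, numeric(1))
  tibble(
    auc = auc_score(as.vector(score_matrix), as.vector(label_matrix)),
    aupr = aupr_score(as.vector(score_matrix), as.vector(label_matrix)),
    coverage = cov,
    c_oracle = c_or,
    c_random = c_rand,
    nc = normalized_coverage(cov, c_or, c_rand),
    c_over_n_targets = cov / n,
    per_drug_auc = mean(per_drug, na.rm = TRUE)
  )
}
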