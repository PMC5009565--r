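# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive enumeration / explicit
# matrix inversion rather than the code paths they verify.

# O(n^2) pairwise AUC: (wins + 0.5 * ties) / (n_pos * n_neg)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  ties <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) wins <- wins + 1 else if (p == q) ties <- ties + 1
    }
  }
  (wins + 0.5 * ties) / (length(pos) * length(neg))
}

# Average precision by explicit positional loop under pessimistic tie order
# (negatives precede positives within a tie group).
brute_ap <- function(scores, labels) {
  n <- length(scores)
  ord <- order(-scores, labels)  # label 0 first among exact ties
  lab <- labels[ord]
  total <- 0
  hits <- 0
  for (i in seq_len(n)) {
    if (lab[i] == 1) {
      hits <- hits + 1
      total <- total + hits / i
    }
  }
  if (hits == 0) NA_real_ else total / hits
}

# Per-drug scan: rank of a target = number of scores >= its score.
naive_coverage <- function(score_matrix, label_matrix, subtract_one = TRUE) {
  worst <- c()
  for (i in seq_len(nrow(score_matrix))) {
    pos <- which(label_matrix[i, ] == 1)
    if (length(pos) == 0) next
    ranks <- vapply(pos, function(j) {
      sum(score_matrix[i, ] >= score_matrix[i, j])
    }, numeric(1))
    worst <- c(worst, max(ranks))
  }
  mean(worst) - if (subtract_one) 1 else 0
}

# Naive agglomerative average-linkage clustering, cut at distance h:
# repeatedly merge the closest pair of clusters while their average
# pairwise distance is <= h.
naive_average_linkage <- function(sim, h) {
  n <- nrow(sim)
  d <- 1 - sim
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        avg <- mean(d[clusters[[a]], clusters[[b]]])
        if (avg < best_d) {
          best_d <- avg
          best <- c(a, b)
        }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (q in seq_along(clusters)) labels[clusters[[q]]] <- q
  labels
}

# Two partitions describe the same clustering iff their co-membership
# matrices agree.
same_partition <- function(p1, p2) {
  identical(outer(p1, p1, "=="), outer(p2, p2, "=="))
}

# Exhaustive double-loop recomputation of the fake-interaction mask.
brute_fake_mask <- function(B, drug_sim, k) {
  m <- nrow(B)
  fake <- matrix(0, m, ncol(B))
  for (q in seq_len(ncol(B))) {
    for (u in seq_len(m)) {
      if (B[u, q] != 1) next
      s <- drug_sim[u, ]
      s[u] <- -Inf
      nn <- order(s, decreasing = TRUE)[seq_len(k)]
      co <- setdiff(which(B[, q] == 1), u)
      if (length(intersect(nn, co)) == 0) fake[u, q] <- 1
    }
  }
  fake
}

# Exhaustive recomputation of the adaptive acceptance flags.
brute_acceptance <- function(B_cleaned, drug_sim, k) {
  vapply(seq_len(ncol(B_cleaned)), function(q) {
    inter <- which(B_cleaned[, q] == 1)
    if (length(inter) == 0) return(FALSE)
    counts <- vapply(inter, function(u) {
      s <- drug_sim[u, ]
      s[u] <- -Inf
      nn <- order(s, decreasing = TRUE)[seq_len(k)]
      length(intersect(nn, setdiff(inter, u)))
    }, numeric(1))
    mean(counts) >= k / 2
  }, logical(1))
}

# Replays the spy-threshold procedure with explicit matrix inversion,
# reproducing the same seeded draws as the implementation.
replay_spy_threshold <- function(dataset, spy_fraction, reps, seed, lambda) {
  A <- dataset$A
  K <- dataset$drug_sim
  j_star <- which.max(colSums(A))
  P <- which(A[, j_star] == 1)
  n_spies <- max(1L, ceiling(spy_fraction * length(P)))
  Minv <- solve(K + diag(lambda, nrow(K)))
  rep_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, reps))
  minima <- vapply(seq_len(reps), function(r) {
    spies <- withr::with_seed(rep_seeds[r], sample(P, n_spies))
    y <- A[, j_star]
    y[spies] <- 0
    w <- Minv %*% y
    min(K[spies, , drop = FALSE] %*% w)
  }, numeric(1))
  mean(minima)
}

# Straight-line recomputation of the combined two-layer score matrix by
# explicit matrix algebra, mirroring each pipeline stage independently.
oracle_comb_scores <- function(dataset, queries, lambda = 0.5,
                               spy_fraction = 0.10, spy_reps = 10L,
                               cut_similarity = 0.6, k = 3L, seed = 1L) {
  A <- dataset$A
  K <- dataset$drug_sim
  m <- nrow(A)
  n <- ncol(A)
  Minv <- solve(K + diag(lambda, m))
  clip <- function(x) {
    x[x < 0] <- 0
    x[x > 1] <- 1
    x
  }

  # spy bottom layer; training-drug scores feed the [0, 1] calibration
  t_val <- replay_spy_threshold(dataset, spy_fraction, spy_reps, seed, lambda)
  bottom <- matrix(0, nrow(queries), n)
  bottom_train <- matrix(0, m, n)
  for (j in seq_len(n)) {
    y <- A[, j]
    sc_train <- K %*% (Minv %*% y)
    rn <- which(y == 0 & sc_train < t_val)
    if (length(rn) == 0) {
      bottom[, j] <- queries %*% (Minv %*% y)
      bottom_train[, j] <- sc_train
    } else {
      idx <- sort(c(which(y == 1), rn))
      Msub <- solve(K[idx, idx] + diag(lambda, length(idx)))
      w <- Msub %*% y[idx]
      bottom[, j] <- queries[, idx, drop = FALSE] %*% w
      bottom_train[, j] <- K[, idx, drop = FALSE] %*% w
    }
  }

  # super-target top layer
  part <- naive_average_linkage(dataset$target_sim, 1 - cut_similarity)
  qs <- sort(unique(part))
  B <- vapply(qs, function(q) {
    as.numeric(rowSums(A[, part == q, drop = FALSE]) > 0)
  }, numeric(m))
  B <- B * (1 - brute_fake_mask(B, K, k))
  accepted <- brute_acceptance(B, K, k)
  W_top <- Minv %*% B
  top <- queries %*% W_top
  top_train <- K %*% W_top

  scale01 <- function(x, r) (x - r[1]) / (r[2] - r[1])
  fused <- clip(scale01(bottom, range(bottom_train)))
  top <- clip(scale01(top, range(top_train)))
  for (j in seq_len(n)) {
    q_of_j <- match(part[j], qs)
    if (accepted[q_of_j]) {
      fused[, j] <- sqrt(top[, q_of_j] * fused[, j])
    }
  }
  fused
}

# Small deterministic datasets used across tests.
make_random_dataset <- function(m = 12, n = 6, seed = 1) {
  withr::with_seed(seed, {
    S <- matrix(runif(m * m, 0.05, 0.95), m)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    Ts <- matrix(runif(n * n, 0.05, 0.95), n)
    Ts <- (Ts + t(Ts)) / 2
    diag(Ts) <- 1
    A <- matrix(rbinom(m * n, 1, 0.35), m, n)
    if (max(colSums(A)) < 2) A[1:2, 1] <- 1  # spy step needs >= 2 positives
    dti_dataset(A, S, Ts)
  })
}
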