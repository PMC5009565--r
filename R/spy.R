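#' Spy configuration
#'
#' Parameters of the positive-unlabeled Spy step: the fraction of positives
#' injected as spies, the number of repetitions averaged into the unified
#' threshold, and the seed driving the draws.
#'
#' @param spy_fraction Fraction of the positive set drawn as spies per
#'   repetition (default 0.10).
#' @param repetitions Number of repeated spy draws averaged (default 10).
#' @param seed Integer seed; each repetition uses a deterministic child seed.
#' @return A `spy_config` list.
#' @export
spy_config <- function(spy_fraction = 0.10, repetitions = 10L, seed = 1L) {
  check_scalar(spy_fraction, "spy_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(repetitions, "repetitions", lower = 1)
  structure(list(spy_fraction = spy_fraction,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "spy_config")
}

#' Estimate the unified spy threshold
#'
#' Because one drug similarity matrix underlies every local classifier, a
#' single score threshold is assumed to separate reliable negatives for all
#' targets. It is estimated on the target with the most interacting drugs:
#' per repetition, `ceiling(spy_fraction * |P|)` spies (at least one) are
#' drawn from that target's positive set `P` and relabeled as unlabeled, an
#' ordinary RLS classifier is fitted on the perturbed labels, and the
#' repetition's threshold is the minimum score among the spies. The unified
#' threshold `t` is the mean over repetitions.
#'
#' @param dataset A [dti_dataset()] restricted to the training drugs.
#' @param config A [spy_config()].
#' @param lambda RLS regularization parameter.
#' @return An object of class `spy_threshold`: list with `t`,
#'   `per_rep_minima`, `source_target`, `config`, `lambda`.
#' @export
estimate_spy_threshold <- function(dataset, config = spy_config(),
                                   lambda = 0.5) {
  A <- dataset$A
  K <- dataset$drug_sim
  degree <- colSums(A)
  j_star <- which.max(degree)  # ties: first (lowest index)
  P <- which(A[, j_star] == 1)
  if (length(P) < 2L) {
    abort(sprintf(
      "max-degree target '%s' has only %d positive(s); the spy threshold needs >= 2 (use a larger dataset)",
      dataset$target_ids[j_star], length(P)
    ))
  }
  n_spies <- max(1L, ceiling(config$spy_fraction * length(P)))
  if (n_spies >= length(P)) {
    abort("spy draw would empty the positive set; lower `spy_fraction`")
  }
  solver <- rls_solver(K, lambda)
  rep_seeds <- derive_seeds(config$seed, config$repetitions)
  minima <- vapply(seq_len(config$repetitions), function(r) {
    spies <- withr::with_seed(rep_seeds[r], sample(P, n_spies))
    y <- A[, j_star]
    y[spies] <- 0  # spies join the unlabeled pool
    w <- solver(y)
    min(K[spies, , drop = FALSE] %*% w)
  }, numeric(1))
  structure(
    list(t = mean(minima), per_rep_minima = minima,
         source_target = dataset$target_ids[j_star],
         n_spies = n_spies, config = config, lambda = lambda),
    class = "spy_threshold"
  )
}

#' @export
print.spy_threshold <- function(x, ...) {
  cat(sprintf("<spy_threshold> t = %.4f from target '%s' (%d reps, %d spies/rep)\n",
              x$t, x$source_target, length(x$per_rep_minima), x$n_spies))
  invisible(x)
}

#' @method tidy spy_threshold
#' @export
tidy.spy_threshold <- function(x, ...) {
  tibble(repetition = seq_along(x$per_rep_minima),
         threshold = x$per_rep_minima)
}

#' Identify reliable negatives for every target
#'
#' For each target the ordinary local classifier (positives = interacting
#' drugs, everything else unlabeled-as-negative) scores the unlabeled drugs;
#' those scoring strictly below the unified spy threshold are reliable
#' negatives. Ties at the threshold stay unlabeled. Spy injection happens
#' only once, while estimating the threshold — not per target.
#'
#' @param dataset Training-fold [dti_dataset()]; must be the fold the
#'   threshold was estimated on.
#' @param threshold A [spy_threshold()] (or a bare numeric threshold).
#' @param lambda RLS regularization parameter.
#' @return An `m x n` logical matrix of class `reliable_negatives`; entry
#'   `(i, j)` marks drug `i` as a reliable negative for target `j`.
#' @export
identify_reliable_negatives <- function(dataset, threshold, lambda = 0.5) {
  t_val <- if (inherits(threshold, "spy_threshold")) threshold$t else threshold
  A <- dataset$A
  K <- dataset$drug_sim
  solver <- rls_solver(K, lambda)
  W <- solver(A)                      # weights for all targets at once
  scores <- K %*% W                   # training-drug scores, m x n
  rn <- (scores < t_val) & (A == 0)   # RN_j is a subset of the unlabeled set
  dimnames(rn) <- dimnames(A)
  structure(rn, class = c("reliable_negatives", class(rn)),
            threshold = t_val)
}

#' Train the Spy bottom layer
#'
#' Fits, per target, an RLS classifier on the target's positives (label 1)
#' and its reliable negatives (label 0) only; unlabeled drugs outside the
#' reliable-negative set are excluded from training entirely. Targets whose
#' reliable-negative set is empty fall back to the ordinary classifier, with
#' one summarizing warning.
#'
#' @param dataset Training-fold [dti_dataset()].
#' @param rn Output of [identify_reliable_negatives()] on the same fold.
#' @param lambda RLS regularization parameter.
#' @return A `dti_bottom_layer` of per-target models.
#' @export
train_spy_classifiers <- function(dataset, rn, lambda = 0.5) {
  A <- dataset$A
  K <- dataset$drug_sim
  n <- ncol(A)
  full_solver <- rls_solver(K, lambda)
  fallback <- character(0)
  models <- vector("list", n)
  for (j in seq_len(n)) {
    pos <- A[, j] == 1
    rn_j <- rn[, j] & !pos  # defensive: RN never overlaps positives
    if (!any(rn_j)) {
      fallback <- c(fallback, dataset$target_ids[j])
      models[[j]] <- list(idx = seq_len(nrow(A)),
                          weights = full_solver(A[, j],
                                                context = dataset$target_ids[j]))
      next
    }
    idx <- which(pos | rn_j)
    sub_solver <- rls_solver(K[idx, idx, drop = FALSE], lambda)
    models[[j]] <- list(idx = idx,
                        weights = sub_solver(A[idx, j],
                                             context = dataset$target_ids[j]))
  }
  if (length(fallback)) {
    warn(sprintf(
      "no reliable negatives for %d target(s) (%s); ordinary classifier used there",
      length(fallback), paste(head(fallback, 5), collapse = ", ")
    ))
  }
  # training-drug scores calibrate the affine [0, 1] map used before fusion
  train_scores <- vapply(models, function(mod) {
    drop(K[, mod$idx, drop = FALSE] %*% mod$weights)
  }, numeric(nrow(A)))
  structure(
    list(kind = "spy", models = models, lambda = lambda,
         calibration = range(train_scores),
         drug_ids = dataset$drug_ids, target_ids = dataset$target_ids,
         fallback_targets = fallback),
    class = "dti_bottom_layer"
  )
}

#' Train the ordinary (non-Spy) bottom layer
#'
#' One RLS classifier per target, trained on all training drugs with the
#' target's interaction column as labels. A single factorization of the
#' system matrix is shared across targets.
#'
#' @inheritParams train_spy_classifiers
#' @return A `dti_bottom_layer`.
#' @export
train_local_classifiers <- function(dataset, lambda = 0.5) {
  solver <- rls_solver(dataset$drug_sim, lambda)
  W <- solver(dataset$A)
  dimnames(W) <- dimnames(dataset$A)
  structure(
    list(kind = "ordinary", weight_matrix = W, lambda = lambda,
         calibration = range(dataset$drug_sim %*% W),
         drug_ids = dataset$drug_ids, target_ids = dataset$target_ids),
    class = "dti_bottom_layer"
  )
}

# q x n matrix of bottom-layer scores for query similarity rows.
score_bottom_layer <- function(layer, queries) {
  queries <- new_drug_query(queries, layer$drug_ids)
  if (layer$kind == "ordinary") {
    out <- queries %*% layer$weight_matrix
  } else {
    out <- vapply(layer$models, function(mod) {
      drop(queries[, mod$idx, drop = FALSE] %*% mod$weights)
    }, numeric(nrow(queries)))
    if (nrow(queries) == 1L) out <- matrix(out, nrow = 1)
  }
  dimnames(out) <- list(rownames(queries), layer$target_ids)
  out
}

#' @export
print.dti_bottom_layer <- function(x, ...) {
  cat(sprintf("<dti_bottom_layer> kind = %s, %d targets, %d training drugs\n",
              x$kind, length(x$target_ids), length(x$drug_ids)))
  invisible(x)
}
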