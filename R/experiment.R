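#' Split drugs into cross-validation folds
#'
#' Cold-start cross-validation holds out whole drugs: the drug indices are
#' shuffled under the seed and cut into `k` blocks whose sizes differ by at
#' most one.
#'
#' @param m Number of drugs.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return An integer vector of length `m` assigning each drug to a fold.
#' @export
split_drugs_kfold <- function(m, k = 5L, seed = 1L) {
  check_scalar(k, "k", lower = 2)
  if (m < k) abort(sprintf("cannot split %d drugs into %d folds", m, k))
  perm <- withr::with_seed(as.integer(seed), sample.int(m))
  sizes <- rep(m %/% k, k) + c(rep(1L, m %% k), rep(0L, k - m %% k))
  assignment <- integer(m)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  assignment
}

#' Cross-validated evaluation of the model variants
#'
#' Runs k-fold cross-validation over drugs. Per fold, every training
#' structure — interaction rows, the drug-similarity submatrix, the spy
#' threshold, the super-target union/cleaning/acceptance — is recomputed from
#' the training drugs only; the target-side clustering uses the full target
#' similarity, which involves no drugs. Test drugs enter solely through their
#' similarity rows to the training drugs. All requested variants share the
#' same folds and the same fitted components, so comparisons are paired.
#'
#' @param dataset A [dti_dataset()].
#' @param variants Character vector among `"rls"`, `"spy"`, `"super"`,
#'   `"comb"`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed driving the fold split and the spy draws.
#' @param lambda,spy_fraction,spy_reps,cut_similarity,supertarget_k Model
#'   parameters, see [dti_fit()].
#' @param truth Optional binary matrix, same shape as `dataset$A`, used as
#'   evaluation ground truth (e.g. the revealed matrix of a synthetic
#'   dataset). Defaults to `dataset$A`.
#' @param repeats Number of whole cross-validation repetitions (default 1);
#'   repeats use distinct derived seeds and are averaged together in
#'   `glance()`.
#' @return An object of class `dti_cv`; see [tidy.dti_cv()] and
#'   [glance.dti_cv()].
#' @examples
#' sim <- generate_dti(synthetic_spec(m = 40, n = 12, seed = 3))
#' cv <- run_cv(sim$dataset, variants = c("rls", "comb"), seed = 3,
#'              truth = reveal(sim)$A)
#' glance(cv)
#' @export
run_cv <- function(dataset, variants = c("rls", "spy", "super", "comb"),
                   folds = 5L, seed = 1L, lambda = 0.5, spy_fraction = 0.10,
                   spy_reps = 10L, cut_similarity = 0.6, supertarget_k = 3L,
                   truth = NULL, repeats = 1L) {
  variants <- match.arg(variants, c("rls", "spy", "super", "comb"),
                        several.ok = TRUE)
  if (is.null(truth)) truth <- dataset$A
  truth <- as.matrix(truth)
  if (!identical(dim(truth), dim(dataset$A))) {
    abort("`truth` must have the shape of the interaction matrix")
  }
  m <- n_drugs(dataset)
  rep_seeds <- derive_seeds(seed, repeats)

  rows <- list()
  thresholds <- list()
  for (rep_i in seq_len(repeats)) {
    plan <- split_drugs_kfold(m, folds, rep_seeds[rep_i])
    for (f in seq_len(folds)) {
      test_idx <- which(plan == f)
      train_idx <- which(plan != f)
      fitted <- cv_fold_scores(dataset, train_idx, test_idx, variants,
                               lambda, spy_fraction, spy_reps,
                               cut_similarity, supertarget_k,
                               seed = rep_seeds[rep_i] %% 100000L + f)
      spy_t <- fitted$spy_t %||% NA_real_
      thresholds[[length(thresholds) + 1L]] <-
        tibble(repeat_id = rep_i, fold = f, spy_threshold = spy_t)
      truth_test <- truth[test_idx, , drop = FALSE]
      for (v in variants) {
        met <- dti_metrics(fitted$scores[[v]], truth_test)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(repeat_id = rep_i, fold = f, variant = v,
                 n_test_drugs = length(test_idx)),
          met
        )
      }
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(rows),
      thresholds = dplyr::bind_rows(thresholds),
      config = list(variants = variants, folds = as.integer(folds),
                    seed = as.integer(seed), lambda = lambda,
                    spy_fraction = spy_fraction,
                    spy_reps = as.integer(spy_reps),
                    cut_similarity = cut_similarity,
                    supertarget_k = as.integer(supertarget_k),
                    repeats = as.integer(repeats)),
      n_drugs = m, n_targets = n_targets(dataset)
    ),
    class = "dti_cv"
  )
}

# Fits the shared components once per fold and assembles the score matrix of
# each requested variant.
cv_fold_scores <- function(dataset, train_idx, test_idx, variants,
                           lambda, spy_fraction, spy_reps,
                           cut_similarity, supertarget_k, seed) {
  train <- subset_drugs(dataset, train_idx)
  queries <- dataset$drug_sim[test_idx, train_idx, drop = FALSE]

  needs_spy <- any(variants %in% c("spy", "comb"))
  needs_ord <- any(variants %in% c("rls", "super"))
  needs_top <- any(variants %in% c("super", "comb"))

  spy_t <- NULL
  bottom_spy <- NULL
  bottom_ord <- NULL
  top <- NULL
  if (needs_spy) {
    thr <- estimate_spy_threshold(train, spy_config(spy_fraction, spy_reps, seed),
                                  lambda)
    spy_t <- thr$t
    rn <- identify_reliable_negatives(train, thr, lambda)
    bottom_spy <- suppressWarnings(train_spy_classifiers(train, rn, lambda))
  }
  if (needs_ord) bottom_ord <- train_local_classifiers(train, lambda)
  if (needs_top) {
    top <- build_supertarget_layer(train, cut_similarity, supertarget_k, lambda)
  }

  sc_spy <- if (needs_spy) score_bottom_layer(bottom_spy, queries)
  sc_ord <- if (needs_ord) score_bottom_layer(bottom_ord, queries)
  sc_top <- if (needs_top) score_supertarget_layer(top, queries)

  # fused variants use the calibrated [0, 1] scores, as in predict()
  fuse_cal <- function(bottom_layer, sc_bottom) {
    fuse_scores(rescale01(sc_bottom, bottom_layer$calibration),
                rescale01(sc_top, top$calibration),
                top$partition, top$accepted)
  }
  scores <- list()
  for (v in variants) {
    scores[[v]] <- switch(
      v,
      rls = sc_ord,
      spy = sc_spy,
      super = fuse_cal(bottom_ord, sc_ord),
      comb = fuse_cal(bottom_spy, sc_spy)
    )
  }
  list(scores = scores, spy_t = spy_t)
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf("<dti_cv> %d-fold CV over %d drugs x %d targets (%d repeat(s))\n",
              x$config$folds, x$n_drugs, x$n_targets, x$config$repeats))
  print(glance(x))
  invisible(x)
}

#' Per-fold and aggregated cross-validation metrics
#'
#' `tidy()` returns one row per (repeat, fold, variant) with the full metrics
#' panel; `glance()` averages the per-fold metrics per variant, the final
#' indicator of the protocol.
#'
#' @param x A `dti_cv` object from [run_cv()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dti_cv
#' @export
tidy.dti_cv <- function(x, ...) {
  x$results
}

#' @rdname tidy.dti_cv
#' @method glance dti_cv
#' @export
glance.dti_cv <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      dplyr::across(c("auc", "aupr", "coverage", "nc", "c_over_n_targets",
                      "per_drug_auc"),
                    ~ mean(.x, na.rm = TRUE)),
      n_folds = dplyr::n(),
      .groups = "drop"
    )
}
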