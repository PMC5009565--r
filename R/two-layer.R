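#' Fuse bottom- and top-layer scores
#'
#' For a target inside an accepted super-target, the final confidence is the
#' geometric mean `sqrt(top * bottom)` of the super-target score and the
#' target score; for a target inside a rejected super-target, the bottom
#' score alone is used. Raw RLS scores can leave `[0, 1]`, so both inputs are
#' clipped to `[0, 1]` first — an order-preserving choice on the operative
#' range that keeps the square root real.
#'
#' @param bottom `q x n` matrix of per-target scores.
#' @param top `q x Q` matrix of per-super-target scores.
#' @param partition Integer vector mapping each target to its super-target.
#' @param accepted Logical vector of length `Q`, the adaptive acceptance
#'   flags.
#' @return A `q x n` matrix of fused scores, all in `[0, 1]`.
#' @export
fuse_scores <- function(bottom, top, partition, accepted) {
  if (length(partition) != ncol(bottom)) {
    abort("every target must be mapped to a super-target")
  }
  if (anyNA(partition)) abort("unmapped target in `partition`")
  qs <- sort(unique(partition))
  col_of <- match(partition, qs)
  if (length(accepted) != length(qs)) {
    abort("`accepted` length must equal the number of super-targets")
  }
  bottom <- clip01(bottom)
  top <- clip01(top)
  fused <- bottom
  use_top <- accepted[col_of]
  if (any(use_top)) {
    jj <- which(use_top)
    fused[, jj] <- sqrt(top[, col_of[jj], drop = FALSE] *
                          bottom[, jj, drop = FALSE])
  }
  fused
}

#' Fit a local DTI prediction model
#'
#' Trains one of the four model variants on a training dataset:
#'
#' * `"rls"` — ordinary per-target RLS classifiers (bottom layer only);
#' * `"spy"` — Spy bottom layer (positives + mined reliable negatives);
#' * `"super"` — ordinary bottom layer fused with the super-target top layer;
#' * `"comb"` — Spy bottom layer fused with the super-target top layer.
#'
#' @param dataset Training [dti_dataset()].
#' @param variant Model variant, one of `"comb"`, `"rls"`, `"spy"`,
#'   `"super"`.
#' @param lambda RLS regularization parameter (default 0.5).
#' @param spy_fraction,spy_reps Spy step parameters, see [spy_config()].
#' @param cut_similarity,supertarget_k Super-target parameters, see
#'   [build_supertarget_layer()].
#' @param seed Integer seed for the spy draws.
#' @return An object of class `dti_model`.
#' @examples
#' sim <- generate_dti(synthetic_spec(m = 40, n = 12, seed = 7))
#' fit <- dti_fit(sim$dataset, variant = "comb", seed = 7)
#' fit
#' @export
dti_fit <- function(dataset, variant = c("comb", "rls", "spy", "super"),
                    lambda = 0.5, spy_fraction = 0.10, spy_reps = 10L,
                    cut_similarity = 0.6, supertarget_k = 3L, seed = 1L) {
  variant <- match.arg(variant)
  needs_spy <- variant %in% c("spy", "comb")
  needs_top <- variant %in% c("super", "comb")

  threshold <- NULL
  if (needs_spy) {
    cfg <- spy_config(spy_fraction, spy_reps, seed)
    threshold <- estimate_spy_threshold(dataset, cfg, lambda)
    rn <- identify_reliable_negatives(dataset, threshold, lambda)
    bottom <- train_spy_classifiers(dataset, rn, lambda)
  } else {
    bottom <- train_local_classifiers(dataset, lambda)
  }
  top <- if (needs_top) {
    build_supertarget_layer(dataset, cut_similarity, supertarget_k, lambda)
  }

  structure(
    list(variant = variant, bottom = bottom, top = top,
         spy_threshold = threshold, lambda = lambda,
         config = list(lambda = lambda, spy_fraction = spy_fraction,
                       spy_reps = as.integer(spy_reps),
                       cut_similarity = cut_similarity,
                       supertarget_k = as.integer(supertarget_k),
                       seed = as.integer(seed)),
         drug_ids = dataset$drug_ids, target_ids = dataset$target_ids),
    class = "dti_model"
  )
}

# Matrix of confidence scores for query similarity rows (internal fast path).
# Single-layer variants return raw kernel-ridge scores. For the fused
# variants, each layer is first mapped onto [0, 1] by the strictly monotone
# affine calibration learned from its training-drug scores (residual
# out-of-range query scores are clipped); a hard clip of the raw scores
# would pile ties at 0, which the pessimistic rank rule punishes.
predict_scores <- function(object, queries) {
  queries <- new_drug_query(queries, object$drug_ids)
  bottom <- score_bottom_layer(object$bottom, queries)
  if (is.null(object$top)) {
    return(bottom)
  }
  top <- score_supertarget_layer(object$top, queries)
  fuse_scores(
    rescale01(bottom, object$bottom$calibration),
    rescale01(top, object$top$calibration),
    object$top$partition, object$top$accepted
  )
}

#' Predict targets for new drugs
#'
#' Scores every (query drug, known target) pair with a fitted model. Queries
#' enter only through their similarities to the training drugs, matching the
#' cold-start scenario: a query drug needs no known interactions.
#'
#' @param object A fitted [dti_fit()] model.
#' @param queries Query similarity rows, see [new_drug_query()].
#' @param type `"long"` (default) for a tidy tibble, `"matrix"` for the raw
#'   `q x n` score matrix.
#' @param ... Unused.
#' @return A tibble with columns `drug_id`, `target_id`, `score`, ordered by
#'   drug then decreasing score — or the score matrix.
#' @export
predict.dti_model <- function(object, queries, type = c("long", "matrix"),
                              ...) {
  type <- match.arg(type)
  scores <- predict_scores(object, queries)
  if (type == "matrix") {
    return(scores)
  }
  tibble(
    drug_id = rep(rownames(scores), times = ncol(scores)),
    target_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores)
  ) |>
    dplyr::arrange(.data$drug_id, dplyr::desc(.data$score))
}

#' @export
print.dti_model <- function(x, ...) {
  cat(sprintf("<dti_model> variant = %s, %d drugs x %d targets, lambda = %g\n",
              x$variant, length(x$drug_ids), length(x$target_ids), x$lambda))
  if (!is.null(x$spy_threshold)) {
    cat(sprintf("  spy threshold t = %.4f (target '%s')\n",
                x$spy_threshold$t, x$spy_threshold$source_target))
  }
  if (!is.null(x$top)) {
    cat(sprintf("  super-targets: %d (%d accepted)\n",
                ncol(x$top$union_adjacency), sum(x$top$accepted)))
  }
  invisible(x)
}

#' @method glance dti_model
#' @export
glance.dti_model <- function(x, ...) {
  tibble(
    variant = x$variant,
    lambda = x$lambda,
    n_drugs = length(x$drug_ids),
    n_targets = length(x$target_ids),
    spy_threshold = if (is.null(x$spy_threshold)) NA_real_ else x$spy_threshold$t,
    n_supertargets = if (is.null(x$top)) NA_integer_ else ncol(x$top$union_adjacency),
    n_accepted = if (is.null(x$top)) NA_integer_ else sum(x$top$accepted)
  )
}
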