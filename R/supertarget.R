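#' Cluster targets into super-targets
#'
#' Average-linkage agglomerative clustering on the distance `1 - similarity`,
#' with the dendrogram cut at distance `1 - cut_similarity`. Singleton
#' clusters are allowed; raising `cut_similarity` only ever splits clusters.
#'
#' @param target_sim Symmetric target similarity matrix.
#' @param cut_similarity Similarity level at which the dendrogram is cut,
#'   in (0, 1); default 0.6.
#' @return An integer vector mapping each target to its super-target index,
#'   named by target ID when `target_sim` has dimnames.
#' @export
cluster_targets <- function(target_sim, cut_similarity = 0.6) {
  check_scalar(cut_similarity, "cut_similarity", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  target_sim <- as.matrix(target_sim)
  if (nrow(target_sim) == 1L) {
    return(setNames(1L, rownames(target_sim)))
  }
  d <- as.dist(1 - target_sim)
  hc <- hclust(d, method = "average")
  cutree(hc, h = 1 - cut_similarity)
}

#' Union adjacency between drugs and super-targets
#'
#' Column-wise OR of the interaction matrix over each super-target's member
#' targets: a drug interacts with a super-target if it interacts with any
#' member.
#'
#' @param A Binary interaction matrix, drugs as rows.
#' @param partition Integer vector from [cluster_targets()], one entry per
#'   column of `A`.
#' @return An `m x Q` binary matrix, columns named `st1 ... stQ`.
#' @export
build_union_adjacency <- function(A, partition) {
  if (length(partition) != ncol(A)) {
    abort("`partition` must assign every column of `A` to a super-target")
  }
  qs <- sort(unique(partition))
  B <- vapply(qs, function(q) {
    as.numeric(rowSums(A[, partition == q, drop = FALSE]) > 0)
  }, numeric(nrow(A)))
  if (nrow(A) == 1L) B <- matrix(B, nrow = 1)
  dimnames(B) <- list(rownames(A), paste0("st", qs))
  B
}

#' Mark fake drug/super-target interactions
#'
#' A drug's link to a super-target is fake when none of the drug's top-`k`
#' most similar other drugs interacts with that super-target: the drug is
#' structurally isolated among the super-target's interactors, so the pooled
#' positive label is likely an artifact of the union. Ties in similarity are
#' broken by ascending drug index.
#'
#' @param B Union adjacency from [build_union_adjacency()].
#' @param drug_sim Drug similarity matrix over the same drugs.
#' @param k Neighborhood size (default 3); must be `< nrow(B)`.
#' @return Binary mask of the same shape as `B`; 1 marks a fake interaction.
#' @export
mark_fake_interactions <- function(B, drug_sim, k = 3L) {
  check_scalar(k, "k", lower = 1)
  nn <- top_k_neighbors(drug_sim, k)
  fake <- matrix(0, nrow(B), ncol(B), dimnames = dimnames(B))
  for (q in seq_len(ncol(B))) {
    inter <- which(B[, q] == 1)
    for (u in inter) {
      others <- setdiff(inter, u)
      if (!any(nn[u, ] %in% others)) fake[u, q] <- 1
    }
  }
  fake
}

#' Adaptive acceptance of the super-target layer
#'
#' For each super-target, every interacting drug contributes the count of its
#' top-`k` nearest neighbors found among the other interacting drugs; the
#' mean count is compared with `k / 2`. Super-targets whose interactors are
#' not mutually similar enough (mean below `k / 2`), or that have no
#' interacting drugs left after cleaning, reject the super-target strategy
#' and fall back to the bottom layer alone.
#'
#' @param B_cleaned Union adjacency after fake interactions are removed.
#' @inheritParams mark_fake_interactions
#' @return A tibble with one row per super-target: `supertarget`,
#'   `n_interacting`, `mean_neighbor_count`, `accepted`.
#' @export
acceptance_flags <- function(B_cleaned, drug_sim, k = 3L) {
  check_scalar(k, "k", lower = 1)
  nn <- top_k_neighbors(drug_sim, k)
  rows <- purrr::map(seq_len(ncol(B_cleaned)), function(q) {
    inter <- which(B_cleaned[, q] == 1)
    if (length(inter) == 0L) {
      return(tibble(supertarget = q, n_interacting = 0L,
                    mean_neighbor_count = NA_real_, accepted = FALSE))
    }
    n_u <- vapply(inter, function(u) {
      sum(nn[u, ] %in% setdiff(inter, u))
    }, numeric(1))
    tibble(supertarget = q, n_interacting = length(inter),
           mean_neighbor_count = mean(n_u),
           accepted = mean(n_u) >= k / 2)
  })
  dplyr::bind_rows(rows)
}

#' Build the complete super-target layer
#'
#' Clusters the targets, forms the union adjacency from the training
#' interactions, removes fake interactions, computes the adaptive acceptance
#' flags on the cleaned adjacency, and trains one ordinary RLS classifier per
#' super-target. Cleaning precedes acceptance so drugs already deemed
#' spurious do not vote on whether the layer is used.
#'
#' @param dataset Training-fold [dti_dataset()].
#' @param cut_similarity Dendrogram cut level, see [cluster_targets()].
#' @param k Neighborhood size shared by the fake rule and the acceptance
#'   rule.
#' @param lambda RLS regularization parameter.
#' @return An object of class `supertarget_layer`.
#' @export
build_supertarget_layer <- function(dataset, cut_similarity = 0.6, k = 3L,
                                    lambda = 0.5) {
  partition <- cluster_targets(dataset$target_sim, cut_similarity)
  B <- build_union_adjacency(dataset$A, partition)
  fake <- mark_fake_interactions(B, dataset$drug_sim, k)
  B_cleaned <- B * (1 - fake)
  flags <- acceptance_flags(B_cleaned, dataset$drug_sim, k)
  weights <- train_supertarget_classifiers(B_cleaned, dataset$drug_sim, lambda)
  structure(
    list(partition = partition, union_adjacency = B, fake_mask = fake,
         cleaned_adjacency = B_cleaned, flags = flags,
         accepted = flags$accepted, weight_matrix = weights,
         calibration = range(dataset$drug_sim %*% weights),
         k = as.integer(k), cut_similarity = cut_similarity, lambda = lambda,
         drug_ids = dataset$drug_ids, target_ids = dataset$target_ids),
    class = "supertarget_layer"
  )
}

#' Train the per-super-target classifiers
#'
#' Ordinary RLS models, one per super-target, trained on all training drugs
#' with the cleaned union-adjacency columns as labels.
#'
#' @param B_cleaned Cleaned union adjacency.
#' @param drug_sim Drug similarity over the training drugs.
#' @param lambda RLS regularization parameter.
#' @return An `m x Q` weight matrix (one column per super-target).
#' @export
train_supertarget_classifiers <- function(B_cleaned, drug_sim, lambda = 0.5) {
  solver <- rls_solver(as.matrix(drug_sim), lambda)
  W <- solver(B_cleaned)
  dimnames(W) <- dimnames(B_cleaned)
  W
}

score_supertarget_layer <- function(layer, queries) {
  queries <- new_drug_query(queries, layer$drug_ids)
  out <- queries %*% layer$weight_matrix
  rownames(out) <- rownames(queries)
  out
}

#' @export
print.supertarget_layer <- function(x, ...) {
  cat(sprintf(
    "<supertarget_layer> %d targets -> %d super-targets (cut %.2f, k = %d); %d accepted, %d fake interactions removed\n",
    length(x$partition), ncol(x$union_adjacency), x$cut_similarity, x$k,
    sum(x$accepted), sum(x$fake_mask)
  ))
  invisible(x)
}

#' @describeIn build_supertarget_layer One row per target: its super-target,
#'   the cluster size, and the acceptance decision it inherits.
#' @param x A `supertarget_layer`.
#' @param ... Unused.
#' @method tidy supertarget_layer
#' @export
tidy.supertarget_layer <- function(x, ...) {
  tibble(
    target_id = x$target_ids,
    supertarget = unname(x$partition),
    cluster_size = as.integer(table(x$partition)[as.character(x$partition)]),
    accepted = x$accepted[x$partition]
  )
}

#' @describeIn build_supertarget_layer One-row summary of the layer.
#' @method glance supertarget_layer
#' @export
glance.supertarget_layer <- function(x, ...) {
  tibble(
    n_targets = length(x$partition),
    n_supertargets = ncol(x$union_adjacency),
    n_accepted = sum(x$accepted),
    n_fake_removed = sum(x$fake_mask),
    cut_similarity = x$cut_similarity,
    k = x$k
  )
}
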