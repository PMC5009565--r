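#' Assemble a drug-target interaction dataset
#'
#' Bundles the three matrices every model in this package consumes: the binary
#' interaction matrix `A` (drugs as rows, targets as columns), a drug-drug
#' similarity matrix and a target-target similarity matrix. All validation
#' happens here so downstream code can assume a clean dataset.
#'
#' Similarity matrices must be square, symmetric within `1e-8` (they are then
#' exactly symmetrized by averaging with their transpose) and are expected to
#' have a unit diagonal; a diagonal deviating from 1 by more than `1e-6` only
#' raises a warning and the values are kept. Similarities outside `[0, 1]` are
#' clipped with a warning, since the score-fusion step assumes nonnegative
#' scores.
#'
#' @param A Binary interaction matrix, drugs as rows and targets as columns.
#' @param drug_sim Drug-drug similarity matrix, `m x m`, values in `[0, 1]`.
#' @param target_sim Target-target similarity matrix, `n x n`.
#' @param drug_ids,target_ids Character vectors of row / column identifiers;
#'   default to the dimnames of `A`.
#'
#' @return An object of class `dti_dataset`: a list with elements `A`,
#'   `drug_sim`, `target_sim`, `drug_ids`, `target_ids`.
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 0, 1), nrow = 2,
#'             dimnames = list(c("d1", "d2"), c("t1", "t2", "t3")))
#' ds <- dti_dataset(A, diag(2), diag(3))
#' ds
#' @export
dti_dataset <- function(A, drug_sim, target_sim,
                        drug_ids = rownames(A), target_ids = colnames(A)) {
  A <- as.matrix(A)
  drug_sim <- as.matrix(drug_sim)
  target_sim <- as.matrix(target_sim)
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(drug_ids)) drug_ids <- sprintf("d%03d", seq_len(m))
  if (is.null(target_ids)) target_ids <- sprintf("t%03d", seq_len(n))
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (length(drug_ids) != m) abort("`drug_ids` must match the rows of `A`")
  if (length(target_ids) != n) abort("`target_ids` must match the columns of `A`")
  if (anyDuplicated(drug_ids)) abort("duplicate drug identifiers")
  if (anyDuplicated(target_ids)) abort("duplicate target identifiers")
  if (!is_binary01(A)) abort("interaction matrix `A` must contain only 0/1")
  storage.mode(A) <- "double"

  drug_sim <- validate_similarity(drug_sim, m, "drug_sim")
  target_sim <- validate_similarity(target_sim, n, "target_sim")

  dimnames(A) <- list(drug_ids, target_ids)
  dimnames(drug_sim) <- list(drug_ids, drug_ids)
  dimnames(target_sim) <- list(target_ids, target_ids)

  structure(
    list(A = A, drug_sim = drug_sim, target_sim = target_sim,
         drug_ids = drug_ids, target_ids = target_ids),
    class = "dti_dataset"
  )
}

validate_similarity <- function(S, size, name, sym_tol = 1e-8, diag_tol = 1e-6) {
  if (nrow(S) != ncol(S)) abort(sprintf("`%s` must be square", name))
  if (nrow(S) != size) {
    abort(sprintf("`%s` is %d x %d but %d entities are expected",
                  name, nrow(S), ncol(S), size))
  }
  asym <- max(abs(S - t(S)))
  if (asym > sym_tol) {
    abort(sprintf("`%s` is asymmetric (max |S - t(S)| = %.3g > %.3g)",
                  name, asym, sym_tol))
  }
  S <- (S + t(S)) / 2
  if (any(S < 0 | S > 1)) {
    warn(sprintf("`%s` has %d entries outside [0, 1]; clipping",
                 name, sum(S < 0 | S > 1)))
    S <- clip01(S)
  }
  if (max(abs(diag(S) - 1)) > diag_tol) {
    warn(sprintf("`%s` diagonal deviates from 1 by up to %.3g; values kept",
                 name, max(abs(diag(S) - 1))))
  }
  S
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat(sprintf(
    "<dti_dataset> %d drugs x %d targets, %d known interactions (density %.3f)\n",
    length(x$drug_ids), length(x$target_ids), sum(x$A),
    mean(x$A)
  ))
  invisible(x)
}

#' Number of drugs / targets in a dataset
#' @param dataset A [dti_dataset()].
#' @return An integer count.
#' @export
n_drugs <- function(dataset) length(dataset$drug_ids)

#' @rdname n_drugs
#' @export
n_targets <- function(dataset) length(dataset$target_ids)

# Restrict a dataset to a subset of drugs (training fold). The target
# similarity is kept whole: targets are never held out in this scenario.
subset_drugs <- function(dataset, idx) {
  dti_dataset(
    dataset$A[idx, , drop = FALSE],
    dataset$drug_sim[idx, idx, drop = FALSE],
    dataset$target_sim,
    drug_ids = dataset$drug_ids[idx],
    target_ids = dataset$target_ids
  )
}

#' Similarity rows for new (query) drugs
#'
#' Builds the `q x m` matrix of similarities between query drugs and the `m`
#' training drugs that `predict()` methods consume. Accepts either a numeric
#' matrix (rows = queries, columns = training drugs, in training order) or a
#' data frame whose first column is the query drug identifier and remaining
#' columns are named by training drug.
#'
#' @param x Matrix or data frame of query similarities.
#' @param drug_ids Character vector of training drug identifiers, in model
#'   order.
#' @return A numeric `q x m` matrix with query identifiers as rownames.
#' @export
new_drug_query <- function(x, drug_ids) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    mat <- as.matrix(x[, -1, drop = FALSE])
    if (!all(drug_ids %in% colnames(mat))) {
      abort("query data frame is missing similarity columns for some training drugs")
    }
    mat <- mat[, drug_ids, drop = FALSE]
    rownames(mat) <- ids
    x <- mat
  }
  x <- as.matrix(x)
  if (ncol(x) != length(drug_ids)) {
    abort(sprintf("query rows have %d similarities but %d training drugs exist",
                  ncol(x), length(drug_ids)))
  }
  if (any(x < 0 | x > 1)) {
    warn("query similarities outside [0, 1]; clipping")
    x <- clip01(x)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("query%02d", seq_len(nrow(x)))
  x
}
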