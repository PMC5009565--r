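# Readers and writers for the tab-delimited benchmark matrix dialect:
# first header row = column IDs, first column of each body row = row ID.
# The header may or may not carry a corner label for the ID column.

parse_matrix_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(sprintf("'%s': not a matrix file", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  body <- cells[-1]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    abort(sprintf("'%s': ragged rows (widths %s)", path,
                  paste(sort(unique(widths)), collapse = ", ")))
  }
  ncol_body <- widths[1] - 1L
  if (length(header) == ncol_body + 1L) header <- header[-1]  # corner label
  if (length(header) != ncol_body) {
    abort(sprintf("'%s': header has %d IDs but rows have %d cells",
                  path, length(header), ncol_body))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(ncol_body))
  )
  mat <- if (ncol_body == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(mat)) abort(sprintf("'%s': non-numeric cells", path))
  if (anyDuplicated(row_ids)) abort(sprintf("'%s': duplicate row IDs", path))
  if (anyDuplicated(header)) abort(sprintf("'%s': duplicate column IDs", path))
  dimnames(mat) <- list(row_ids, header)
  mat
}

#' Read a binary interaction matrix
#'
#' Reads the tab-delimited adjacency used by the enzyme / ion channel / GPCR /
#' nuclear receptor benchmark files and normalizes it to the package-wide
#' orientation: drugs as rows, targets as columns.
#'
#' With `orientation = "auto"` the file is transposed when its row IDs match
#' the target vocabulary given in `target_ids` (typically the IDs of the
#' target similarity file). Matrix shape is never used to guess orientation:
#' some benchmarks have more targets than drugs.
#'
#' @param path Path to a tab-delimited 0/1 matrix with ID headers.
#' @param orientation One of `"auto"`, `"drugs_as_rows"`, `"targets_as_rows"`.
#' @param target_ids Target vocabulary used by `"auto"`; required then.
#' @return A binary matrix, drugs as rows, with dimnames.
#' @export
read_interaction_matrix <- function(path,
                                    orientation = c("auto", "drugs_as_rows",
                                                    "targets_as_rows"),
                                    target_ids = NULL) {
  orientation <- match.arg(orientation)
  mat <- parse_matrix_file(path)
  if (!is_binary01(mat)) {
    abort(sprintf("'%s': interaction cells must be 0/1", path))
  }
  if (orientation == "auto") {
    if (is.null(target_ids)) {
      abort("orientation = \"auto\" needs `target_ids` (e.g. from the target similarity file)")
    }
    rows_are_targets <- all(rownames(mat) %in% target_ids)
    cols_are_targets <- all(colnames(mat) %in% target_ids)
    if (rows_are_targets && !cols_are_targets) {
      mat <- t(mat)
    } else if (!rows_are_targets && !cols_are_targets) {
      abort(sprintf("'%s': neither axis matches the target vocabulary", path))
    }
  } else if (orientation == "targets_as_rows") {
    mat <- t(mat)
  }
  mat
}

#' Read a similarity matrix
#'
#' Reads a square tab-delimited similarity matrix with matching row and column
#' IDs. Asymmetry up to `1e-8` is repaired by averaging with the transpose;
#' larger asymmetry is an error. A diagonal off 1 by more than `1e-6` warns.
#'
#' @param path Path to the file.
#' @return A symmetric numeric matrix with ID dimnames.
#' @export
read_similarity_matrix <- function(path) {
  mat <- parse_matrix_file(path)
  if (nrow(mat) != ncol(mat)) {
    abort(sprintf("'%s': similarity matrix must be square (got %d x %d)",
                  path, nrow(mat), ncol(mat)))
  }
  if (!identical(rownames(mat), colnames(mat))) {
    abort(sprintf("'%s': row and column IDs differ", path))
  }
  validate_similarity(mat, nrow(mat), basename(path))
}

#' Read a complete benchmark dataset
#'
#' Convenience wrapper reading the interaction matrix and both similarity
#' matrices, aligning the interaction matrix to the similarity files' ID
#' orderings.
#'
#' @param interactions,drug_sim,target_sim File paths.
#' @inheritParams read_interaction_matrix
#' @return A [dti_dataset()].
#' @export
read_dti_dataset <- function(interactions, drug_sim, target_sim,
                             orientation = "auto") {
  ds <- read_similarity_matrix(drug_sim)
  ts <- read_similarity_matrix(target_sim)
  A <- read_interaction_matrix(interactions, orientation,
                               target_ids = rownames(ts))
  if (!setequal(rownames(A), rownames(ds))) {
    abort("interaction drug IDs do not match the drug similarity file")
  }
  if (!setequal(colnames(A), rownames(ts))) {
    abort("interaction target IDs do not match the target similarity file")
  }
  A <- A[rownames(ds), rownames(ts), drop = FALSE]
  dti_dataset(A, ds, ts)
}

#' Average two similarity matrices
#'
#' Elementwise mean of two similarity matrices over the same entities, e.g.
#' a structure-based and an annotation-based drug similarity. IDs must agree
#' in the same order; there is no silent realignment.
#'
#' @param sim1,sim2 Square similarity matrices with identical dimnames.
#' @return The elementwise mean.
#' @export
average_similarities <- function(sim1, sim2) {
  sim1 <- as.matrix(sim1)
  sim2 <- as.matrix(sim2)
  if (!identical(dim(sim1), dim(sim2))) {
    abort("similarity matrices have different shapes")
  }
  if (!is.null(dimnames(sim1)) || !is.null(dimnames(sim2))) {
    if (!identical(dimnames(sim1), dimnames(sim2))) {
      abort("similarity matrices have different ID orderings; realign explicitly")
    }
  }
  (sim1 + sim2) / 2
}

write_matrix_file <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dataset in the benchmark dialect
#'
#' Writes the three tab-delimited matrix files (interactions with drugs as
#' rows, drug similarity, target similarity) so they round-trip through
#' [read_dti_dataset()].
#'
#' @param dataset A [dti_dataset()].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_dti_dataset <- function(dataset, dir, prefix = "dti") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("interactions.tsv", "drug_sim.tsv",
                                   "target_sim.tsv")))
  write_matrix_file(dataset$A, paths[1])
  write_matrix_file(dataset$drug_sim, paths[2])
  write_matrix_file(dataset$target_sim, paths[3])
  invisible(paths)
}

#' Write predictions as a three-column TSV
#'
#' @param predictions A tibble with columns `drug_id`, `target_id`, `score`
#'   (as returned by [predict.dti_model()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("drug_id", "target_id", "score") %in% names(predictions)))
  write.table(predictions[, c("drug_id", "target_id", "score")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' Serializes a metrics tibble or list (plus the configuration it was produced
#' under) as a self-describing JSON report.
#'
#' @param report A list or data frame of metrics.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
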