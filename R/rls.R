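#' Regularized least-squares kernel classifier
#'
#' The scorer at the heart of every classifier in both layers. For a target
#' with label vector \eqn{Y} over the \eqn{p} training drugs and kernel
#' \eqn{K} (the drug similarity matrix used directly, no positive-definite
#' repair), the fitted weights are \eqn{w = (K + \lambda I)^{-1} Y} and a
#' query with similarity row \eqn{k_x} scores \eqn{f(x) = k_x w}.
#'
#' The system matrix \eqn{K + \lambda I} does not depend on the label vector,
#' so one factorization can be shared by every target trained on the same
#' drug set; [rls_solver()] exposes exactly that.
#'
#' @param train_kernel Symmetric `p x p` similarity matrix over the training
#'   drugs.
#' @param labels Binary (0/1) label vector of length `p`.
#' @param lambda Regularization parameter, default 0.5. `lambda = 0` is
#'   allowed only when the kernel itself is invertible.
#' @param solver Optional solver from [rls_solver()] built on the same kernel,
#'   reused across targets.
#' @param context Optional label (e.g. the target ID) used in error messages
#'   when the solve fails.
#' @return An object of class `rls_model` with elements `weights`, `lambda`,
#'   `labels`, `drug_ids`.
#' @examples
#' K <- diag(3)
#' fit <- fit_rls(K, c(1, 0, 1), lambda = 0.5)
#' score_rls(fit, diag(3))  # 1/1.5, 0, 1/1.5
#' @export
fit_rls <- function(train_kernel, labels, lambda = 0.5, solver = NULL,
                    context = NULL) {
  train_kernel <- as.matrix(train_kernel)
  p <- nrow(train_kernel)
  if (ncol(train_kernel) != p) abort("`train_kernel` must be square")
  if (length(labels) != p) abort("`labels` length must match the kernel size")
  if (!is_binary01(labels)) abort("`labels` must be 0/1")
  check_scalar(lambda, "lambda", lower = 0)
  if (is.null(solver)) solver <- rls_solver(train_kernel, lambda)
  w <- solver(as.numeric(labels), context = context)
  structure(
    list(weights = w, lambda = lambda, labels = as.numeric(labels),
         drug_ids = rownames(train_kernel)),
    class = "rls_model"
  )
}

#' Shared factorization of the RLS system matrix
#'
#' Factorizes \eqn{K + \lambda I} once and returns a function mapping a label
#' vector to its weight vector. A Cholesky factorization is tried first; if
#' the (not necessarily positive-definite) similarity kernel defeats it, a QR
#' least-squares solve is used instead.
#'
#' @inheritParams fit_rls
#' @return A function `f(labels, context = NULL)` returning the weight vector.
#' @export
rls_solver <- function(train_kernel, lambda = 0.5) {
  train_kernel <- as.matrix(train_kernel)
  p <- nrow(train_kernel)
  M <- train_kernel + diag(lambda, p)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) {
    function(labels, context = NULL) {
      backsolve(ch, backsolve(ch, labels, transpose = TRUE))
    }
  } else {
    qr_M <- qr(M)
    function(labels, context = NULL) {
      w <- tryCatch(qr.coef(qr_M, labels), error = function(e) NULL)
      if (is.null(w) || anyNA(w)) {
        abort(sprintf(
          "RLS system (K + %g I) is singular%s", lambda,
          if (is.null(context)) "" else sprintf(" for target '%s'", context)
        ))
      }
      w
    }
  }
}

#' Score query drugs with a fitted RLS model
#'
#' @param model An `rls_model` from [fit_rls()].
#' @param test_rows `q x p` matrix of similarities between query drugs and the
#'   model's training drugs (a single row may be given as a vector).
#' @return Numeric vector of `q` confidence scores.
#' @export
score_rls <- function(model, test_rows) {
  if (is.null(dim(test_rows))) test_rows <- matrix(test_rows, nrow = 1)
  if (ncol(test_rows) != length(model$weights)) {
    abort(sprintf("query rows have %d columns but the model was trained on %d drugs",
                  ncol(test_rows), length(model$weights)))
  }
  drop(test_rows %*% model$weights)
}

#' @export
predict.rls_model <- function(object, newdata, ...) {
  score_rls(object, newdata)
}

#' @export
print.rls_model <- function(x, ...) {
  cat(sprintf("<rls_model> %d training drugs, lambda = %g, %d positives\n",
              length(x$weights), x$lambda, sum(x$labels)))
  invisible(x)
}
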