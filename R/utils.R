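# Internal helpers shared across modules.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Affine map onto [0, 1] using a calibration range learned from training
# scores: strictly monotone, so it never creates ties among in-range scores.
rescale01 <- function(x, calibration) {
  span <- calibration[2] - calibration[1]
  if (span <= 0) {
    return(x * 0 + 0.5)  # degenerate: all training scores identical
  }
  (x - calibration[1]) / span
}

is_binary01 <- function(x) {
  all(x == 0 | x == 1)
}

#' Top-k most similar other drugs, ties broken by ascending index
#'
#' Returns an m x k integer matrix; row u holds the indices of the k training
#' drugs most similar to drug u (u itself excluded). Shared by the
#' fake-interaction rule and the adaptive acceptance rule.
#' @noRd
top_k_neighbors <- function(drug_sim, k) {
  m <- nrow(drug_sim)
  if (k >= m) {
    abort(sprintf("k = %d must be smaller than the number of drugs (%d)", k, m))
  }
  t(vapply(seq_len(m), function(u) {
    s <- drug_sim[u, ]
    s[u] <- -Inf
    # order(): decreasing similarity, ties by ascending drug index
    head(order(s, decreasing = TRUE), k)
  }, integer(k)))
}

# Deterministic child seeds (< 2^31) derived from one parent seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}
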