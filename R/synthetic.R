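#' Specification of a synthetic DTI dataset
#'
#' Describes a cluster-structured drug-target interaction dataset: drugs and
#' targets fall into round-robin clusters; similarities are `within_sim`
#' inside a cluster and `between_sim` across clusters, plus Gaussian noise,
#' symmetrized and clipped to `[0, 1]` with a unit diagonal. Interactions are
#' Bernoulli draws whose probability is a drug-cluster by target-cluster
#' block value plus a uniform background. A fraction of the resulting
#' interactions is then hidden — flipped to 0 and recorded in a ledger — to
#' emulate true interactions missing from a curated dataset.
#'
#' The default block table links drug cluster `c` to target cluster
#' `((c - 1) mod target_clusters) + 1` with probability 0.5 and all other
#' blocks with 0.05, giving each drug cluster a preferred target family, the
#' regime in which similar drugs share targets.
#'
#' @param m,n Numbers of drugs and targets.
#' @param drug_clusters,target_clusters Numbers of clusters (defaults 5, 4).
#' @param within_sim,between_sim Within/between-cluster similarity levels
#'   (defaults 0.9, 0.1).
#' @param sim_noise_sd Standard deviation of the similarity noise (default
#'   0.02).
#' @param block_interaction_prob Optional `drug_clusters x target_clusters`
#'   probability table.
#' @param background_prob Background interaction probability added to every
#'   block (default 0.02).
#' @param hidden_fraction Fraction of true interactions hidden (default
#'   0.15).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(m = 100L, n = 40L, drug_clusters = 5L,
                           target_clusters = 4L, within_sim = 0.9,
                           between_sim = 0.1, sim_noise_sd = 0.02,
                           block_interaction_prob = NULL,
                           background_prob = 0.02, hidden_fraction = 0.15,
                           seed = 1L) {
  check_scalar(within_sim, "within_sim", lower = 0, upper = 1)
  check_scalar(between_sim, "between_sim", lower = 0, upper = within_sim,
               strict_upper = TRUE)
  check_scalar(sim_noise_sd, "sim_noise_sd", lower = 0)
  check_scalar(background_prob, "background_prob", lower = 0, upper = 1)
  check_scalar(hidden_fraction, "hidden_fraction", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (m < drug_clusters) abort("every drug cluster needs at least one drug")
  if (n < target_clusters) abort("every target cluster needs at least one target")
  if (is.null(block_interaction_prob)) {
    block_interaction_prob <- matrix(0.05, drug_clusters, target_clusters)
    for (c in seq_len(drug_clusters)) {
      block_interaction_prob[c, ((c - 1L) %% target_clusters) + 1L] <- 0.5
    }
  }
  if (!all(dim(block_interaction_prob) == c(drug_clusters, target_clusters))) {
    abort("`block_interaction_prob` must be drug_clusters x target_clusters")
  }
  if (any(block_interaction_prob < 0 | block_interaction_prob > 1)) {
    abort("block probabilities must lie in [0, 1]")
  }
  structure(
    list(m = as.integer(m), n = as.integer(n),
         drug_clusters = as.integer(drug_clusters),
         target_clusters = as.integer(target_clusters),
         within_sim = within_sim, between_sim = between_sim,
         sim_noise_sd = sim_noise_sd,
         block_interaction_prob = block_interaction_prob,
         background_prob = background_prob,
         hidden_fraction = hidden_fraction, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

cluster_similarity <- function(labels, within, between, noise_sd) {
  S <- ifelse(outer(labels, labels, "=="), within, between)
  if (noise_sd > 0) {
    S <- S + matrix(rnorm(length(S), sd = noise_sd), nrow(S))
  }
  S <- (S + t(S)) / 2
  S <- clip01(S)
  diag(S) <- 1
  S
}

#' Generate a synthetic DTI dataset with a hidden-interaction ledger
#'
#' Fully seeded; identical specs produce identical datasets and ledgers.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_dti`: list with `dataset` (a
#'   [dti_dataset()] whose matrix has the hidden interactions zeroed),
#'   `hidden_ledger` (tibble of the zeroed true interactions), and `spec`.
#' @examples
#' sim <- generate_dti(synthetic_spec(m = 30, n = 12, seed = 42))
#' sim$dataset
#' nrow(sim$hidden_ledger)
#' @export
generate_dti <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    drug_lab <- ((seq_len(spec$m) - 1L) %% spec$drug_clusters) + 1L
    target_lab <- ((seq_len(spec$n) - 1L) %% spec$target_clusters) + 1L
    drug_sim <- cluster_similarity(drug_lab, spec$within_sim,
                                   spec$between_sim, spec$sim_noise_sd)
    target_sim <- cluster_similarity(target_lab, spec$within_sim,
                                     spec$between_sim, spec$sim_noise_sd)
    prob <- spec$block_interaction_prob[cbind(
      rep(drug_lab, times = spec$n), rep(target_lab, each = spec$m)
    )]
    prob <- pmin(1, prob + spec$background_prob)
    A_true <- matrix(as.numeric(runif(spec$m * spec$n) < prob), spec$m, spec$n)

    ones <- which(A_true == 1)
    h <- round(spec$hidden_fraction * length(ones))
    hidden <- if (h > 0) sort(sample(ones, h)) else integer(0)
    A <- A_true
    A[hidden] <- 0

    drug_ids <- sprintf("d%03d", seq_len(spec$m))
    target_ids <- sprintf("t%03d", seq_len(spec$n))
    ledger <- tibble(
      drug = ((hidden - 1L) %% spec$m) + 1L,
      target = ((hidden - 1L) %/% spec$m) + 1L
    )
    ledger$drug_id <- drug_ids[ledger$drug]
    ledger$target_id <- target_ids[ledger$target]

    structure(
      list(
        dataset = dti_dataset(A, drug_sim, target_sim, drug_ids, target_ids),
        hidden_ledger = ledger,
        drug_clusters = drug_lab, target_clusters = target_lab,
        spec = spec
      ),
      class = "synthetic_dti"
    )
  })
}

#' Restore the hidden interactions of a synthetic dataset
#'
#' Returns the dataset with every ledgered interaction set back to 1, for use
#' as evaluation ground truth.
#'
#' @param x A `synthetic_dti` from [generate_dti()].
#' @return A [dti_dataset()].
#' @export
reveal <- function(x) {
  stopifnot(inherits(x, "synthetic_dti"))
  A <- x$dataset$A
  if (nrow(x$hidden_ledger)) {
    A[cbind(x$hidden_ledger$drug, x$hidden_ledger$target)] <- 1
  }
  dti_dataset(A, x$dataset$drug_sim, x$dataset$target_sim,
              x$dataset$drug_ids, x$dataset$target_ids)
}

#' Write the hidden-interaction ledger as TSV
#'
#' @param x A `synthetic_dti`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hidden_ledger <- function(x, path) {
  write.table(x$hidden_ledger[, c("drug_id", "target_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.synthetic_dti <- function(x, ...) {
  cat(sprintf("<synthetic_dti> %d x %d, %d interactions visible, %d hidden\n",
              x$spec$m, x$spec$n, sum(x$dataset$A), nrow(x$hidden_ledger)))
  invisible(x)
}
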