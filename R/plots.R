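# ggplot2 views of the result objects.

#' Plot cross-validated metrics by variant
#'
#' Per-fold points with the fold-averaged value highlighted, one panel per
#' metric (AUC and Coverage by default), so the paired variant comparison is
#' visible at a glance.
#'
#' @param object A `dti_cv` from [run_cv()].
#' @param metrics Character vector of metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dti_cv
#' @export
autoplot.dti_cv <- function(object, metrics = c("auc", "coverage"), ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value")
  means <- long |>
    dplyr::group_by(.data$variant, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, position = ggplot2::position_jitter(
      width = 0.08, height = 0, seed = 1
    )) +
    ggplot2::geom_point(data = means, colour = "red", size = 3, shape = 18) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "model variant", y = NULL,
                  title = "Cross-validated performance per fold",
                  subtitle = "red diamonds: fold means")
}

#' Plot a synthetic interaction matrix
#'
#' Tile view of the interaction matrix with the deliberately hidden
#' interactions highlighted, showing what the generator asks a model to
#' recover.
#'
#' @param object A `synthetic_dti` from [generate_dti()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_dti
#' @export
autoplot.synthetic_dti <- function(object, ...) {
  A <- object$dataset$A
  df <- tibble(
    drug = rep(seq_len(nrow(A)), times = ncol(A)),
    target = rep(seq_len(ncol(A)), each = nrow(A)),
    status = dplyr::case_when(as.vector(A) == 1 ~ "interaction",
                              TRUE ~ "none")
  )
  if (nrow(object$hidden_ledger)) {
    hid <- paste(object$hidden_ledger$drug, object$hidden_ledger$target)
    df$status[paste(df$drug, df$target) %in% hid] <- "hidden"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$drug,
                                   fill = .data$status)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(interaction = "grey20",
                                          hidden = "firebrick",
                                          none = "grey95")) +
    ggplot2::labs(title = "Synthetic drug-target interactions",
                  subtitle = "hidden = true interactions recorded as 0")
}
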