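# ggplot2 views of the two main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram
#'   geom_vline labs scale_shape_manual scale_colour_manual theme_minimal
NULL

#' Plot a signature as a feature-by-dataset dot panel
#'
#' Selected features are drawn per dataset and feature type; enriched
#' features (positive median coefficient) as red up-triangles, depleted ones
#' as blue down-triangles, sized by selection frequency.
#'
#' @param object a `plurisig_signature`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plurisig_signature <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  if (nrow(df) == 0) abort("cannot plot an empty signature")
  ggplot(df, aes(
    x = .data$feature_type, y = .data$dataset_id,
    shape = .data$sign, colour = .data$sign, size = .data$selection_frequency
  )) +
    geom_point() +
    scale_shape_manual(values = c("+" = 24, "-" = 25)) +
    scale_colour_manual(values = c("+" = "firebrick", "-" = "steelblue")) +
    labs(
      x = "feature", y = "dataset", size = "selection frequency",
      title = paste0("Signature (", attr(object, "scope"), " scope)")
    ) +
    theme_minimal()
}

#' Plot the per-resample AUC distribution of an ensemble
#'
#' @param object a `plurisig_ensemble`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plurisig_ensemble <- function(object, ...) {
  df <- tibble(auc = object$per_resample_auc)
  ggplot(df, aes(x = .data$auc)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$mean_auc, colour = "firebrick") +
    geom_vline(xintercept = 0.5, linetype = "dashed") +
    labs(
      x = "per-resample AUC", y = "resamples",
      title = sprintf("%s scope: mean AUC %.3f", object$scope, object$mean_auc)
    ) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
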