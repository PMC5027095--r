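# broom-style accessors: tidy() gives the per-unit table of a result,
# glance() its one-row summary.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @rdname select_signature
#' @param x a `plurisig_signature`.
#' @param all return every scope column's frequency, not only the entries at
#'   or above the threshold.
#' @param ... unused.
tidy.plurisig_signature <- function(x, all = FALSE, ...) {
  if (all) {
    attr(x, "all_frequencies", exact = TRUE)
  } else {
    as_tibble(as.data.frame(x))
  }
}

#' @export
#' @rdname select_signature
glance.plurisig_signature <- function(x, ...) {
  tibble(
    scope = attr(x, "scope"),
    n_selected = nrow(x),
    n_resamples = attr(x, "n_resamples"),
    frequency_threshold = attr(x, "frequency_threshold"),
    max_frequency = if (nrow(x)) max(x$selection_frequency) else NA_real_
  )
}

#' @export
#' @rdname run_ensemble
#' @param x a `plurisig_ensemble`.
#' @param ... unused.
tidy.plurisig_ensemble <- function(x, ...) {
  x$predictions
}

#' @export
#' @rdname run_ensemble
glance.plurisig_ensemble <- function(x, ...) {
  tibble(
    scope = x$scope,
    mean_auc = x$mean_auc,
    sd_auc = x$sd_auc,
    n_resamples = x$n_resamples,
    n_candidates = length(x$candidates),
    call_threshold = x$call_threshold
  )
}
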