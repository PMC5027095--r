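# The genes x (dataset x feature) matrix is carried as a tibble (gene_id
# column plus one numeric column per dataset/feature pair) with the column
# metadata and normalization state attached as attributes. dplyr verbs on it
# return plain tibbles; the pipeline functions always go through the
# accessors below.

new_plurisig_features <- function(tbl, info, normalized = FALSE, sentinel = 1e6) {
  stopifnot(is_tibble(tbl), "gene_id" %in% names(tbl))
  stopifnot(all(info$column %in% names(tbl)))
  structure(
    tbl[c("gene_id", info$column)],
    feature_info = info,
    normalized = normalized,
    sentinel = sentinel,
    class = c("plurisig_features", class(tbl))
  )
}

#' Column metadata of a feature matrix
#'
#' @param features a `plurisig_features` object.
#' @return tibble with columns `column`, `dataset_id`, `feature_type`,
#'   `assay_class`, one row per value column in matrix order.
#' @export
feature_info <- function(features) {
  info <- attr(features, "feature_info", exact = TRUE)
  if (is.null(info)) abort("not a plurisig feature matrix (missing column metadata)")
  info
}

#' @export
#' @rdname feature_info
is_normalized <- function(features) isTRUE(attr(features, "normalized", exact = TRUE))

feature_values <- function(features) {
  as.matrix(features[feature_info(features)$column])
}

#' Columns belonging to a feature scope
#'
#' Scopes mirror the signature types of the modelling framework: histone
#' marks only (`epigenetic`), transcription-factor/protein binding only
#' (`protein_binding`), both (`combined`), or both plus the expression
#' column (`combined_expression`).
#'
#' @param features a `plurisig_features` object.
#' @param scope one of `"epigenetic"`, `"protein_binding"`, `"combined"`,
#'   `"combined_expression"`.
#' @return character vector of column ids.
#' @export
scope_columns <- function(features,
                          scope = c("combined", "epigenetic", "protein_binding", "combined_expression")) {
  scope <- match.arg(scope)
  info <- feature_info(features)
  classes <- switch(scope,
    epigenetic = "epigenetic",
    protein_binding = "protein_binding",
    combined = c("epigenetic", "protein_binding"),
    combined_expression = c("epigenetic", "protein_binding", "expression")
  )
  info$column[info$assay_class %in% classes]
}

#' @export
print.plurisig_features <- function(x, ...) {
  info <- feature_info(x)
  cat(sprintf(
    "<plurisig feature matrix: %d genes x %d columns (%s)>\n",
    nrow(x), nrow(info), if (is_normalized(x)) "normalized" else "raw"
  ))
  NextMethod()
}
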