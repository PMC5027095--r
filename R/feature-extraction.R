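# Step 1 of the framework: assign peaks to the gene with the closest TSS,
# reduce each gene x dataset to (count, signed distance, breadth) and
# optionally the maximum fold enrichment, then Z-score the assembled matrix.

#' Assign peaks to the gene with the closest TSS
#'
#' Each peak is anchored at its summit when one is recorded, otherwise at its
#' integer midpoint `floor((start + end) / 2)`, and assigned to the gene
#' whose TSS minimizes the absolute distance to the anchor on the same
#' chromosome. Ties between two equidistant TSSs go to the lexicographically
#' smaller `gene_id`. The signed distance is strand-aware: positive when the
#' anchor lies downstream of the TSS in gene orientation, negative upstream.
#' Peaks on chromosomes with no annotated gene are dropped with a message
#' giving the count.
#'
#' @param peaks tibble of peaks as returned by [read_peak_file()].
#' @param annotation tibble as returned by [read_gene_annotation()].
#' @return tibble of assigned peaks: the peak columns plus `anchor`,
#'   `gene_id` and `signed_distance`, in input peak order.
#' @export
assign_peaks_to_genes <- function(peaks, annotation) {
  validate_annotation(annotation)
  if (nrow(annotation) == 0) abort("annotation must be nonempty")
  # double arithmetic: start + end can exceed .Machine$integer.max
  anchor <- ifelse(
    !is.na(peaks$summit_offset %||% rep(NA_integer_, nrow(peaks))),
    as.numeric(peaks$start) + peaks$summit_offset,
    floor((as.numeric(peaks$start) + peaks$end) / 2)
  )
  gene_id <- rep(NA_character_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pk_idx <- which(peaks$chrom == ch)
    genes <- annotation[annotation$chrom == ch, ]
    if (nrow(genes) == 0) next
    # sort TSSs; tie on position broken by gene_id so the lexicographically
    # smaller gene wins when two TSSs coincide or are equidistant
    ord <- order(genes$tss, genes$gene_id)
    tss <- genes$tss[ord]
    ids <- genes$gene_id[ord]
    a <- anchor[pk_idx]
    lo <- findInterval(a, tss) # index of rightmost tss <= a (0 if none)
    hi <- lo + 1L
    d_lo <- ifelse(lo >= 1L, abs(a - tss[pmax(lo, 1L)]), Inf)
    d_hi <- ifelse(hi <= length(tss), abs(tss[pmin(hi, length(tss))] - a), Inf)
    use_lo <- d_lo < d_hi |
      (d_lo == d_hi & ids[pmax(lo, 1L)] <= ids[pmin(hi, length(tss))])
    pick <- ifelse(use_lo, pmax(lo, 1L), pmin(hi, length(tss)))
    gene_id[pk_idx] <- ids[pick]
  }
  dropped <- sum(is.na(gene_id))
  if (dropped > 0) {
    inform(sprintf("%d peak(s) on chromosomes with no annotated gene were dropped", dropped))
  }
  keep <- !is.na(gene_id)
  out <- peaks[keep, , drop = FALSE]
  out$anchor <- anchor[keep]
  out$gene_id <- gene_id[keep]
  strand <- annotation$strand[match(out$gene_id, annotation$gene_id)]
  tss <- annotation$tss[match(out$gene_id, annotation$gene_id)]
  out$signed_distance <- ifelse(strand == "+", out$anchor - tss, tss - out$anchor)
  as_tibble(out)
}

#' Reduce assigned peaks to per-gene features
#'
#' For every annotated gene: `count` is the number of assigned peaks (0 when
#' none); `breadth` the length of the broadest assigned peak (0 when none);
#' `signed_distance` the signed distance of the assigned peak closest to the
#' TSS by absolute distance, with ties broken toward the downstream
#' (positive) peak; `fold_enrichment` the maximum `signal_value` among
#' assigned peaks (`NA` when none carry a signal). Genes without any peak get
#' the large positive distance sentinel, which encodes "no peak anywhere
#' near" consistently with the distance semantics.
#'
#' @param assignment output of [assign_peaks_to_genes()].
#' @param annotation the same annotation the assignment was built from.
#' @param sentinel distance value imputed for peakless genes (bp).
#' @return tibble with columns `gene_id`, `count`, `signed_distance`,
#'   `breadth`, `fold_enrichment`, one row per annotated gene in annotation
#'   order.
#' @export
extract_features <- function(assignment, annotation, sentinel = 1e6) {
  validate_annotation(annotation)
  out <- tibble(
    gene_id = annotation$gene_id,
    count = 0L,
    signed_distance = as.double(sentinel),
    breadth = 0L,
    fold_enrichment = NA_real_
  )
  if (nrow(assignment) > 0) {
    g <- match(assignment$gene_id, out$gene_id)
    if (anyNA(g)) abort("assignment contains genes absent from the annotation")
    cnt <- tabulate(g, nbins = nrow(out))
    out$count <- cnt
    len <- assignment$end - assignment$start
    br <- vapply(split(len, g), max, 0)
    out$breadth[as.integer(names(br))] <- as.integer(br)
    # closest peak by |distance|; ties go to the downstream (positive) peak
    d <- assignment$signed_distance
    ord <- order(g, abs(d), -sign(d))
    first <- ord[!duplicated(g[ord])]
    out$signed_distance[g[first]] <- d[first]
    sv <- assignment$signal_value
    has_sv <- !is.na(sv)
    if (any(has_sv)) {
      fe <- vapply(split(sv[has_sv], g[has_sv]), max, 0)
      out$fold_enrichment[as.integer(names(fe))] <- fe
    }
  }
  out
}

#' Assemble the genes x (dataset x feature) matrix
#'
#' Columns follow manifest order crossed with the feature-type order
#' `count`, `distance`, `breadth` (and `fold_enrichment` when enabled); the
#' expression column, when supplied, comes last with assay class
#' `expression`. Column ids are `<dataset_id>.<feature_type>`.
#'
#' @param per_dataset_features named list (by `dataset_id`) of tibbles from
#'   [extract_features()]; all must cover the same gene universe.
#' @param manifest dataset manifest tibble (`dataset_id`, `assay_class`, ...).
#' @param expression optional expression tibble (`gene_id`, `expression`);
#'   genes missing from it get 0.
#' @param enabled_features feature types to include; `fold_enrichment` is off
#'   by default.
#' @param sentinel signed-distance value imputed for peakless genes (bp).
#' @return an unnormalized `plurisig_features` object.
#' @export
build_feature_matrix <- function(per_dataset_features, manifest, expression = NULL,
                                 enabled_features = c("count", "distance", "breadth"),
                                 sentinel = 1e6) {
  validate_manifest(manifest)
  bad <- setdiff(enabled_features, c("count", "distance", "breadth", "fold_enrichment"))
  if (length(bad) > 0) abort(paste0("unknown feature type: ", bad[1]))
  if (!setequal(names(per_dataset_features), manifest$dataset_id)) {
    abort("per_dataset_features names must match the manifest dataset ids")
  }
  if (any(grepl("[.:]", manifest$dataset_id))) {
    abort("dataset_id must not contain '.' or ':' (reserved for column ids)")
  }
  gene_ids <- per_dataset_features[[manifest$dataset_id[1]]]$gene_id
  for (ds in manifest$dataset_id) {
    if (!identical(per_dataset_features[[ds]]$gene_id, gene_ids)) {
      abort(paste0("gene universe mismatch across datasets (dataset ", ds, ")"))
    }
  }
  ftypes <- intersect(c("count", "distance", "breadth", "fold_enrichment"), enabled_features)
  src <- c(count = "count", distance = "signed_distance", breadth = "breadth",
           fold_enrichment = "fold_enrichment")
  cols <- list()
  info <- list()
  for (d in seq_len(nrow(manifest))) {
    ds <- manifest$dataset_id[d]
    for (ft in ftypes) {
      id <- paste0(ds, ".", ft)
      cols[[id]] <- as.double(per_dataset_features[[ds]][[src[[ft]]]])
      info[[id]] <- tibble(
        column = id, dataset_id = ds, feature_type = ft,
        assay_class = manifest$assay_class[d]
      )
    }
  }
  if (!is.null(expression)) {
    e <- expression$expression[match(gene_ids, expression$gene_id)]
    e[is.na(e)] <- 0
    cols[["expression"]] <- as.double(e)
    info[["expression"]] <- tibble(
      column = "expression", dataset_id = "expression",
      feature_type = "expression", assay_class = "expression"
    )
  }
  vals <- tibble(gene_id = gene_ids, !!!cols)
  if (!all(vapply(cols, function(v) all(is.finite(v) | is.na(v)), TRUE))) {
    abort("feature values must be finite")
  }
  new_plurisig_features(vals, dplyr::bind_rows(info), normalized = FALSE, sentinel = sentinel)
}

#' Z-score normalize a feature matrix
#'
#' Each column is centred and scaled to population standard deviation 1
#' (divisor n, not n - 1) over all genes. Zero-variance columns are dropped
#' with a warning. Applying the transform twice would silently rescale
#' already-standardized features, so a normalized input is a hard error.
#'
#' @param features an unnormalized `plurisig_features` object.
#' @return the normalized matrix (a `plurisig_features` object with the
#'   `normalized` flag set).
#' @export
zscore_normalize <- function(features) {
  if (is_normalized(features)) abort("feature matrix is already normalized")
  info <- feature_info(features)
  vals <- feature_values(features)
  n <- nrow(vals)
  mu <- colMeans(vals, na.rm = TRUE)
  sd_pop <- sqrt(colMeans(sweep(vals, 2, mu)^2, na.rm = TRUE))
  keep <- is.finite(sd_pop) & sd_pop > 1e-12
  if (!any(keep)) abort("all feature columns have zero variance")
  if (any(!keep)) {
    warn(paste0(
      "dropping zero-variance column(s): ",
      paste(info$column[!keep], collapse = ", ")
    ))
  }
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep]), 2, sd_pop[keep], "/")
  out <- tibble(gene_id = features$gene_id, !!!as.data.frame(z, check.names = FALSE))
  new_plurisig_features(out, info[keep, ],
    normalized = TRUE,
    sentinel = attr(features, "sentinel", exact = TRUE) %||% 1e6
  )
}
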