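# Readers and writers for every on-disk format the pipeline touches.
# Coordinates are BED-style 0-based half-open throughout; no conversion is
# ever applied, so what is read is what downstream math sees.

peak_dialects <- c("bed3plus", "narrowPeak", "broadPeak")

#' Read a called-peak file (BED3+, narrowPeak or broadPeak)
#'
#' Track, browser and `#` comment lines are skipped. The dialect is never
#' guessed from the column count: a 10-column file can be narrowPeak or an
#' annotated BED, so the caller (normally the dataset manifest) states it.
#'
#' @param path path to a tab-separated peak file.
#' @param dialect one of `"bed3plus"`, `"narrowPeak"`, `"broadPeak"`. For
#'   narrowPeak, column 7 is kept as `signal_value` and column 10 (when
#'   non-negative) as `summit_offset`; for broadPeak column 7 is kept as
#'   `signal_value`; for BED3+ only the first four columns are used.
#' @return a tibble with columns `chrom`, `start`, `end`, `name`,
#'   `signal_value`, `summit_offset`, one row per data line in file order.
#' @export
read_peak_file <- function(path, dialect = c("bed3plus", "narrowPeak", "broadPeak")) {
  dialect <- tryCatch(match.arg(dialect),
    error = function(e) abort(paste0("unknown peak dialect: ", dialect[1]))
  )
  if (!file.exists(path)) abort(paste0("peak file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), signal_value = double(), summit_offset = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- 3L
  bad <- which(vapply(fields, length, 1L) < ncol_min)
  if (length(bad) > 0) {
    abort(sprintf("line %d: expected at least 3 tab-separated columns", line_no[bad[1]]))
  }
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("line %d: non-integer peak coordinates", line_no[bad[1]]))
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("line %d: start must be < end and non-negative", line_no[bad[1]]))
  }
  name <- get_col(4)
  signal_value <- rep(NA_real_, length(lines))
  summit_offset <- rep(NA_integer_, length(lines))
  if (dialect %in% c("narrowPeak", "broadPeak")) {
    signal_value <- suppressWarnings(as.double(get_col(7)))
  }
  if (dialect == "narrowPeak") {
    summit <- suppressWarnings(as.integer(get_col(10)))
    summit[!is.na(summit) & summit < 0L] <- NA_integer_
    bad <- which(!is.na(summit) & start + summit >= end)
    if (length(bad) > 0) {
      abort(sprintf("line %d: summit offset falls outside the peak", line_no[bad[1]]))
    }
    summit_offset <- summit
  }
  tibble(
    chrom = chrom, start = start, end = end, name = name,
    signal_value = signal_value, summit_offset = summit_offset
  )
}

#' Write peaks as an ENCODE broadPeak file
#'
#' @param peaks tibble with at least `chrom`, `start`, `end`; optional
#'   `name` and `signal_value` columns are carried through.
#' @param path output path.
#' @export
write_peak_file <- function(peaks, path) {
  n <- nrow(peaks)
  name <- if ("name" %in% names(peaks)) ifelse(is.na(peaks$name), ".", peaks$name) else rep(".", n)
  sig <- if ("signal_value" %in% names(peaks)) peaks$signal_value else rep(NA_real_, n)
  sig <- ifelse(is.na(sig), "0", formatC(sig, format = "g", digits = 17))
  out <- paste(peaks$chrom, peaks$start, peaks$end, name, 0L, ".", sig, -1L, -1L, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a header line `gene_id  chrom  tss  strand` (tab-separated). The
#' TSS is a single 0-based coordinate; strand must be `+` or `-`.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    abort(paste0("annotation must have columns: ", paste(need, collapse = ", ")))
  }
  ann <- as_tibble(df[need])
  ann$tss <- as.integer(ann$tss)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) {
    abort(paste0("duplicate gene_id in annotation: ", ann$gene_id[duplicated(ann$gene_id)][1]))
  }
  if (any(is.na(ann$tss)) || any(ann$tss < 0)) abort("tss must be a non-negative integer")
  if (!all(ann$strand %in% c("+", "-"))) {
    abort(paste0("invalid strand: ", setdiff(unique(ann$strand), c("+", "-"))[1]))
  }
  ann
}

#' @export
#' @rdname read_gene_annotation
#' @param annotation tibble as returned by [read_gene_annotation()].
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a gene list (one id per line)
#'
#' Blank lines are ignored; duplicates are collapsed with a warning. An empty
#' file is an error because an empty positive set leaves every downstream
#' step undefined.
#'
#' @param path path to a plain-text gene list.
#' @return character vector of unique gene ids, in first-seen order.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("gene list is empty: ", path))
  if (anyDuplicated(lines)) {
    warn(sprintf("%d duplicate gene ids collapsed in %s", sum(duplicated(lines)), path))
    lines <- unique(lines)
  }
  lines
}

#' @export
#' @rdname read_gene_list
#' @param genes character vector of gene ids.
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated with header `gene_id  expression`; expression values must be
#' non-negative (arbitrary normalized units).
#'
#' @param path path to the TSV file.
#' @return tibble with columns `gene_id`, `expression`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "expression")
  if (!all(need %in% names(df))) abort("expression table must have columns gene_id, expression")
  out <- as_tibble(df[need])
  out$expression <- as.double(out$expression)
  if (any(is.na(out$expression)) || any(out$expression < 0)) {
    abort("expression values must be non-negative numbers")
  }
  out
}

#' @export
#' @rdname read_expression_table
#' @param expression tibble with columns `gene_id`, `expression`.
write_expression_table <- function(expression, path) {
  df <- as.data.frame(expression)
  df$expression <- formatC(df$expression, format = "g", digits = 17)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest labels every peak file with a unique `dataset_id`, its
#' `assay_class` (`epigenetic` for histone marks, `protein_binding` for
#' transcription factors and other bound proteins), a display `label`, the
#' file `path` and its `dialect` (see [read_peak_file()]).
#'
#' @param path path to the manifest TSV.
#' @return tibble with columns `dataset_id`, `assay_class`, `label`, `path`,
#'   `dialect`.
#' @export
read_dataset_manifest <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("dataset_id", "assay_class", "label", "path", "dialect")
  if (!all(need %in% names(df))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  }
  validate_manifest(as_tibble(df[need]))
}

validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$dataset_id)) abort("duplicate dataset_id in manifest")
  bad <- setdiff(unique(manifest$assay_class), c("epigenetic", "protein_binding"))
  if (length(bad) > 0) abort(paste0("invalid assay_class: ", bad[1]))
  if ("dialect" %in% names(manifest)) {
    bad <- setdiff(unique(manifest$dialect), peak_dialects)
    if (length(bad) > 0) abort(paste0("unknown peak dialect in manifest: ", bad[1]))
  }
  manifest
}

#' @export
#' @rdname read_dataset_manifest
#' @param manifest tibble as returned by [read_dataset_manifest()].
write_dataset_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature matrix
#'
#' The on-disk form is a TSV with a two-line header: line one holds the
#' column ids (`gene_id` first), line two the per-column metadata as
#' `assay_class:feature_type` (the first cell records whether the matrix is
#' `raw` or `normalized`). Values are written with 17 significant digits so
#' the round trip is bit-exact; non-finite values are written as `nan` and
#' restored as missing.
#'
#' @param features a `plurisig_features` object (see [build_feature_matrix()]).
#' @param path output path.
#' @export
write_feature_matrix <- function(features, path) {
  info <- feature_info(features)
  vals <- as.matrix(features[info$column])
  header1 <- paste(c("gene_id", info$column), collapse = "\t")
  header2 <- paste(
    c(
      if (isTRUE(attr(features, "normalized"))) "normalized" else "raw",
      paste0(info$assay_class, ":", info$feature_type)
    ),
    collapse = "\t"
  )
  fmt <- function(v) {
    out <- formatC(v, format = "g", digits = 17)
    out[!is.finite(v)] <- "nan"
    out
  }
  body <- vapply(
    seq_len(nrow(vals)),
    function(i) paste(c(features$gene_id[i], fmt(vals[i, ])), collapse = "\t"),
    ""
  )
  writeLines(c(header1, header2, body), path)
  invisible(path)
}

#' @export
#' @rdname write_feature_matrix
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("feature matrix file must have a two-line header")
  h1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (h1[1] != "gene_id" || !(h2[1] %in% c("raw", "normalized")) || length(h1) != length(h2)) {
    abort("malformed feature matrix header: expected column ids then assay_class:feature_type metadata")
  }
  meta <- strsplit(h2[-1], ":", fixed = TRUE)
  if (any(vapply(meta, length, 1L) != 2L)) {
    abort("malformed column metadata; expected assay_class:feature_type")
  }
  info <- tibble(
    column = h1[-1],
    dataset_id = sub("\\.[^.]+$", "", h1[-1]),
    feature_type = vapply(meta, `[[`, "", 2),
    assay_class = vapply(meta, `[[`, "", 1)
  )
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (any(vapply(body, length, 1L) != length(h1))) {
    abort("feature matrix row with wrong number of fields")
  }
  gene_ids <- vapply(body, `[[`, "", 1)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(h1) - 1)
  for (j in seq_len(ncol(vals))) {
    raw <- vapply(body, `[[`, "", j + 1)
    v <- suppressWarnings(as.double(raw))
    v[raw == "nan"] <- NA_real_
    vals[, j] <- v
  }
  colnames(vals) <- info$column
  out <- as_tibble(as.data.frame(vals, check.names = FALSE))
  out <- tibble(gene_id = gene_ids, !!!out)
  new_plurisig_features(out, info, normalized = h2[1] == "normalized")
}
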