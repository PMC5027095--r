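test_that("signed distance follows gene orientation and ties break lexicographically", {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    tss = c(1000L, 2000L), strand = c("+", "-")
  )
  # anchor 1150: 150 bp downstream of gA's + strand TSS
  a <- assign_peaks_to_genes(peak_tbl("chr1", 1100, 1200), ann)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$signed_distance, 150)
  # anchor 2150: higher coordinate than a - strand TSS, hence upstream
  a <- assign_peaks_to_genes(peak_tbl("chr1", 2100, 2200), ann)
  expect_equal(a$gene_id, "gB")
  expect_equal(a$signed_distance, -150)
  # equidistant anchor goes to the lexicographically smaller gene_id
  ann2 <- tibble::tibble(
    gene_id = c("gB", "gA"), chrom = "chr1",
    tss = c(3000L, 1000L), strand = "+"
  )
  a <- assign_peaks_to_genes(peak_tbl("chr1", 1995, 2005), ann2)
  expect_equal(a$gene_id, "gA")
  # a summit overrides the midpoint as anchor
  a <- assign_peaks_to_genes(
    peak_tbl("chr1", 900, 1300, summit_offset = 100), ann
  )
  expect_equal(a$signed_distance, 0)
})

test_that("assignment equals the brute-force all-pairs minimum on random instances", {
  for (rep in 1:10) {
    set.seed(rep)
    n_genes <- sample(3:50, 1)
    n_peaks <- sample(5:200, 1)
    ann <- tibble::tibble(
      gene_id = sprintf("g%03d", sample(900, n_genes)),
      chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
      tss = sample.int(50000, n_genes),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    start <- sample.int(50000, n_peaks)
    peaks <- peak_tbl(
      sample(c("chr1", "chr2", "chr3"), n_peaks, replace = TRUE),
      start, start + sample.int(500, n_peaks)
    )
    got <- suppressMessages(assign_peaks_to_genes(peaks, ann))
    want <- brute_force_assignment(peaks, ann)
    expect_identical(got$gene_id, want[!is.na(want)])
    # strand-aware sign: recompute directly
    tss <- ann$tss[match(got$gene_id, ann$gene_id)]
    strand <- ann$strand[match(got$gene_id, ann$gene_id)]
    expect_identical(
      got$signed_distance,
      ifelse(strand == "+", got$anchor - tss, tss - got$anchor)
    )
  }
})

test_that("every peak on an annotated chromosome is counted exactly once", {
  set.seed(3)
  ann <- tiny_annotation(tss = c(1000, 40000, 90000, 140000))
  start <- sample.int(150000, 300)
  peaks <- peak_tbl("chr1", start, start + 200)
  assigned <- assign_peaks_to_genes(peaks, ann)
  feats <- extract_features(assigned, ann)
  expect_equal(sum(feats$count), nrow(peaks))
})

test_that("flipping a gene's strand negates its signed distances", {
  set.seed(4)
  ann <- tiny_annotation(tss = c(5000, 60000), strand = c("+", "-"))
  start <- sample.int(100000, 50)
  peaks <- peak_tbl("chr1", start, start + 100)
  a1 <- assign_peaks_to_genes(peaks, ann)
  ann_flipped <- ann
  ann_flipped$strand <- c("-", "+")
  a2 <- assign_peaks_to_genes(peaks, ann_flipped)
  expect_identical(a1$gene_id, a2$gene_id)
  expect_identical(a1$signed_distance, -a2$signed_distance)
})

test_that("per-gene features reduce assigned peaks as defined", {
  ann <- tibble::tibble(gene_id = "gA", chrom = "chr1", tss = 10000L, strand = "+")
  # two peaks: lengths 500 and 120, signed distances +150 and -9000
  peaks <- peak_tbl("chr1", c(9900, 940), c(10400, 1060), signal_value = c(3, 8))
  feats <- extract_features(assign_peaks_to_genes(peaks, ann), ann)
  expect_equal(feats$count, 2L)
  expect_equal(feats$breadth, 500L)
  expect_equal(feats$signed_distance, 150)
  expect_equal(feats$fold_enrichment, 8)

  # no peaks: count 0, breadth 0, distance = sentinel
  empty <- assign_peaks_to_genes(peak_tbl(character(), integer(), integer()), ann)
  feats <- extract_features(empty, ann)
  expect_equal(feats$count, 0L)
  expect_equal(feats$breadth, 0L)
  expect_equal(feats$signed_distance, 1e6)

  # peak anchored exactly at the TSS
  feats <- extract_features(
    assign_peaks_to_genes(peak_tbl("chr1", 9950, 10050), ann), ann
  )
  expect_equal(feats$signed_distance, 0)

  # equal |distance| on both sides: the downstream (positive) peak wins
  feats <- extract_features(
    assign_peaks_to_genes(peak_tbl("chr1", c(9850, 10050), c(9950, 10150)), ann), ann
  )
  expect_equal(feats$signed_distance, 100)
})

test_that("the assembled matrix has the documented layout", {
  cfg <- generator_config(
    n_genes = 10, n_positive = 2,
    n_datasets_epigenetic = 2, n_datasets_protein = 2,
    signature_datasets = list()
  )
  study <- generate_study(cfg)
  f <- study_features(study)
  info <- feature_info(f)
  expect_equal(nrow(f), 10)
  expect_equal(nrow(info), 12) # 4 datasets x 3 feature types
  expect_equal(
    info$feature_type[1:3], c("count", "distance", "breadth")
  )
  expect_equal(unique(info$dataset_id), study$manifest$dataset_id)

  fe <- study_features(study, use_expression = TRUE)
  expect_equal(nrow(feature_info(fe)), 13)
  expect_equal(utils::tail(feature_info(fe)$assay_class, 1), "expression")

  # a dataset with no peaks at all: count/breadth 0, distance all sentinel
  study$peaks[["ep01"]] <- study$peaks[["ep01"]][0, ]
  f0 <- study_features(study)
  expect_true(all(f0[["ep01.count"]] == 0))
  expect_true(all(f0[["ep01.breadth"]] == 0))
  expect_true(all(f0[["ep01.distance"]] == 1e6))

  # mismatched gene universes across datasets are a hard error
  per_ds <- lapply(study$peaks, function(pk) {
    extract_features(assign_peaks_to_genes(pk, study$annotation), study$annotation)
  })
  per_ds[[2]] <- per_ds[[2]][-1, ]
  expect_error(
    build_feature_matrix(per_ds, study$manifest),
    "gene universe mismatch"
  )
})

test_that("Z-scoring uses the population SD, drops constants and refuses to re-run", {
  f <- manual_features(
    c("gA", "gB", "gC"),
    list("d1.count" = c(1, 2, 3), "d2.count" = c(5, 5, 5)),
    tibble::tibble(
      column = c("d1.count", "d2.count"), dataset_id = c("d1", "d2"),
      feature_type = "count", assay_class = "epigenetic"
    )
  )
  expect_warning(fz <- zscore_normalize(f), "zero-variance")
  expect_equal(fz[["d1.count"]], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_false("d2.count" %in% names(fz))
  expect_true(is_normalized(fz))
  expect_error(zscore_normalize(fz), "already normalized")

  # every surviving column: mean 0, population SD 1 within 1e-8
  set.seed(9)
  g <- random_features(50, 6)$features
  vals <- as.matrix(g[feature_info(g)$column])
  expect_true(all(abs(colMeans(vals)) < 1e-8))
  expect_true(all(abs(sqrt(colMeans(sweep(vals, 2, colMeans(vals))^2)) - 1) < 1e-8))

  f_const <- manual_features(
    c("gA", "gB"), list("d1.count" = c(2, 2)),
    tibble::tibble(
      column = "d1.count", dataset_id = "d1",
      feature_type = "count", assay_class = "epigenetic"
    )
  )
  expect_warning(
    expect_error(zscore_normalize(f_const), "zero variance"),
    NA
  )
})
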